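#' Synthetic study configuration
#'
#' Parameters of the seeded generator that emulates the field design behind
#' the analysis: five nitrogen application rates grown in three replicate
#' plots and scanned at four growth stages (5 x 3 x 4 = 60 modeling
#' samples), plus an independent 15-plot field at a single uniform rate
#' scanned at the same four stages (15 x 4 = 60 validation samples). Each
#' sample is emitted as three raw spectrometer scans.
#'
#' @param n_rates nitrogen application rates, kg/ha.
#' @param reps replicate plots per rate (default 3).
#' @param stages number of growth stages (default 4).
#' @param validation_plots independent validation plots (default 15).
#' @param validation_rate nitrogen rate of the validation field, kg/ha
#'   (default 300).
#' @param no3n_range admissible petiole nitrate range, g/L (default 2--18).
#' @param noise_sd spectral noise standard deviation in reflectance units
#'   (default 0.003); the noise is band-correlated with `noise_corr_nm`
#'   correlation length, emulating smooth spectrometer error.
#' @param noise_corr_nm noise correlation length, nm (default 15).
#' @param scans_per_sample raw scans per sample (default 3).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_rates = c(0, 195.5, 299, 402.5, 506), reps = 3,
                       stages = 4, validation_plots = 15,
                       validation_rate = 300, no3n_range = c(2, 18),
                       noise_sd = 0.003, noise_corr_nm = 15,
                       scans_per_sample = 3, seed = 1) {
  stopifnot(length(n_rates) >= 1, reps >= 1, stages >= 1,
            validation_plots >= 1, noise_sd >= 0,
            length(no3n_range) == 2, all(no3n_range > 0),
            no3n_range[1] < no3n_range[2])
  structure(list(n_rates = n_rates, reps = reps, stages = stages,
                 validation_plots = validation_plots,
                 validation_rate = validation_rate,
                 no3n_range = no3n_range, noise_sd = noise_sd,
                 noise_corr_nm = noise_corr_nm,
                 scans_per_sample = scans_per_sample,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys raise a named
#' error.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, vals)
}

# treatment-mean petiole nitrate (g/L) at a given N rate, first stage
rate_mean_no3n <- function(rate, cfg) {
  lo <- 4
  hi <- 16
  ref <- max(cfg$n_rates, cfg$validation_rate)
  lo + (hi - lo) * (rate / ref)^0.8
}

# multiplicative decline of petiole nitrate across growth stages
stage_factors <- function(stages) {
  if (stages == 1) return(1)
  seq(1, 0.6, length.out = stages)
}

# lognormal multiplicative noise with unit mean and the given cv
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate petiole nitrate concentrations
#'
#' Draws per-sample nitrate-nitrogen concentrations for the modeling design
#' (treatment means increasing in N rate, declining across growth stages,
#' with 10% cv lognormal plot noise) and the validation field (single rate,
#' 15% cv between-plot variability), clipped to the configured range.
#'
#' @param cfg a [sim_config()]; its seed is used.
#' @param plot_cv,validation_plot_cv lognormal coefficients of variation
#'   (defaults 0.10 and 0.15).
#' @return list of two data frames (`modeling`, `validation`) with columns
#'   `sample_id`, `treatment`, `stage`, `plot`, `no3n`.
#' @export
simulate_no3n <- function(cfg = sim_config(), plot_cv = 0.10,
                          validation_plot_cv = 0.15) {
  set.seed(cfg$seed)
  sf <- stage_factors(cfg$stages)
  rows <- list()
  for (r in seq_along(cfg$n_rates)) {
    mu <- rate_mean_no3n(cfg$n_rates[r], cfg)
    for (st in seq_len(cfg$stages)) {
      for (rep in seq_len(cfg$reps)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("N%d_S%d_R%d", r - 1, st, rep),
          treatment = paste0("N", r - 1), stage = paste0("S", st),
          plot = sprintf("N%d_R%d", r - 1, rep),
          no3n = mu * sf[st] * lnorm_noise(1, plot_cv),
          stringsAsFactors = FALSE)
      }
    }
  }
  modeling <- do.call(rbind, rows)
  mu_v <- rate_mean_no3n(cfg$validation_rate, cfg)
  plot_eff <- lnorm_noise(cfg$validation_plots, validation_plot_cv)
  rows <- list()
  for (st in seq_len(cfg$stages)) {
    for (p in seq_len(cfg$validation_plots)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("V%02d_S%d", p, st),
        treatment = "V", stage = paste0("S", st),
        plot = sprintf("V%02d", p),
        no3n = mu_v * sf[st] * plot_eff[p] * lnorm_noise(1, plot_cv / 2),
        stringsAsFactors = FALSE)
    }
  }
  validation <- do.call(rbind, rows)
  clip <- function(v) pmin(pmax(v, cfg$no3n_range[1]), cfg$no3n_range[2])
  modeling$no3n <- clip(modeling$no3n)
  validation$no3n <- clip(validation$no3n)
  rownames(modeling) <- rownames(validation) <- NULL
  list(modeling = modeling, validation = validation)
}

# band-correlated Gaussian noise: white noise convolved with a Gaussian
# kernel and rescaled to the requested pointwise sd
correlated_noise <- function(n, sd, ell) {
  if (sd == 0) return(numeric(n))
  pad <- ceiling(3 * ell)
  z <- stats::rnorm(n + 2 * pad)
  k <- stats::dnorm(seq(-pad, pad), sd = ell)
  k <- k / sqrt(sum(k^2))           # unit output variance
  s <- stats::filter(z, k, sides = 2)
  as.numeric(s[(pad + 1):(pad + n)]) * sd
}

#' Simulate one canopy reflectance curve
#'
#' Parametric canopy spectrum on the 350--1075 nm grid at 1 nm: a flat
#' visible baseline, a green reflectance peak at 550 nm whose amplitude
#' increases with petiole nitrate (driving the blue-edge parameters
#' upward), a chlorophyll absorption well at 675 nm deepening with nitrate,
#' and a logistic red edge to a near-infrared plateau whose maximum slope
#' decreases -- and whose midpoint blue-shifts -- with nitrate (driving the
#' red-edge parameters and indices downward). This deliberately reproduces
#' the empirical correlation-sign pattern of the study design (positive
#' blue edge, negative red/yellow edge), not plant optics. Band-correlated
#' Gaussian noise of sd `cfg$noise_sd` is added and the curve is clipped to
#' [0, 1].
#'
#' @param no3n petiole nitrate concentration, g/L.
#' @param cfg a [sim_config()] (noise settings).
#' @return numeric reflectance vector of length 726 (grid 350--1075 nm).
#' @export
simulate_spectrum <- function(no3n, cfg = sim_config()) {
  wl <- 350:1075
  amp <- 0.02 + 0.04 * sqrt(no3n)
  depth <- 0.008 + 0.0008 * no3n
  vis <- 0.04 + amp * exp(-(wl - 550)^2 / (2 * 45^2)) -
    depth * exp(-(wl - 675)^2 / (2 * 16^2))
  lam0 <- 723 - 0.8 * no3n
  s <- 13 + 1.1 * no3n
  L <- stats::plogis((wl - lam0) / s)
  L668 <- stats::plogis((668 - lam0) / s)
  Lt <- pmax(0, (L - L668) / (1 - L668))
  r <- vis * (1 - Lt) + 0.46 * Lt
  r <- r + correlated_noise(length(wl), cfg$noise_sd, cfg$noise_corr_nm)
  pmin(pmax(r, 0), 1)
}

#' Generate the full labelled synthetic dataset
#'
#' Simulates nitrate concentrations for the whole design, then emits each
#' sample as `cfg$scans_per_sample` raw scans so that scan averaging is
#' exercised downstream. Fully deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `modeling` and `validation`, each a list of
#'   `spectra` (raw scans) and `targets` (data frame `sample_id`, `no3n`
#'   plus design metadata).
#' @export
generate_dataset <- function(cfg = sim_config()) {
  targets <- simulate_no3n(cfg)
  make_set <- function(tt, subseed) {
    set.seed(subseed)
    nscan <- cfg$scans_per_sample
    m <- matrix(NA_real_, nrow(tt) * nscan, 726)
    meta <- tt[rep(seq_len(nrow(tt)), each = nscan), , drop = FALSE]
    meta$scan <- rep(seq_len(nscan), nrow(tt))
    for (i in seq_len(nrow(meta)))
      m[i, ] <- simulate_spectrum(meta$no3n[i], cfg)
    meta$no3n <- NULL
    rownames(meta) <- NULL
    list(spectra = spectra(m, 350:1075, "reflectance", meta),
         targets = tt)
  }
  list(modeling = make_set(targets$modeling, cfg$seed + 1L),
       validation = make_set(targets$validation, cfg$seed + 2L))
}

#' Run the full synthetic study once
#'
#' Convenience wrapper: generates the dataset, averages scans, builds both
#' feature tables, and returns them with the targets attached. This is the
#' entry point the screening and comparison stages start from.
#'
#' @param cfg a [sim_config()].
#' @return list with `modeling` and `validation` feature tables.
#' @export
synthetic_feature_tables <- function(cfg = sim_config()) {
  ds <- generate_dataset(cfg)
  build <- function(part) {
    avg <- average_scans(part$spectra, "sample_id")
    feature_table(avg, part$targets)
  }
  list(modeling = build(ds$modeling), validation = build(ds$validation))
}
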