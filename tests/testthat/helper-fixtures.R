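# Shared in-code fixtures: small constructed spectra with known analytic
# feature values, built fresh at test time.

grid_350_1075 <- 350:1075

# flat reflectance curve
flat_spectra <- function(level = 0.3, n = 1) {
  spectra(matrix(level, n, length(grid_350_1075)), grid_350_1075,
          "reflectance",
          data.frame(sample_id = paste0("F", seq_len(n))))
}

# linear ramp R(lambda) = r0 + slope * (lambda - 350)
ramp_spectra <- function(slope = 0.001, r0 = 0) {
  vals <- r0 + slope * (grid_350_1075 - 350)
  spectra(matrix(vals, 1), grid_350_1075, "reflectance",
          data.frame(sample_id = "ramp"))
}

# piecewise-linear curve rising with `slope` per nm exactly on [from, to],
# flat elsewhere
edge_ramp_spectra <- function(slope, from, to, base = 0.1) {
  wl <- grid_350_1075
  vals <- base + slope * pmin(pmax(wl - from, 0), to - from)
  spectra(matrix(vals, 1), wl, "reflectance",
          data.frame(sample_id = "edge"))
}

# random smooth-ish reflectance curves in (0, 1)
random_spectra <- function(n = 5, seed = 99) {
  set.seed(seed)
  wl <- grid_350_1075
  m <- t(sapply(seq_len(n), function(i) {
    0.3 + 0.15 * sin(wl / runif(1, 40, 120) + runif(1, 0, 6)) +
      0.05 * sin(wl / runif(1, 5, 15))
  }))
  spectra(m, wl, "reflectance",
          data.frame(sample_id = paste0("R", seq_len(n))))
}

# tiny deterministic regression dataset
tiny_xy <- function(seed = 3, n = 20) {
  set.seed(seed)
  x <- seq(0, 2, length.out = n)
  y <- 3 * x + 2 + rnorm(n, sd = 0.3)
  list(x = x, y = y)
}

# small synthetic study kept cheap for unit tests
small_sim <- function(seed = 1) {
  sim_config(n_rates = c(0, 250, 506), reps = 2, stages = 2,
             validation_plots = 4, seed = seed)
}
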