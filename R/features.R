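#' Default trilateral edge windows (nm)
#'
#' Red edge 680--760, yellow edge 560--640, blue edge 490--530. Amplitudes
#' (Dr, Dy, Db) take the maximum first-derivative value with both endpoints
#' included; areas (SDr, SDy, SDb) sum derivative points over the half-open
#' window [start, end), so under forward differencing each area equals the
#' reflectance difference across its window.
#'
#' @return named list of `c(start, end)` pairs.
#' @export
edge_windows <- function() {
  list(red = c(680, 760), yellow = c(560, 640), blue = c(490, 530))
}

#' Trilateral edge parameters
#'
#' Computes the six trilateral parameters per sample from a first-derivative
#' spectra set: the amplitude (maximum first derivative) and area (sum of
#' first-derivative values) of the red, yellow, and blue edges.
#'
#' Within the yellow edge, canopy derivatives are typically negative, so a
#' literal (signed) maximum picks the least-negative value; that is the
#' default. `yellow_extremum = "abs_max"` instead returns the signed value of
#' the largest-magnitude derivative.
#'
#' @param d a `spectra` object of kind `"derivative"`.
#' @param windows edge windows as returned by [edge_windows()].
#' @param yellow_extremum `"max"` (signed, default) or `"abs_max"`.
#' @return data frame: `sample_id`, `Dr`, `SDr`, `Dy`, `SDy`, `Db`, `SDb`.
#' @export
trilateral_params <- function(d, windows = edge_windows(),
                              yellow_extremum = c("max", "abs_max")) {
  yellow_extremum <- match.arg(yellow_extremum)
  stopifnot_same_grid(d)
  if (d$kind != "derivative")
    stop("trilateral parameters are defined on derivative spectra",
         call. = FALSE)
  wl <- d$wavelengths
  for (w in windows) {
    if (min(wl) > w[1] || max(wl) < w[2])
      stop(sprintf("window %g-%g nm not covered by the grid", w[1], w[2]),
           call. = FALSE)
  }
  amp <- function(vals, w, mode = "max") {
    sel <- vals[, wl >= w[1] & wl <= w[2], drop = FALSE]
    if (mode == "abs_max") {
      apply(sel, 1, function(v) v[which.max(abs(v))])
    } else {
      apply(sel, 1, max)
    }
  }
  area <- function(vals, w) {
    rowSums(vals[, wl >= w[1] & wl < w[2], drop = FALSE])
  }
  v <- d$values
  data.frame(
    sample_id = d$meta$sample_id,
    Dr  = amp(v, windows$red),
    SDr = area(v, windows$red),
    Dy  = amp(v, windows$yellow, yellow_extremum),
    SDy = area(v, windows$yellow),
    Db  = amp(v, windows$blue),
    SDb = area(v, windows$blue),
    stringsAsFactors = FALSE
  )
}

vi_bands <- c(705, 710, 720, 735, 740, 750, 780, 790)

#' Vegetation indices
#'
#' Computes the six red-edge vegetation indices per sample:
#' \describe{
#'   \item{RD}{V740 / V720}
#'   \item{CI_red_edge}{V780 / V710 - 1}
#'   \item{NDRE}{(V790 - V720) / (V790 + V720)}
#'   \item{ND705}{(V750 - V705) / (V750 + V705)}
#'   \item{NIR}{V780 / V740}
#'   \item{RI_1dB}{V735 / V720}
#' }
#' where V is the value of the basis curve at the named wavelength:
#' reflectance for `basis = "original"`, or the first-derivative curve
#' (forward differencing) for `basis = "first_derivative"` -- the same
#' formulas with D(lambda) substituted for R(lambda).
#'
#' Any index whose denominator has magnitude below 1e-12 is returned as `NA`
#' for that sample (the row is flagged, not the whole table).
#'
#' @param x a `spectra` object of kind `"reflectance"` covering 705--790 nm.
#' @param basis `"original"` or `"first_derivative"`.
#' @return data frame: `sample_id` plus the six indices.
#' @export
vegetation_indices <- function(x, basis = c("original", "first_derivative")) {
  basis <- match.arg(basis)
  stopifnot_same_grid(x)
  if (x$kind != "reflectance")
    stop("supply reflectance spectra; the derivative basis is computed internally",
         call. = FALSE)
  curve <- if (basis == "original") x else first_derivative(x, "forward")
  idx <- match(vi_bands, curve$wavelengths)
  if (anyNA(idx))
    stop("curve must be defined at ", paste(vi_bands, collapse = ", "), " nm",
         call. = FALSE)
  V <- function(l) curve$values[, match(l, curve$wavelengths)]
  ratio <- function(num, den) ifelse(abs(den) < 1e-12, NA_real_, num / den)
  data.frame(
    sample_id   = x$meta$sample_id,
    RD          = ratio(V(740), V(720)),
    CI_red_edge = ratio(V(780), V(710)) - 1,
    NDRE        = ratio(V(790) - V(720), V(790) + V(720)),
    ND705       = ratio(V(750) - V(705), V(750) + V(705)),
    NIR         = ratio(V(780), V(740)),
    RI_1dB      = ratio(V(735), V(720)),
    stringsAsFactors = FALSE
  )
}

#' Full feature table
#'
#' Joins, per averaged sample, the six trilateral parameters (computed on
#' the forward first derivative), the six vegetation indices on the original
#' reflectance (suffix `_orig`), the same six on the first-derivative curve
#' (suffix `_d1`), and the petiole nitrate concentration `no3n` (g/L).
#' Samples with any undefined (flagged) index are dropped with a message
#' giving the count.
#'
#' @param x averaged `spectra` object of kind `"reflectance"`.
#' @param targets data frame with `sample_id` and `no3n` (g/L), one row per
#'   sample of `x`.
#' @return data frame with `sample_id`, 18 feature columns in fixed order,
#'   and `no3n`.
#' @export
feature_table <- function(x, targets) {
  stopifnot_same_grid(x)
  miss <- setdiff(x$meta$sample_id, targets$sample_id)
  if (length(miss))
    stop("join error: no target for sample(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  d1 <- first_derivative(x, "forward")
  tri <- trilateral_params(d1)
  vo <- vegetation_indices(x, "original")
  vd <- vegetation_indices(x, "first_derivative")
  names(vo)[-1] <- paste0(names(vo)[-1], "_orig")
  names(vd)[-1] <- paste0(names(vd)[-1], "_d1")
  ft <- Reduce(function(a, b) merge(a, b, by = "sample_id", sort = FALSE),
               list(tri, vo, vd))
  ft$no3n <- targets$no3n[match(ft$sample_id, targets$sample_id)]
  flagged <- !stats::complete.cases(ft)
  if (any(flagged)) {
    message("dropping ", sum(flagged), " sample(s) with undefined indices")
    ft <- ft[!flagged, , drop = FALSE]
  }
  ord <- c("sample_id", "Dr", "SDr", "Dy", "SDy", "Db", "SDb",
           paste0(c("RD", "CI_red_edge", "NDRE", "ND705", "NIR", "RI_1dB"),
                  "_orig"),
           paste0(c("RD", "CI_red_edge", "NDRE", "ND705", "NIR", "RI_1dB"),
                  "_d1"),
           "no3n")
  rownames(ft) <- NULL
  ft[ord]
}
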