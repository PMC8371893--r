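#' First-derivative spectra
#'
#' Differentiates reflectance curves with respect to wavelength. The default
#' forward scheme defines D(lambda_k) = (R(lambda_{k+1}) - R(lambda_k)) /
#' delta, indexed at lambda_k, so the curve loses its last point and the sum
#' of derivative values over any half-open window [a, b) telescopes exactly
#' to R(b) - R(a). The central scheme uses (R(k+1) - R(k-1)) / (2 delta) on
#' interior points.
#'
#' @param x a `spectra` object of kind `"reflectance"` on a uniform grid.
#' @param method `"forward"` (default) or `"central"`.
#' @return a `spectra` object of kind `"derivative"` (units: per nm).
#' @export
first_derivative <- function(x, method = c("forward", "central")) {
  method <- match.arg(method)
  stopifnot_same_grid(x)
  if (x$kind != "reflectance")
    stop("input is already a derivative set", call. = FALSE)
  wl <- x$wavelengths
  steps <- diff(wl)
  if (length(steps) < 1 || any(abs(steps - steps[1]) > 1e-9))
    stop("non-uniform grid: differentiate on an even wavelength grid",
         call. = FALSE)
  h <- steps[1]
  n <- length(wl)
  if (method == "forward") {
    d <- (x$values[, -1, drop = FALSE] - x$values[, -n, drop = FALSE]) / h
    new_wl <- wl[-n]
  } else {
    d <- (x$values[, 3:n, drop = FALSE] - x$values[, 1:(n - 2), drop = FALSE]) /
      (2 * h)
    new_wl <- wl[2:(n - 1)]
  }
  out <- spectra(d, new_wl, "derivative", x$meta)
  out
}

#' Savitzky-Golay smoothing
#'
#' Optional polynomial smoothing of reflectance curves ahead of
#' differentiation. Off by default throughout the package; provided for
#' noisier instruments. A window of 1 is the identity, and any curve that is
#' itself a polynomial of degree at most `polyorder` passes through
#' unchanged.
#'
#' @param x a `spectra` object.
#' @param window odd window length in grid points (> `polyorder`).
#' @param polyorder polynomial order (default 2).
#' @return smoothed `spectra` object on the same grid.
#' @export
smooth_spectra <- function(x, window = 11, polyorder = 2) {
  stopifnot_same_grid(x)
  if (window == 1) return(x)
  if (window %% 2 != 1) stop("`window` must be odd", call. = FALSE)
  if (window <= polyorder)
    stop("`window` must exceed `polyorder`", call. = FALSE)
  if (window >= length(x$wavelengths))
    stop("`window` must be shorter than the curve", call. = FALSE)
  sm <- t(apply(x$values, 1, function(r)
    signal::sgolayfilt(r, p = polyorder, n = window)))
  if (x$kind == "reflectance") sm <- pmin(pmax(sm, 0), 1)
  spectra(sm, x$wavelengths, x$kind, x$meta)
}
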