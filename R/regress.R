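#' Pearson correlation with significance flag
#'
#' Product-moment correlation between a single feature and the petiole
#' nitrate concentration, with a two-sided t-test; significance is flagged
#' at p < 0.01 (the screening tables' convention; no multiplicity
#' correction).
#'
#' @param x,y equal-length numeric vectors, n >= 3, both with non-zero
#'   variance.
#' @return list with `r`, `p_value`, `significant`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       significant = ct$p.value < 0.01, n = length(x))
}

#' Single-feature regression fit
#'
#' Fits one of the three classical families used in the screening stage:
#' linear y = a x + b and quadratic y = a x^2 + b x + c by ordinary least
#' squares, exponential y = a exp(b x) by true nonlinear least squares
#' (Levenberg-Marquardt, initialized from the log-linearized fit, which
#' requires y > 0). R-squared is 1 - SSres/SStot on the fit's own
#' predictions (it may fall below 0 for a pathological nonlinear fit and is
#' then reported as computed); RMSE is the root mean squared residual in
#' g/L.
#'
#' @param x feature vector.
#' @param y target vector (g/L).
#' @param family `"linear"`, `"exponential"`, or `"quadratic"`.
#' @return object of class `regression_fit`: `family`, `coefficients`
#'   (named a, b and, for quadratic, c), `r_squared`, `rmse`, `n`,
#'   `fitted`.
#' @export
fit_regression <- function(x, y, family = c("linear", "exponential",
                                            "quadratic")) {
  family <- match.arg(family)
  n <- length(x)
  if (length(y) != n) stop("length mismatch", call. = FALSE)
  k <- if (family == "quadratic") 3 else 2
  if (n < k + 1) stop("too few points for a ", family, " fit", call. = FALSE)
  if (family == "linear") {
    fit <- stats::lm(y ~ x)
    co <- c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
    pred <- unname(stats::fitted(fit))
  } else if (family == "quadratic") {
    fit <- stats::lm(y ~ x + I(x^2))
    cf <- stats::coef(fit)
    co <- c(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1]))
    pred <- unname(stats::fitted(fit))
  } else {
    if (any(y <= 0))
      stop("exponential family requires strictly positive targets",
           call. = FALSE)
    lin <- stats::lm(log(y) ~ x)
    start <- list(a = exp(unname(stats::coef(lin)[1])),
                  b = unname(stats::coef(lin)[2]))
    fit <- minpack.lm::nlsLM(
      y ~ a * exp(b * x), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10))
    cf <- stats::coef(fit)
    co <- c(a = unname(cf["a"]), b = unname(cf["b"]))
    pred <- co["a"] * exp(co["b"] * x)
  }
  res <- y - pred
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / sstot
  structure(list(family = family, coefficients = co,
                 r_squared = r2, rmse = sqrt(mean(res^2)),
                 n = n, fitted = unname(pred)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<%s fit: R^2 = %.3f, RMSE = %.3f g/L, n = %d>\n",
              x$family, x$r_squared, x$rmse, x$n))
  invisible(x)
}

#' Correlation and regression screening tables
#'
#' Reproduces the screening stage of the analysis: for every feature column
#' of a feature table, the Pearson correlation with petiole nitrate (with a
#' p < 0.01 significance flag), and the three single-feature regression
#' fits with their R-squared and RMSE. A family that fails to fit records a
#' missing row rather than aborting.
#'
#' @param ft a feature table from [feature_table()] (>= 10 rows).
#' @return list of data frames: `trilateral_cor` (6 rows), `vi_cor` (12
#'   rows: six indices on each basis), `trilateral_fits` (18 rows),
#'   `vi_fits` (36 rows).
#' @export
screening_tables <- function(ft) {
  if (nrow(ft) < 10) stop("need at least 10 samples to screen", call. = FALSE)
  tri_feats <- c("Dr", "SDr", "Dy", "SDy", "Db", "SDb")
  vi_feats <- c(paste0(c("RD", "CI_red_edge", "NDRE", "ND705", "NIR",
                         "RI_1dB"), "_orig"),
                paste0(c("RD", "CI_red_edge", "NDRE", "ND705", "NIR",
                         "RI_1dB"), "_d1"))
  cor_table <- function(feats) {
    do.call(rbind, lapply(feats, function(f) {
      pr <- pearson_r(ft[[f]], ft$no3n)
      data.frame(feature = f, r = pr$r, p_value = pr$p_value,
                 significant = pr$significant, stringsAsFactors = FALSE)
    }))
  }
  fit_table <- function(feats) {
    do.call(rbind, lapply(feats, function(f) {
      do.call(rbind, lapply(c("linear", "exponential", "quadratic"),
                            function(fam) {
        fit <- tryCatch(fit_regression(ft[[f]], ft$no3n, fam),
                        error = function(e) NULL)
        if (is.null(fit)) {
          data.frame(feature = f, family = fam, a = NA_real_, b = NA_real_,
                     c = NA_real_, r_squared = NA_real_, rmse = NA_real_,
                     stringsAsFactors = FALSE)
        } else {
          co <- fit$coefficients
          data.frame(feature = f, family = fam,
                     a = co[["a"]], b = co[["b"]],
                     c = if ("c" %in% names(co)) co[["c"]] else NA_real_,
                     r_squared = fit$r_squared, rmse = fit$rmse,
                     stringsAsFactors = FALSE)
        }
      }))
    }))
  }
  list(trilateral_cor = cor_table(tri_feats),
       vi_cor = cor_table(vi_feats),
       trilateral_fits = fit_table(tri_feats),
       vi_fits = fit_table(vi_feats))
}
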