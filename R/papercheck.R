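#' Published fit statistics
#'
#' The fit statistics the source study printed for its screening and model
#' comparison (single-feature regression R-squared/RMSE values, correlation
#' coefficients, and per-model R-squared/RMSE/MAE on the modeling and
#' validation splits). These are the inputs to the published percent-change
#' arithmetic; the study's raw field data were not deposited, so the values
#' themselves are not recomputable here.
#'
#' @return data frame with `key`, `value`, `description`.
#' @export
published_values <- function() {
  utils::read.csv(system.file("extdata", "published_values.csv",
                              package = "nitraspec"),
                  stringsAsFactors = FALSE)
}

#' Published percent-change claims
#'
#' Every "increased by x% / reduced by y%" sentence of the study's results,
#' expressed as a [percent_change()] call over two published fit
#' statistics: which statistic is `new`, which is `old`, the direction,
#' whether magnitudes are compared (for negative correlations), and the
#' printed percentage. Claims whose printed percentage cannot be obtained
#' from any printed statistics (evidently computed upstream from unrounded
#' metrics) are flagged `reproducible = FALSE`.
#'
#' @return data frame of claims.
#' @export
published_claims <- function() {
  utils::read.csv(system.file("extdata", "published_claims.csv",
                              package = "nitraspec"),
                  stringsAsFactors = FALSE)
}

#' Recompute the published percent-change arithmetic
#'
#' For every published claim, recomputes the percentage from the published
#' fit statistics via [percent_change()] and compares it with the printed
#' figure at the given tolerance (in percentage points, on the unrounded
#' recomputed value).
#'
#' @param tol match tolerance in percentage points (default 0.05).
#' @return data frame: claim id, inputs, `printed`, `recomputed`,
#'   `recomputed_rounded` (half-up, 1 decimal), `matches`, `reproducible`.
#' @export
recompute_published_changes <- function(tol = 0.05) {
  vals <- published_values()
  lookup <- stats::setNames(vals$value, vals$key)
  claims <- published_claims()
  rec <- mapply(function(nk, ok, dir, ab) {
    new <- lookup[[nk]]
    old <- lookup[[ok]]
    if (ab) {
      new <- abs(new)
      old <- abs(old)
    }
    percent_change(new, old, dir)
  }, claims$new_key, claims$old_key, claims$direction, claims$use_abs)
  claims$recomputed <- unname(rec)
  claims$recomputed_rounded <- round_half_up(claims$recomputed, 1)
  claims$matches <- abs(claims$recomputed - claims$printed_percent) <=
    tol + 1e-9
  claims[c("claim_id", "new_key", "old_key", "direction", "use_abs",
           "printed_percent", "recomputed", "recomputed_rounded",
           "matches", "reproducible", "note")]
}

#' Summary check of the published arithmetic
#'
#' Convenience wrapper around [recompute_published_changes()] reporting the
#' number of claims that reproduce, and whether every claim flagged
#' reproducible actually matched.
#'
#' @param tol match tolerance in percentage points (default 0.05).
#' @return list with `table`, `n_claims`, `n_matching`, `all_reproducible_match`.
#' @export
check_published_arithmetic <- function(tol = 0.05) {
  tab <- recompute_published_changes(tol)
  list(table = tab,
       n_claims = nrow(tab),
       n_matching = sum(tab$matches),
       all_reproducible_match = all(tab$matches[tab$reproducible]))
}
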