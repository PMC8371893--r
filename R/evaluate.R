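#' Prediction accuracy metrics
#'
#' The four metrics used throughout the comparison, for predicted values F
#' against true values T (both g/L):
#' \describe{
#'   \item{r_squared}{1 - sum((F - T)^2) / sum((T - mean(T))^2)}
#'   \item{rmse}{sqrt(mean((F - T)^2)), g/L}
#'   \item{mae}{mean(|F - T|), g/L}
#'   \item{mre}{sqrt(mean(((F - T) / T)^2)) * 100, percent -- the
#'     root-mean-square relative error used for hidden-node selection}
#' }
#' R-squared is undefined (error) when T has zero variance; MRE is
#' undefined when any T is 0.
#'
#' @param f predicted values (g/L).
#' @param t true values (g/L), same length, n >= 1 (n >= 2 for R-squared).
#' @return list with `r_squared`, `rmse`, `mae`, `mre`, `n`.
#' @export
eval_metrics <- function(f, t) {
  if (length(f) != length(t)) stop("length mismatch", call. = FALSE)
  n <- length(t)
  if (n < 1) stop("empty prediction pair", call. = FALSE)
  sstot <- sum((t - mean(t))^2)
  r2 <- if (n >= 2 && sstot > 0) 1 - sum((f - t)^2) / sstot else NA_real_
  mre <- if (any(t == 0)) NA_real_ else sqrt(mean(((f - t) / t)^2)) * 100
  list(r_squared = r2,
       rmse = sqrt(mean((f - t)^2)),
       mae = mean(abs(f - t)),
       mre = mre,
       n = n)
}

#' Percent change between two metric values
#'
#' The arithmetic behind every "increased by x%" / "reduced by y%" sentence
#' of the comparison: increase = (new/old - 1) * 100, reduction =
#' (1 - new/old) * 100. Values are kept at full precision; use
#' [round_half_up()] for 1-decimal presentation.
#'
#' @param new,old metric values; `old` must be positive.
#' @param direction `"increase"` or `"reduction"`.
#' @return percent change (full precision).
#' @export
percent_change <- function(new, old, direction = c("increase", "reduction")) {
  direction <- match.arg(direction)
  if (!is.finite(old) || old <= 0)
    stop("`old` must be a positive number", call. = FALSE)
  if (direction == "increase") (new / old - 1) * 100 else (1 - new / old) * 100
}

#' Round half away from zero
#'
#' Presentation rounding for reported percentages (R's [round()] rounds
#' half to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded value.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Default comparison feature sets
#'
#' The two predictor sets carried into the model comparison: the blue-edge
#' trilateral parameters (Db, SDb) and the two first-derivative vegetation
#' indices (ND705, CI red edge).
#'
#' @return named list of feature-column vectors.
#' @export
comparison_feature_sets <- function() {
  list(blue_edge = c("Db", "SDb"),
       d1_vi = c("ND705_d1", "CI_red_edge_d1"))
}

#' Model comparison report
#'
#' Trains the four model families (WNN, RF, RBF, BP) on the modeling
#' feature table for each feature set, evaluates them on the modeling and
#' validation sets, and derives the pairwise percent changes: WNN's
#' blue-edge model against its first-derivative-index model per split, WNN
#' against each baseline per feature set on validation, and each baseline's
#' blue-edge model against its index model on validation.
#'
#' @param modeling,validation feature tables from [feature_table()].
#' @param feature_sets named list of feature-column vectors (default
#'   [comparison_feature_sets()]).
#' @param cfg a [train_config()]; its seed also seeds RF.
#' @param n_hidden hidden nodes for WNN and BP (default 10).
#' @return list with `metrics` (data frame: model, feature_set, split,
#'   r_squared, rmse, mae, n), `percent_changes` (data frame: comparison,
#'   metric, value), and `models` (nested list of trained models). A model
#'   family that fails records missing metric cells rather than aborting.
#' @export
comparison_report <- function(modeling, validation,
                              feature_sets = comparison_feature_sets(),
                              cfg = train_config(), n_hidden = 10) {
  trainers <- list(
    WNN = function(X, Y) train_wnn(X, Y, n_hidden = n_hidden, cfg = cfg),
    RF  = function(X, Y) train_rf(X, Y, seed = cfg$seed),
    RBF = function(X, Y) train_rbf(X, Y),
    BP  = function(X, Y) train_bp(X, Y, n_hidden = n_hidden, cfg = cfg)
  )
  rows <- list()
  models <- list()
  for (fs in names(feature_sets)) {
    cols <- feature_sets[[fs]]
    missing_cols <- setdiff(cols, names(modeling))
    if (length(missing_cols))
      stop("feature set `", fs, "` needs column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    Xm <- as.matrix(modeling[cols]); Ym <- modeling$no3n
    Xv <- as.matrix(validation[cols]); Yv <- validation$no3n
    for (mod in names(trainers)) {
      fit <- tryCatch(trainers[[mod]](Xm, Ym), error = function(e) NULL)
      models[[fs]][[mod]] <- fit
      for (split in c("modeling", "validation")) {
        if (is.null(fit)) {
          met <- list(r_squared = NA_real_, rmse = NA_real_,
                      mae = NA_real_, n = NA_integer_)
        } else {
          X <- if (split == "modeling") Xm else Xv
          Y <- if (split == "modeling") Ym else Yv
          met <- eval_metrics(predict(fit, X), Y)
        }
        rows[[length(rows) + 1]] <- data.frame(
          model = mod, feature_set = fs, split = split,
          r_squared = met$r_squared, rmse = met$rmse, mae = met$mae,
          n = met$n, stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  list(metrics = metrics,
       percent_changes = report_percent_changes(metrics),
       models = models)
}

# the pairwise percent-change entries derived from a comparison metric grid
report_percent_changes <- function(metrics) {
  cell <- function(model, fs, split, metric) {
    v <- metrics[metrics$model == model & metrics$feature_set == fs &
                   metrics$split == split, metric]
    if (length(v) != 1) NA_real_ else v
  }
  out <- list()
  add <- function(comparison, metric, new, old, direction) {
    val <- if (is.na(new) || is.na(old) || old <= 0) NA_real_
           else percent_change(new, old, direction)
    out[[length(out) + 1]] <<- data.frame(
      comparison = comparison, metric = metric, direction = direction,
      percent = val, stringsAsFactors = FALSE)
  }
  fsets <- unique(metrics$feature_set)
  if (all(c("blue_edge", "d1_vi") %in% fsets)) {
    for (split in c("modeling", "validation")) {
      for (mod in unique(metrics$model)) {
        tag <- sprintf("%s_blue_edge_vs_d1_vi_%s", mod, split)
        add(tag, "r_squared",
            cell(mod, "blue_edge", split, "r_squared"),
            cell(mod, "d1_vi", split, "r_squared"), "increase")
        for (m in c("rmse", "mae"))
          add(tag, m, cell(mod, "blue_edge", split, m),
              cell(mod, "d1_vi", split, m), "reduction")
      }
    }
  }
  for (fs in fsets) {
    for (base in setdiff(unique(metrics$model), "WNN")) {
      tag <- sprintf("WNN_vs_%s_%s_validation", base, fs)
      add(tag, "r_squared",
          cell("WNN", fs, "validation", "r_squared"),
          cell(base, fs, "validation", "r_squared"), "increase")
      for (m in c("rmse", "mae"))
        add(tag, m, cell("WNN", fs, "validation", m),
            cell(base, fs, "validation", m), "reduction")
    }
  }
  do.call(rbind, out)
}

#' Write an evaluation report
#'
#' Emits the comparison grid as CSV and the full report (grid plus percent
#' changes) as a JSON document keyed by model, feature set, and split.
#'
#' @param report result of [comparison_report()].
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write_table(report$metrics, csv_path)
  if (!is.null(json_path)) {
    doc <- list(metrics = report$metrics,
                percent_changes = report$percent_changes)
    jsonlite::write_json(doc, json_path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  }
  invisible(report)
}
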