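test_that("metrics follow their closed forms", {
  t <- c(1, 2, 3, 4, 5)
  m <- eval_metrics(t, t)
  expect_equal(m$r_squared, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  expect_equal(m$mre, 0)

  off <- eval_metrics(t + 1, t)
  expect_equal(off$mae, 1)
  expect_equal(off$rmse, 1)

  single <- eval_metrics(1.1, 1.0)
  expect_equal(single$mre, 10, tolerance = 1e-12)

  # mean-predicting model scores exactly zero
  expect_equal(eval_metrics(rep(mean(t), 5), t)$r_squared, 0)

  # direct-formula recomputation on random pairs
  set.seed(67)
  f <- runif(30, 1, 10); tt <- runif(30, 1, 10)
  m2 <- eval_metrics(f, tt)
  expect_equal(m2$r_squared,
               1 - sum((f - tt)^2) / sum((tt - mean(tt))^2),
               tolerance = 1e-12)
  expect_equal(m2$rmse, sqrt(sum((f - tt)^2) / 30), tolerance = 1e-12)
  expect_equal(m2$mae, sum(abs(f - tt)) / 30, tolerance = 1e-12)
  expect_equal(m2$mre, sqrt(mean(((f - tt) / tt)^2)) * 100,
               tolerance = 1e-12)
})

test_that("MAE never exceeds RMSE and degenerate cases are flagged", {
  set.seed(71)
  for (i in 1:20) {
    f <- rnorm(15, 5); t <- rnorm(15, 5)
    m <- eval_metrics(f, t)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
  expect_true(is.na(eval_metrics(c(1, 2), c(3, 3))$r_squared))
  expect_true(is.na(eval_metrics(c(1, 2), c(0, 1))$mre))
})

test_that("percent change reproduces the published screening arithmetic", {
  expect_equal(round_half_up(percent_change(0.80, 0.64, "increase")), 25.0)
  expect_equal(round_half_up(percent_change(0.92, 1.69, "reduction")), 45.6)
  expect_equal(percent_change(3, 3, "increase"), 0)
  expect_equal(percent_change(3, 3, "reduction"), 0)
  expect_error(percent_change(1, 0, "increase"), "positive")
  # presentation rounding is half away from zero
  expect_equal(round_half_up(18.75), 18.8)
  expect_equal(round_half_up(-18.75), -18.8)
})

test_that("comparison report fills the full grid and is self-consistent", {
  ft <- synthetic_feature_tables(small_sim())
  rep <- comparison_report(ft$modeling, ft$validation,
                           cfg = train_config(seed = 1, max_iterations = 200))
  expect_equal(nrow(rep$metrics), 4 * 2 * 2)  # 4 models x 2 sets x 2 splits
  val <- rep$metrics[rep$metrics$split == "validation", ]
  expect_false(any(is.na(val$rmse)))

  # percent-change entries recomputed independently from the grid
  pc <- rep$percent_changes
  g <- rep$metrics
  pick <- function(model, fs, split, metric)
    g[g$model == model & g$feature_set == fs & g$split == split, metric]
  row <- pc[pc$comparison == "WNN_vs_BP_blue_edge_validation" &
              pc$metric == "rmse", ]
  expect_equal(row$percent,
               (1 - pick("WNN", "blue_edge", "validation", "rmse") /
                  pick("BP", "blue_edge", "validation", "rmse")) * 100,
               tolerance = 1e-12)
  row2 <- pc[pc$comparison == "WNN_blue_edge_vs_d1_vi_modeling" &
               pc$metric == "r_squared", ]
  expect_equal(row2$percent,
               (pick("WNN", "blue_edge", "modeling", "r_squared") /
                  pick("WNN", "d1_vi", "modeling", "r_squared") - 1) * 100,
               tolerance = 1e-12)

  # report writing round-trips the grid
  fcsv <- withr::local_tempfile(fileext = ".csv")
  fjson <- withr::local_tempfile(fileext = ".json")
  write_report(rep, fcsv, fjson)
  back <- read.csv(fcsv, stringsAsFactors = FALSE)
  expect_equal(back$rmse, rep$metrics$rmse, tolerance = 1e-12)
  doc <- jsonlite::read_json(fjson, simplifyVector = TRUE)
  expect_equal(doc$metrics$rmse, rep$metrics$rmse, tolerance = 1e-12)
})
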