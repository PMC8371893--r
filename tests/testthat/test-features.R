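test_that("trilateral parameters vanish on a flat spectrum", {
  tri <- trilateral_params(first_derivative(flat_spectra()))
  expect_equal(unlist(tri[1, -1]), c(Dr = 0, SDr = 0, Dy = 0, SDy = 0,
                                     Db = 0, SDb = 0))
})

test_that("trilateral parameters match constructed-spectrum oracles", {
  # slope 0.002/nm exactly on the red edge window
  red <- edge_ramp_spectra(0.002, 680, 760)
  tri <- trilateral_params(first_derivative(red))
  expect_equal(tri$Dr, 0.002, tolerance = 1e-12)
  expect_equal(tri$SDr, 0.16, tolerance = 1e-12)  # R(760) - R(680)

  # slope 0.0005/nm on the blue edge window only
  blue <- edge_ramp_spectra(0.0005, 490, 530)
  tb <- trilateral_params(first_derivative(blue))
  expect_equal(tb$Db, 0.0005, tolerance = 1e-12)
  expect_equal(tb$SDb, 0.02, tolerance = 1e-12)
  expect_equal(tb$Dr, 0, tolerance = 1e-15)
  expect_equal(tb$Dy, 0, tolerance = 1e-15)
  expect_equal(tb$SDr, 0, tolerance = 1e-15)
  expect_equal(tb$SDy, 0, tolerance = 1e-15)
})

test_that("edge areas equal reflectance differences on random spectra", {
  s <- random_spectra(n = 100, seed = 21)
  tri <- trilateral_params(first_derivative(s))
  win <- edge_windows()
  at <- function(l) s$values[, match(l, s$wavelengths)]
  expect_equal(tri$SDr, at(win$red[2]) - at(win$red[1]), tolerance = 1e-10)
  expect_equal(tri$SDy, at(win$yellow[2]) - at(win$yellow[1]),
               tolerance = 1e-10)
  expect_equal(tri$SDb, at(win$blue[2]) - at(win$blue[1]), tolerance = 1e-10)
})

test_that("yellow extremum convention is configurable", {
  # descending curve on the yellow window: all derivatives negative there
  wl <- grid_350_1075
  vals <- 0.5 - 0.002 * pmin(pmax(wl - 560, 0), 120) -
    1e-5 * pmin(pmax(wl - 560, 0), 120)^2 / 80
  s <- spectra(matrix(vals, 1), wl, "reflectance")
  d <- first_derivative(s)
  signed <- trilateral_params(d, yellow_extremum = "max")$Dy
  absmax <- trilateral_params(d, yellow_extremum = "abs_max")$Dy
  expect_lt(signed, 0)
  expect_lt(absmax, signed)  # abs_max picks the steepest (most negative)
})

test_that("vegetation indices follow their closed forms and flag zero denominators", {
  wl <- grid_350_1075
  vals <- rep(0.5, length(wl))
  vals[match(740, wl)] <- 0.45
  vals[match(720, wl)] <- 0.30
  vals[match(780, wl)] <- 0.50
  vals[match(710, wl)] <- 0.50
  vals[match(790, wl)] <- 0.30  # equal to V720
  s <- spectra(matrix(vals, 1), wl, "reflectance")
  vi <- vegetation_indices(s, "original")
  expect_equal(vi$RD, 1.5)
  expect_equal(vi$CI_red_edge, 0)       # V780 == V710
  expect_equal(vi$NDRE, 0)              # V790 == V720
  expect_equal(vi$NIR, 0.5 / 0.45)
  expect_equal(vi$RI_1dB, 0.5 / 0.30)

  # a zero denominator flags only that index
  zvals <- vals
  zvals[match(720, wl)] <- 0
  zvals[match(790, wl)] <- 0
  z <- spectra(matrix(zvals, 1), wl, "reflectance")
  vz <- vegetation_indices(z, "original")
  expect_true(is.na(vz$RD))
  expect_true(is.na(vz$NDRE))           # V790 + V720 == 0
  expect_false(is.na(vz$ND705))
})

test_that("derivative-basis indices equal the formulas on the derivative curve", {
  s <- random_spectra(n = 4, seed = 31)
  vd <- vegetation_indices(s, "first_derivative")
  d <- first_derivative(s, "forward")
  Vd <- function(l) d$values[, match(l, d$wavelengths)]
  expect_equal(vd$RD, Vd(740) / Vd(720), tolerance = 1e-12)
  expect_equal(vd$ND705, (Vd(750) - Vd(705)) / (Vd(750) + Vd(705)),
               tolerance = 1e-12)
})

test_that("reflectance-basis normalized-difference indices stay within [-1, 1]", {
  s <- random_spectra(n = 50, seed = 41)
  vi <- vegetation_indices(s, "original")
  expect_true(all(abs(vi$NDRE) <= 1))
  expect_true(all(abs(vi$ND705) <= 1))
  expect_true(all(vi$RD > 0 & vi$NIR > 0 & vi$RI_1dB > 0))
})

test_that("feature table has the fixed layout and validates the join", {
  ft <- synthetic_feature_tables(small_sim())
  expect_equal(names(ft$modeling)[1:7],
               c("sample_id", "Dr", "SDr", "Dy", "SDy", "Db", "SDb"))
  expect_equal(names(ft$modeling)[20], "no3n")
  expect_equal(ncol(ft$modeling), 20)
  expect_true(all(stats::complete.cases(ft$modeling)))

  ds <- generate_dataset(small_sim())
  avg <- average_scans(ds$modeling$spectra)
  bad_targets <- ds$modeling$targets[-1, ]
  expect_error(feature_table(avg, bad_targets),
               ds$modeling$targets$sample_id[1])
})

test_that("feature extraction ignores wavelengths outside all windows and bands", {
  s <- random_spectra(n = 3, seed = 55)
  wl <- s$wavelengths
  keep <- wl >= 480 & wl <= 800
  trimmed <- spectra(s$values[, keep], wl[keep], "reflectance", s$meta)
  tri_full <- trilateral_params(first_derivative(s))
  tri_trim <- trilateral_params(first_derivative(trimmed))
  expect_equal(tri_trim, tri_full, tolerance = 1e-12)
  expect_equal(vegetation_indices(trimmed, "original"),
               vegetation_indices(s, "original"), tolerance = 1e-12)
})
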