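test_that("density calibration round-trips and scales correctly", {
  tt <- make_titration_table(c(0.001, 0.002, 0.005, 0.01), A_true = 0.4)
  expect_equal(calibrate_A(tt$slb), 0.4, tolerance = 1e-9)
  # doubling all intensities halves A
  dbl <- tt$slb; dbl$intensity <- 2 * dbl$intensity
  expect_equal(calibrate_A(dbl), 0.2, tolerance = 1e-9)
  expect_error(calibrate_A(data.frame(fraction = 0.01, intensity = 5)),
               "2 nonzero")
  # Monte-Carlo recovery with 5% relative noise across 60 seeds
  rec <- vapply(1:60, function(s) {
    t <- make_titration_table(seq(0.002, 0.012, by = 0.002), A_true = 0.4,
                              noise_sd = 0.05, seed = s)
    calibrate_A(t$slb)
  }, 0)
  expect_lt(max(abs(rec - 0.4)) / 0.4, 0.10)
})

test_that("the combined prefactor assembles A, dye ratio and labeling", {
  tt <- make_titration_table(c(0.002, 0.005), A_true = 0.5, ratio_true = 1.8)
  expect_equal(calibrate_dye_ratio(tt$dye), 1.8, tolerance = 1e-9)
  cal <- calibration_result(A = 0.5, dye_ratio = 1.8, Z = 1)
  expect_equal(cal$combined_prefactor, 0.5 / 1.8, tolerance = 1e-12)
  # doubling the degree of labeling halves the converted density
  cal2 <- calibration_result(A = 0.5, dye_ratio = 1.8, Z = 2)
  expect_equal(density_from_intensity(100, cal2),
               density_from_intensity(100, cal) / 2)
  expect_equal(density_from_intensity(0, cal), 0)
  # the bundled reference calibration converts the reference bed density
  ref <- reference_calibration()
  expect_equal(ref$combined_prefactor, 0.278)
  expect_equal(density_from_intensity(28777, ref), 8000, tolerance = 1)
})

test_that("recovery normalization averages replicates on a common base", {
  crv <- make_frap_curve(1, 1, n_points = 30)
  expect_equal(normalize_recovery(crv), crv)
  five <- replicate(5, crv, simplify = FALSE)
  expect_equal(normalize_recovery(five), crv)
  # averaging five noisy replicates shrinks the pointwise sd ~ sqrt(5)
  noisy <- lapply(1:5, function(s)
    make_frap_curve(1, 1, n_points = 200, noise_sd = 0.05, seed = s))
  avg <- normalize_recovery(noisy)
  clean <- make_frap_curve(1, 1, n_points = 200)
  resid1 <- noisy[[1]]$I - clean$I
  residm <- avg$I - clean$I
  expect_equal(sd(residm) * sqrt(5), sd(resid1), tolerance = 0.35)
  bad <- make_frap_curve(1, 1, n_points = 31)
  expect_error(normalize_recovery(list(crv, bad)), "time base")
})

test_that("exponential recovery fitting is exact on noiseless curves", {
  t <- seq(0, 12, by = 0.1)
  curve <- data.frame(t = t, I = 1 - 0.5 * exp(-t / 2))
  f <- fit_recovery(curve)
  expect_equal(f$tau, 2, tolerance = 1e-6)
  expect_equal(f$tau_half, 2 * log(2), tolerance = 1e-6)
  expect_equal(f$plateau, 1, tolerance = 1e-6)
  # the generator's D is recovered through the fitted half-time
  crv <- make_frap_curve(D = 0.224, r = 1, n_points = 100)
  expect_equal(fit_recovery(crv)$tau_half, 1, tolerance = 1e-6)
  flat <- data.frame(t = t, I = rep(0.8, length(t)))
  expect_error(fit_recovery(flat), "flat")
})

test_that("the Soumpasis relation and its round trip hold across D", {
  expect_equal(soumpasis_D(1, 1), 0.224)
  expect_equal(soumpasis_D(2, 1), 4 * soumpasis_D(1, 1))
  expect_equal(soumpasis_D(0.5, 0.224), 0.25)
  expect_error(soumpasis_D(0, 1), "> 0")
  for (D in c(0.1, 0.5, 1, 2, 5)) {
    f <- fit_recovery(make_frap_curve(D, r = 1, n_points = 100))
    expect_equal(soumpasis_D(1, f$tau_half), D, tolerance = 0.01 * D)
  }
})

test_that("the Einstein bridge converts mobility to anchor drag", {
  expect_equal(anchor_drag_from_D(1, kBT = 4.1), 4.1e-6)
  expect_equal(anchor_drag_from_D(0.5), 2 * anchor_drag_from_D(1))
  expect_lt(anchor_drag_from_D(1e6), 1e-11)
  expect_error(anchor_drag_from_D(0), "> 0")
})
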