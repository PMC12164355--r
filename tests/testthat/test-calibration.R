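test_that("noise-free sigmoid data are recovered to 4 significant digits", {
  d <- generateCalibrationSet(noise_sd = 0)
  cal <- fitSigmoid(d$sp, d$lambda_iso)
  truth <- attr(d, "truth")
  for (nm in names(cal$par))
    expect_equal(signif(cal$par[[nm]], 4), signif(truth[[nm]], 4))
  # midpoint property
  expect_equal(predict(cal, cal$par[["x0"]]),
               (cal$par[["lambda_A"]] + cal$par[["lambda_B"]]) / 2)
})

test_that("forward-inverse round trip is exact to 1e-10", {
  d <- generateCalibrationSet(noise_sd = 0)
  cal <- fitSigmoid(d$sp, d$lambda_iso)
  for (sp in c(0.1, 0.45, 0.7, 1.1, 1.5)) {
    lam <- predict(cal, sp)
    expect_lt(abs(invertSigmoid(lam, cal)$sp - sp), 1e-10)
  }
  expect_equal(invertSigmoid((cal$par[["lambda_A"]] +
                                cal$par[["lambda_B"]]) / 2, cal)$sp,
               cal$par[["x0"]], tolerance = 1e-10)
})

test_that("out-of-calibration wavelengths raise, never clamp", {
  d <- generateCalibrationSet(noise_sd = 0)
  cal <- fitSigmoid(d$sp, d$lambda_iso)
  expect_error(invertSigmoid(cal$par[["lambda_A"]] + 1, cal),
               "outside the open calibration interval")
  expect_error(invertSigmoid(cal$par[["lambda_B"]], cal), "outside")
})

test_that("noisy fits stay within propagated uncertainties", {
  d <- generateCalibrationSet(noise_sd = 0.3, seed = 7)
  cal <- fitSigmoid(d$sp, d$lambda_iso)
  truth <- attr(d, "truth")
  se <- sqrt(diag(cal$cov))
  expect_lt(abs(cal$par[["x0"]] - truth$x0), 3 * se[["x0"]])
})

test_that("one-flank data yield an ill-conditioned inflection", {
  full <- generateCalibrationSet(noise_sd = 0.05, seed = 3)
  calf <- fitSigmoid(full$sp, full$lambda_iso)
  clip <- generateCalibrationSet(noise_sd = 0.05, seed = 3,
                                 sp = seq(0.9, 1.6, length.out = 12))
  calc <- tryCatch(fitSigmoid(clip$sp, clip$lambda_iso),
                   error = function(e) NULL)
  if (is.null(calc)) succeed("clipped fit refused outright")
  else expect_gt(sqrt(calc$cov[["x0", "x0"]]),
                 5 * sqrt(calf$cov[["x0", "x0"]]))
})

test_that("stiffness calibration inverts the reported endpoints", {
  st <- c(0.006, 0.012, 0.018, 0.031)
  li <- c(537, 532, 529, 527)
  cal <- fitStiffnessMap(st, li)
  inv <- invertStiffness(536.99, cal)
  expect_equal(inv$stiffness, 0.006, tolerance = 0.1)
  # round trip on the fitted curve
  lam <- predict(cal, 0.015)
  expect_lt(abs(invertStiffness(lam, cal)$stiffness - 0.015), 1e-10)
  expect_error(fitStiffnessMap(st, rev(li)), "monotonically")
})

test_that("stiffness recovery has near-nominal Monte-Carlo coverage", {
  truth <- list(lambda_A = 538, lambda_B = 526.5, x0 = 0.012, k = 0.004)
  stg <- seq(0.004, 0.034, length.out = 10)
  lam0 <- (truth$lambda_A - truth$lambda_B) /
    (1 + exp((stg - truth$x0) / truth$k)) + truth$lambda_B
  target <- 0.015
  true_lam <- (truth$lambda_A - truth$lambda_B) /
    (1 + exp((target - truth$x0) / truth$k)) + truth$lambda_B
  set.seed(11)
  hits <- 0; n_ok <- 0
  for (rep in seq_len(200)) {
    cal <- tryCatch(
      fitStiffnessMap(stg, lam0 + rnorm(length(stg), sd = 0.5)),
      error = function(e) NULL)
    if (is.null(cal)) next
    inv <- tryCatch(invertStiffness(true_lam, cal, sigma_lambda = 0.5),
                    error = function(e) NULL)
    if (is.null(inv) || !is.finite(inv$sd) || inv$sd == 0) next
    n_ok <- n_ok + 1
    if (abs(inv$stiffness - target) <= 1.96 * inv$sd) hits <- hits + 1
  }
  expect_gt(n_ok, 150)
  expect_gte(hits / n_ok, 0.9)
})

test_that("calibrations round-trip through key/value text", {
  d <- generateCalibrationSet(noise_sd = 0.1, seed = 2)
  cal <- fitSigmoid(d$sp, d$lambda_iso)
  tf <- tempfile(fileext = ".cal")
  on.exit(unlink(tf))
  writeCalibration(cal, tf)
  cal2 <- readCalibration(tf)
  expect_equal(cal2$par, cal$par, tolerance = 1e-10)
  expect_equal(cal2$cov, cal$cov, tolerance = 1e-8)
  expect_equal(invertSigmoid(531, cal2)$sp, invertSigmoid(531, cal)$sp)
})
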