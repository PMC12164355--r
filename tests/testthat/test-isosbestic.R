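grid <- seq(400, 800, by = 1)

twoBand <- function() {
  A <- Spectrum(grid, lorentz(grid, 524, 30), "absorbance")
  B <- Spectrum(grid, 0.6 * lorentz(grid, 524, 30) +
                  0.4 * lorentz(grid, 609, 50), "absorbance")
  list(A = A, B = B)
}

test_that("mixtures interpolate their endpoints pointwise", {
  eb <- twoBand()
  expect_equal(mixtureSpectrum(0, eb$B, eb$A)$value, eb$A$value)
  expect_equal(mixtureSpectrum(1, eb$B, eb$A)$value, eb$B$value)
  expect_equal(mixtureSpectrum(0.5, eb$B, eb$A)$value,
               (eb$A$value + eb$B$value) / 2)
  expect_error(mixtureSpectrum(1.2, eb$B, eb$A), "\\[0, 1\\]")
  s2 <- Spectrum(grid + 1, eb$A$value, "absorbance")
  expect_error(mixtureSpectrum(0.5, s2, eb$A), "grid")
})

test_that("crossing location matches a 0.01-nm brute-force oracle", {
  eb <- twoBand()
  r <- findIsosbestic(eb$A, eb$B)
  dense <- seq(450, 650, 0.01)
  d <- lorentz(dense, 524, 30) -
    (0.6 * lorentz(dense, 524, 30) + 0.4 * lorentz(dense, 609, 50))
  sgn <- which(d[-1] * d[-length(d)] < 0)
  oracle <- dense[sgn[which.min(abs(dense[sgn] - 524))]]
  expect_true(r$present)
  expect_equal(r$lambda_iso, oracle, tolerance = 0.2)
})

test_that("offset and identical spectra are handled distinctly", {
  eb <- twoBand()
  up <- Spectrum(grid, eb$A$value + 0.3, "absorbance")
  r <- findIsosbestic(up, eb$A)
  expect_false(r$present)
  expect_true(is.na(r$lambda_iso))
  expect_error(findIsosbestic(eb$A, eb$A), "degenerate")
})

test_that("every convex mixture passes through the crossing exactly", {
  eb <- twoBand()
  lam0 <- findIsosbestic(eb$A, eb$B)$lambda_iso
  lam <- stats::uniroot(function(x) lorentz(x, 524, 30) -
                          (0.6 * lorentz(x, 524, 30) +
                             0.4 * lorentz(x, 609, 50)),
                        lam0 + c(-2, 2), tol = 1e-14)$root
  valA <- lorentz(lam, 524, 30)
  for (f in seq(0.1, 0.9, 0.2)) {
    mixval <- f * (0.6 * lorentz(lam, 524, 30) +
                     0.4 * lorentz(lam, 609, 50)) + (1 - f) * valA
    expect_equal(mixval, valA, tolerance = 1e-12)
  }
  # and all pairwise crossings coincide within grid tolerance
  fam <- lapply(seq(0, 1, 0.25), mixtureSpectrum, coupled = eb$B,
                uncoupled = eb$A)
  res <- isosbesticFromFamily(fam)
  expect_true(res$is_isosbestic)
  expect_lt(res$dispersion, 1e-6)
})

test_that("drifting endpoints destroy the family isosbestic", {
  fam <- lapply(seq_len(5), function(i) {
    red <- 560 + 15 * i  # coupled band drifts red with concentration
    Spectrum(grid, 0.5 * lorentz(grid, 524, 30) +
               0.5 * lorentz(grid, red, 50), "absorbance")
  })
  res <- isosbesticFromFamily(fam)
  expect_false(res$is_isosbestic)
  expect_gt(res$dispersion, 1.5)
  expect_error(isosbesticFromFamily(fam[1:2]), "at least 3")
})

test_that("parametric sweep is monotone and inverts to sub-nm spacings", {
  sw <- isosbesticSweep(seq(0.2, 1.6, 0.2))
  expect_true(all(sw$present))
  expect_true(all(diff(sw$lambda_iso) < 0))
  cal <- fitSigmoid(sw$sp, sw$lambda_iso)
  sp531 <- invertSigmoid(531, cal, sigma_lambda = 1)
  sp529 <- invertSigmoid(529, cal, sigma_lambda = 1)
  expect_gt(sp531$sp, 0.3); expect_lt(sp531$sp, 1)
  expect_gt(sp529$sp, sp531$sp)  # strict monotone inversion
  expect_lt(sp529$sp, 1)
})

test_that("solver endpoints lose the crossing at large spacings", {
  sw <- suppressWarnings(
    isosbesticSweep(c(0.6, 4), endpoint = "solver",
                    arrangement = "chain_1d", n_particles = 3,
                    wavelength = seq(420, 780, 2)))
  expect_true(sw$present[sw$sp == 0.6])
  expect_false(sw$present[sw$sp == 4])
})

test_that("aggregation index responds to red-band weight", {
  eb <- twoBand()
  ai_unc <- aggregationIndex(eb$A)
  ai_mix <- aggregationIndex(mixtureSpectrum(0.5, eb$B, eb$A))
  expect_gt(ai_mix, ai_unc)
  flat <- Spectrum(grid, rep(2, length(grid)), "absorbance")
  expect_equal(as.numeric(aggregationIndex(flat)), 1, tolerance = 1e-12)
  # monotone non-decreasing in the coupled fraction (brute force)
  ais <- vapply(seq(0, 1, 0.1), function(f)
    as.numeric(aggregationIndex(mixtureSpectrum(f, eb$B, eb$A))),
    numeric(1))
  expect_true(all(diff(ais) >= 0))
  expect_equal(attr(ai_unc, "definition"), "band_ratio")
  short <- Spectrum(seq(500, 650, 5), rep(1, 31), "absorbance")
  expect_error(aggregationIndex(short), "500-700")
})

test_that("regime classification finds the constructed changeover", {
  sc <- spectralScenario(template_concentrations =
                           seq(6e10, 1.2e12, length.out = 12),
                         noise_sd = 0.001)
  ser <- generateMixtureSeries(sc)
  cls <- classifyConcentrationRegime(ser)
  true_boundary <- max(ser$template_concentration[
    ser$truth$regime == "saturation"])
  expect_equal(cls$boundary, true_boundary)
  # a strictly two-endpoint series is all saturation
  sc2 <- spectralScenario(noise_sd = 0)
  ser2 <- generateMixtureSeries(sc2)
  cls2 <- classifyConcentrationRegime(ser2)
  expect_true(all(cls2$table$regime == "saturation"))
  ser3 <- ser2
  ser3$template_concentration <- rev(ser3$template_concentration)
  expect_error(classifyConcentrationRegime(ser3), "increasing")
})
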