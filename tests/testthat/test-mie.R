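test_that("incident irradiance follows E0^2/(2 Z0)", {
  expect_equal(signif(incidentIrradiance(1e5, 376.73), 3), 1.33e7)
  expect_identical(incidentIrradiance(0), 0)
  expect_equal(incidentIrradiance(2e5) / incidentIrradiance(1e5), 4)
  expect_error(incidentIrradiance(-1), "non-negative")
  expect_error(incidentIrradiance(1, Z0 = 0), "positive")
})

test_that("the 12-nm sphere resonates with a single peak near 521 nm", {
  xs <- mieCrossSections(6, Medium(1.343))
  pk <- peakWavelengths(xs$extinction)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$wavelength, 521.3, tolerance = 0.01)
})

test_that("cross sections are non-negative and extinction is their sum", {
  for (r in c(2, 6, 20, 40)) {
    xs <- mieCrossSections(r, Medium(1.343), seq(400, 800, 10))
    expect_true(all(xs$absorption$value >= 0))
    expect_true(all(xs$scattering$value >= 0))
    expect_equal(xs$extinction$value,
                 xs$absorption$value + xs$scattering$value)
  }
})

test_that("small spheres follow the dipole r^3 / r^6 scaling laws", {
  a3 <- mieCrossSections(3, Medium(1.343), c(695, 700, 705))
  a6 <- mieCrossSections(6, Medium(1.343), c(695, 700, 705))
  expect_equal(a6$absorption$value[2] / a3$absorption$value[2], 8,
               tolerance = 0.1)
  expect_equal(a6$scattering$value[2] / a3$scattering$value[2], 64,
               tolerance = 0.1)
})

test_that("full Mie matches the closed-form dipole limit for r <= 10", {
  for (r in c(3, 6, 10)) {
    grid <- seq(480, 560, 2)
    full <- mieCrossSections(r, Medium(1.343), grid)
    dip <- dipoleCrossSections(r, 1.343, grid)
    ipk <- which.max(full$extinction$value)
    expect_lt(abs(full$extinction$value[ipk] / dip$ext[ipk] - 1), 0.05)
  }
})

test_that("peak finding resolves two separated Lorentzian bands", {
  grid <- seq(400, 800, 1)
  s <- Spectrum(grid, lorentz(grid, 524, 12) + 0.8 * lorentz(grid, 609, 12),
                "absorbance")
  pk <- peakWavelengths(s)
  # dense-grid oracle
  dense <- seq(450, 700, 0.001)
  dv <- lorentz(dense, 524, 12) + 0.8 * lorentz(dense, 609, 12)
  o1 <- dense[dense < 560][which.max(dv[dense < 560])]
  o2 <- dense[dense > 560][which.max(dv[dense > 560])]
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$wavelength, c(o1, o2), tolerance = 0.5)
})

test_that("monotone and flat spectra contain no peaks", {
  grid <- seq(400, 800, 10)
  expect_equal(nrow(peakWavelengths(Spectrum(grid, grid / 800,
                                             "absorbance"))), 0L)
  expect_equal(nrow(peakWavelengths(Spectrum(grid, rep(1, length(grid)),
                                             "absorbance"))), 0L)
  expect_error(peakWavelengths(Spectrum(1:4, 1:4, "absorbance")),
               "at least 5")
})
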