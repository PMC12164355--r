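# Coupled-dipole solver checks against independent electromagnetic limits.

grid2 <- seq(420, 780, by = 4)

test_that("a single dipole reproduces the Mie extinction within 3%", {
  cs <- solveClusterSpectrum(singleSphereGeometry(6), wavelength = grid2)
  mie <- mieCrossSections(6, Medium(1.343), grid2)
  expect_lt(max(abs(cs$extinction$value / mie$extinction$value - 1)), 0.03)
})

test_that("well-separated spheres are additive within 2%", {
  g2p <- buildChainGeometry(60, 6, 2)  # gap = 10 x radius
  cs2 <- solveClusterSpectrum(g2p, wavelength = grid2)
  cs1 <- solveClusterSpectrum(singleSphereGeometry(6), wavelength = grid2)
  expect_lt(max(abs(cs2$extinction$value / (2 * cs1$extinction$value) - 1)),
            0.02)
})

test_that("the radial arrangement is polarization-isotropic", {
  g <- buildRadialGeometry(0.8)
  cs <- suppressWarnings(
    solveClusterSpectrum(g, wavelength = seq(450, 700, 10)))
  pp <- cs$per_polarization$extinction
  expect_lt(max(abs(pp[, "Ex"] / pp[, "Ey"] - 1)), 0.01)
})

test_that("optical theorem agrees with far-field flux integration", {
  med <- Medium(1.343)
  for (n in c(2, 3)) {
    g <- buildChainGeometry(2, 6, n)
    for (lam in c(480, 530, 580)) {
      cs <- solveClusterSpectrum(g, med, c(lam - 1, lam),
                                 solverSettings("Ex"))
      csca_solver <- cs$scattering$value[2]
      csca_ff <- farFieldScattering(g, med, lam)
      expect_lt(abs(csca_ff / csca_solver - 1), 0.02)
    }
  }
})

test_that("spectra are invariant under rigid rotation with polarization", {
  # chain along X with Ex versus chain along Y with Ey
  gx <- buildChainGeometry(1, 6, 3)
  gy <- plasmiso:::newClusterGeometry(
    data.frame(id = 1:3, x = 0, y = gx$x, z = 0, radius = 6,
               subgroup = 1L),
    1, "chain_1d", 6, sp_variants = rep(1, 3), anisotropic = TRUE)
  sx <- solveClusterSpectrum(gx, wavelength = grid2,
                             settings = solverSettings("Ex"))
  sy <- solveClusterSpectrum(gy, wavelength = grid2,
                             settings = solverSettings("Ey"))
  expect_equal(sx$extinction$value, sy$extinction$value, tolerance = 1e-10)
})

test_that("peak positions are converged in the wavelength step", {
  g <- buildChainGeometry(1, 6, 10)
  coarse <- solveClusterSpectrum(g, wavelength = seq(480, 700, 2))
  fine <- solveClusterSpectrum(g, wavelength = seq(480, 700, 1))
  pc <- peakWavelengths(coarse$extinction)
  pf <- peakWavelengths(fine$extinction)
  expect_lt(abs(max(pc$wavelength) - max(pf$wavelength)), 0.5)
})

test_that("sub-validity gaps trigger the fidelity warning", {
  g <- buildChainGeometry(0.3, 6, 2)  # gap/radius = 0.05
  expect_warning(solveClusterSpectrum(g, wavelength = c(520, 530)),
                 "point-dipole")
  expect_silent(solveClusterSpectrum(buildChainGeometry(2, 6, 2),
                                     wavelength = c(520, 530)))
})

test_that("field maps approach 1 far away, peak in gaps, mask spheres", {
  g <- buildChainGeometry(4, 6, 2)
  # far point: >= 20 x radius from the cluster
  far <- fieldEnhancementMap(g, 524, x = 300, y = 0)
  expect_equal(as.numeric(far), 1, tolerance = 0.02)
  inside <- fieldEnhancementMap(g, 524, x = 0, y = 0)
  expect_true(is.na(as.numeric(inside)))
  # gap enhancement at the resonant wavelength exceeds the red one
  gap_x <- 8  # midpoint between sphere surfaces
  e524 <- as.numeric(fieldEnhancementMap(g, 524, x = gap_x, y = 0))
  e609 <- as.numeric(fieldEnhancementMap(g, 609, x = gap_x, y = 0))
  expect_gte(e524, e609)
  expect_gt(e524, 1)
})
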