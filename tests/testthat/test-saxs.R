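Qgrid <- exp(seq(log(0.3), log(3), length.out = 200))

test_that("profiles convert Angstrom input exactly once", {
  p <- SAXSProfile(c(0.03, 0.1, 0.3), c(3, 2, 1), q_unit = "A^-1")
  expect_equal(p$Q, c(0.3, 1, 3))
  expect_true(attr(p, "converted"))
  p2 <- SAXSProfile(p$Q, p$I)  # already nm^-1, no further conversion
  expect_equal(p2$Q, p$Q)
  expect_error(SAXSProfile(c(1, 1, 2), 1:3), "strictly increasing")
  expect_error(SAXSProfile(c(-1, 1), c(1, 1)), "positive")
})

test_that("Schulz form factor is normalized and has the sphere minimum", {
  expect_equal(schulzFormFactor(1e-8, 6.9, 0.13), 1, tolerance = 1e-8)
  expect_equal(schulzFormFactor(1e-8, 6.9, 1e-6), 1, tolerance = 1e-8)
  # monodisperse limit: first zero of the sphere amplitude at x = 4.4934
  qs <- seq(0.55, 0.75, 1e-4)
  Pm <- schulzFormFactor(qs, 6.9, 1e-6)
  expect_equal(qs[which.min(Pm)], 4.493409 / 6.9, tolerance = 1e-3)
  expect_error(schulzFormFactor(1, 6.9, 0.5), "0.5")
})

test_that("closed form matches adaptive quadrature within 0.1%", {
  qs <- c(0.03, 0.1, 0.3, 0.651, 1.5, 3)
  expect_equal(schulzFormFactor(qs, 6.9, 0.13),
               schulzQuadOracle(qs, 6.9, 0.13), tolerance = 1e-3)
})

test_that("structure factor limits: dilute and hard-sphere", {
  S <- shsStructureFactor(Qgrid, 1e-6, 0.5, 13.8)
  expect_lt(max(abs(S - 1)), 1e-4)
  # tau -> Inf recovers the Percus-Yevick hard sphere (independent route)
  for (eta in c(0.05, 0.2, 0.4)) {
    Sshs <- shsStructureFactor(Qgrid, eta, 1e6, 13.8)
    Spy <- pyHardSphereSQ(Qgrid, 13.8, eta)
    expect_lt(max(abs(Sshs / Spy - 1)), 1e-3)
  }
})

test_that("stronger stickiness raises low-Q and depletes the flank", {
  taus <- c(0.2, 0.4, 0.8, 2, 10)
  lowQ <- vapply(taus, function(t)
    shsStructureFactor(0.05, 0.15, t, 13.8), numeric(1))
  expect_true(all(diff(lowQ) < 0))  # decreasing tau (reversed) raises S(0)
  flank <- vapply(taus, function(t)
    shsStructureFactor(0.35, 0.15, t, 13.8), numeric(1))
  expect_true(all(diff(flank) > 0))  # attraction depletes the left flank
})

test_that("forbidden parameter region raises a parameter-region error", {
  expect_error(shsStructureFactor(Qgrid, 0.0189, 0.01, 13.8),
               "forbidden region")
})

test_that("intensity model composes scale, P, S and background", {
  I0 <- saxsIntensity(Qgrid, 2, 0.1, 6.9, 0.13)
  expect_equal(I0$I, 2 * schulzFormFactor(Qgrid, 6.9, 0.13) + 0.1)
  I2 <- saxsIntensity(Qgrid, 4, 0.1, 6.9, 0.13)
  expect_equal(I2$I - 0.1, 2 * (I0$I - 0.1))
  expect_error(saxsIntensity(Qgrid, -1, 0, 6.9, 0.13), "non-negative")
})

test_that("noise-free generated parameters are recovered exactly", {
  tab <- shsPresets()
  for (s in c("DOPC", "POPC/DSPC")) {
    prof <- generateSAXSProfile(saxsScenario(), preset = s)
    fit <- fitStickyHardSphere(prof, 6.9, 0.13)
    row <- tab[tab$sample == s, ]
    expect_equal(fit$params$volume_fraction, row$volume_fraction,
                 tolerance = 1e-5)
    expect_equal(fit$params$stickiness, row$stickiness, tolerance = 1e-5)
  }
})

test_that("a noisy fit stays within three standard errors", {
  prof <- generateSAXSProfile(saxsScenario(noise_fraction = 0.02,
                                           seed = 42))
  fit <- fitStickyHardSphere(prof, 6.9, 0.13)
  expect_lt(abs(fit$params$volume_fraction - 0.0189),
            3 * fit$se[["volume_fraction"]])
  expect_lt(abs(fit$params$stickiness - 0.0634),
            3 * fit$se[["stickiness"]])
})

test_that("structure-factor extraction recovers the generating S(Q)", {
  free <- saxsIntensity(Qgrid, 1, 0, 6.9, 0.13)
  identical_S <- extractStructureFactor(free, free)
  expect_equal(identical_S$I, rep(1, length(Qgrid)), tolerance = 1e-12)
  Strue <- shsStructureFactor(Qgrid, 0.15, 0.3, 13.8)
  mix <- SAXSProfile(Qgrid, free$I * Strue)
  ext <- extractStructureFactor(mix, free)
  P <- schulzFormFactor(Qgrid, 6.9, 0.13)
  ok <- P > 0.01 * max(P)
  expect_equal(ext$I[ok], Strue[ok], tolerance = 0.01)
})

test_that("the S(Q) peak moves to higher Q for tighter packings", {
  free <- saxsIntensity(Qgrid, 1, 0, 6.9, 0.13)
  peakQ <- function(sig) {
    S <- shsStructureFactor(Qgrid, 0.15, 0.3, sig)
    ext <- extractStructureFactor(SAXSProfile(Qgrid, free$I * S), free)
    sel <- Qgrid > 0.3 & Qgrid < 1.2
    Qgrid[sel][which.max(ext$I[sel])]
  }
  expect_gt(peakQ(13.8), peakQ(16.5))
})

test_that("stickiness converts to the attractive pair potential", {
  eps <- 0.02
  expect_equal(tauToPairPotential(1 / (12 * eps), eps), 0)
  # softest-template reference value
  expect_lt(abs(tauToPairPotential(0.0634, 0.02) - (-4.190)), 0.1)
  taus <- c(0.05, 0.1, 0.2, 0.6)
  expect_true(all(diff(tauToPairPotential(taus, eps)) > 0))
  expect_error(tauToPairPotential(-1, eps), "positive")
  expect_error(tauToPairPotential(1, 0.2), "0.1")
  expect_equal(wellWidthFromSpacing(0.3, 13.8), 0.3 / 14.1)
})

test_that("reconstructed pair potentials preserve the stiffness ordering", {
  tab <- shsPresets()
  u0 <- tauToPairPotential(tab$stickiness, 0.02)
  expect_true(all(diff(u0) > 0))
  expect_true(all(diff(tab$u0) > 0))
})
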