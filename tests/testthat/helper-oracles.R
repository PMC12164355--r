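# Independent oracles used across the suite. These deliberately do not
# share code with the implementation paths they check.

lorentz <- function(x, center, width) 1 / (1 + ((x - center) / width)^2)

# closed-form dipole-limit cross sections of a small sphere: the
# Clausius-Mossotti polarizability with the finite-size dynamic
# depolarization and radiative-reaction corrections
dipoleCrossSections <- function(radius, nmed, wavelength,
                                model = goldDielectric()) {
  eps <- goldPermittivity(wavelength, model)
  em <- nmed^2
  k <- 2 * pi * nmed / wavelength
  al0 <- radius^3 * (eps - em) / (eps + 2 * em)
  al <- al0 / (1 - k^2 * al0 / radius - 2i / 3 * k^3 * al0)
  cext <- 4 * pi * k * Im(al)
  csca <- 8 * pi / 3 * k^4 * Mod(al)^2
  list(ext = cext, sca = csca, abs = cext - csca)
}

# Percus-Yevick hard-sphere structure factor, Ashcroft-Lekner direct
# correlation route (independent of the Baxter factorization used in the
# implementation)
pyHardSphereSQ <- function(Q, sigma, eta) {
  a <- (1 + 2 * eta)^2 / (1 - eta)^4
  b <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  cc <- eta * a / 2
  x <- Q * sigma
  s <- sin(x); co <- cos(x)
  I1 <- (s - x * co) / x^3
  I2 <- (2 * x * s - (x^2 - 2) * co - 2) / x^4
  I4 <- ((4 * x^3 - 24 * x) * s - (x^4 - 12 * x^2 + 24) * co + 24) / x^6
  ncq <- -24 * eta * (a * I1 + b * I2 + cc * I4)
  1 / (1 - ncq)
}

# Schulz-averaged sphere form factor by adaptive quadrature over the
# radius distribution (normalized to P(0) = 1)
schulzQuadOracle <- function(Q, R, p) {
  Z <- 1 / p^2 - 1
  beta <- (Z + 1) / R
  dens <- function(r) exp(Z * log(r) - beta * r + (Z + 1) * log(beta) -
                            lgamma(Z + 1))
  den <- stats::integrate(function(r) dens(r) * r^6, 0, R * 6,
                          rel.tol = 1e-10)$value
  vapply(Q, function(q) {
    num <- stats::integrate(function(r) {
      x <- q * r
      Fa <- 3 * (sin(x) - x * cos(x)) / x^3
      dens(r) * (r^3 * Fa)^2
    }, 0, R * 6, rel.tol = 1e-10)$value
    num / den
  }, numeric(1))
}

# far-field scattering cross section by angular quadrature of the dipole
# radiation pattern (the "integrating sphere" route)
farFieldScattering <- function(geometry, medium, wavelength_nm,
                               pol = "Ex", ntheta = 64, nphi = 64) {
  prep <- plasmiso:::.cdaPrep(geometry)
  em <- medium$permittivity
  k <- 2 * pi * medium$n / wavelength_nm
  eps <- goldPermittivity(wavelength_nm)
  sol <- plasmiso:::.cdaSolve(prep, attr(geometry, "radius"), eps, em, k,
                              "radiative_reaction", pol)
  p <- matrix(sol$p[, 1], nrow = 3)
  th <- (seq_len(ntheta) - 0.5) * pi / ntheta
  ph <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  tot <- 0
  for (t in th) for (f in ph) {
    rhat <- c(sin(t) * cos(f), sin(t) * sin(f), cos(t))
    amp <- c(0 + 0i, 0, 0)
    for (j in seq_len(ncol(p))) {
      pj <- p[, j]
      phase <- exp(-1i * k * sum(rhat * prep$xyz[j, ]))
      amp <- amp + (pj - rhat * sum(rhat * pj)) * phase
    }
    tot <- tot + sum(Mod(amp)^2) * sin(t)
  }
  k^4 * tot * (pi / ntheta) * (2 * pi / nphi)
}

singleSphereGeometry <- function(radius = 6) {
  plasmiso:::newClusterGeometry(
    data.frame(id = 1L, x = 0, y = 0, z = 0, radius = radius,
               subgroup = 1L),
    sp_nominal = 1, arrangement = "radial_2d", radius = radius)
}
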