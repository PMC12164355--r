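# Coupled-dipole solver for cluster extinction/absorption/scattering.
#
# Each sphere carries one induced point dipole with a radiatively corrected
# Clausius-Mossotti polarizability; dipoles interact through the full
# retarded dyadic Green function. Extinction follows from the optical
# theorem, absorption from per-dipole dissipation. Quantitatively reliable
# for surface gaps above roughly 0.15 particle radii; below that a fidelity
# warning is emitted (point-dipole validity limit).

#' Coupled-dipole solver settings
#'
#' @param polarization `"unpolarized"` (mean of Ex and Ey solves), `"Ex"`
#'   or `"Ey"`; propagation is along +Z, normal to the radial plane.
#' @param correction Polarizability correction: `"radiative_reaction"`
#'   (default) or `"dynamic_depolarization"` (adds the Meier-Wokaun
#'   finite-size k^2 term).
#' @param tol Relative tolerance on the linear solve residual.
#' @return A `SolverSettings` list.
#' @export
solverSettings <- function(polarization = c("unpolarized", "Ex", "Ey"),
                           correction = c("radiative_reaction",
                                          "dynamic_depolarization"),
                           tol = 1e-8) {
  structure(list(polarization = match.arg(polarization),
                 correction = match.arg(correction), tol = tol),
            class = "SolverSettings")
}

# per-geometry precomputation shared across wavelengths
.cdaPrep <- function(geometry) {
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  n <- nrow(xyz)
  D <- as.matrix(stats::dist(xyz))
  diag(D) <- 1  # placeholder, diagonal blocks are zeroed
  rh <- array(0, c(n, n, 3))
  for (a in 1:3)
    rh[, , a] <- outer(xyz[, a], xyz[, a], "-") / D
  n3 <- 3L * n
  bigidx <- rep(seq_len(n), each = 3L)
  Rbig <- matrix(0, n3, n3)
  I3big <- matrix(0, n3, n3)
  for (a in 1:3) for (b in 1:3) {
    Rbig[seq.int(a, n3, by = 3L), seq.int(b, n3, by = 3L)] <- rh[, , a] * rh[, , b]
    if (a == b)
      I3big[seq.int(a, n3, by = 3L), seq.int(b, n3, by = 3L)] <- 1
  }
  diagmask <- kronecker(diag(n), matrix(1, 3, 3)) == 1
  list(xyz = xyz, n = n, D = D, Rbig = Rbig, I3big = I3big,
       diagmask = diagmask, bigidx = bigidx)
}

# polarizability per particle at one wavelength
.cdaAlpha <- function(radius, eps, em, k, correction) {
  al0 <- radius^3 * (eps - em) / (eps + 2 * em)
  denom <- 1 - 2i / 3 * k^3 * al0
  if (correction == "dynamic_depolarization")
    denom <- denom - k^2 * al0 / radius
  al0 / denom
}

# one wavelength: returns list(p = 3N x npol dipole matrix, cext, cabs per
# polarization)
.cdaSolve <- function(prep, radius, eps, em, k, correction, pols) {
  al <- .cdaAlpha(radius, eps, em, k, correction)
  ph <- exp(1i * k * prep$D)
  c1 <- k^2 * ph / prep$D
  c2 <- ph * (1 / prep$D^3 - 1i * k / prep$D^2)
  C1 <- c1[prep$bigidx, prep$bigidx]
  C2 <- c2[prep$bigidx, prep$bigidx]
  G <- C1 * (prep$I3big - prep$Rbig) + C2 * (3 * prep$Rbig - prep$I3big)
  G[prep$diagmask] <- 0
  A <- -G
  dind <- cbind(seq_len(3L * prep$n), seq_len(3L * prep$n))
  A[dind] <- A[dind] + rep(1 / al, each = 3L)
  phz <- exp(1i * k * prep$xyz[, 3])
  E <- sapply(pols, function(pol) rep(phz, each = 3L) *
                rep(if (pol == "Ex") c(1, 0, 0) else c(0, 1, 0), prep$n))
  if (is.null(dim(E))) E <- matrix(E, ncol = 1L)
  p <- solve(A, E)
  if (is.null(dim(p))) p <- matrix(p, ncol = 1L)
  cext <- cabs <- numeric(ncol(p))
  for (j in seq_len(ncol(p))) {
    pj <- p[, j]
    cext[j] <- 4 * pi * k * sum(Im(Conj(E[, j]) * pj))
    p2 <- Mod(pj)^2
    cabs[j] <- 4 * pi * k * sum(-Im(rep(1 / al, each = 3L)) * p2 -
                                  (2 / 3) * k^3 * p2)
  }
  list(p = p, cext = cext, cabs = cabs)
}

#' Solve the coupled-dipole system over a wavelength grid
#'
#' @param geometry A `ClusterGeometry`.
#' @param medium A [Medium].
#' @param wavelength Wavelength grid in nm.
#' @param settings [solverSettings()].
#' @param model Dielectric model for the particles.
#' @param keep_dipoles Store per-particle dipole moments (needed only for
#'   field maps built by hand; [fieldEnhancementMap()] re-solves).
#' @return A `ClusterSpectra` list: [Spectrum] elements `extinction`,
#'   `absorption`, `scattering` (whole-cluster cross sections, nm^2),
#'   `n_particles`, and the per-polarization cross sections.
#' @examples
#' g <- buildChainGeometry(2, 6, 2)
#' cs <- solveClusterSpectrum(g, wavelength = seq(500, 560, 10))
#' @export
solveClusterSpectrum <- function(geometry, medium = Medium(),
                                 wavelength = seq(400, 800, by = 2),
                                 settings = solverSettings(),
                                 model = goldDielectric(),
                                 keep_dipoles = FALSE) {
  stopifnot(inherits(geometry, "ClusterGeometry"), inherits(medium, "Medium"))
  validateGeometry(geometry)
  radius <- attr(geometry, "radius")
  gapmin <- min(attr(geometry, "sp_variants"))
  if (nrow(geometry) > 1L && gapmin / radius < 0.15)
    warning(sprintf(
      "minimum gap/radius = %.3f is below the point-dipole validity limit ",
      gapmin / radius), "(0.15); treat spectra as qualitative", call. = FALSE)
  prep <- .cdaPrep(geometry)
  pols <- switch(settings$polarization,
                 unpolarized = c("Ex", "Ey"), Ex = "Ex", Ey = "Ey")
  em <- medium$permittivity
  eps <- goldPermittivity(wavelength, model)
  nw <- length(wavelength)
  cext <- cabs <- matrix(0, nw, length(pols),
                         dimnames = list(NULL, pols))
  dip <- if (keep_dipoles) vector("list", nw) else NULL
  for (i in seq_len(nw)) {
    k <- 2 * pi * medium$n / wavelength[i]
    sol <- .cdaSolve(prep, radius, eps[i], em, k, settings$correction, pols)
    cext[i, ] <- sol$cext
    cabs[i, ] <- sol$cabs
    if (keep_dipoles) dip[[i]] <- sol$p
  }
  ce <- rowMeans(cext)
  ca <- rowMeans(cabs)
  cs <- ce - ca
  if (any(cs < -settings$tol * max(abs(ce))))
    warning("scattering cross section slightly negative beyond tolerance",
            call. = FALSE)
  cs <- pmax(cs, 0)
  structure(list(
    extinction = Spectrum(wavelength, pmax(ce, 0), "extinction"),
    absorption = Spectrum(wavelength, pmax(ca, 0), "absorption"),
    scattering = Spectrum(wavelength, cs, "scattering"),
    per_polarization = list(extinction = cext, absorption = cabs),
    n_particles = nrow(geometry),
    settings = settings, dipoles = dip, wavelength = wavelength),
    class = "ClusterSpectra")
}

#' @export
print.ClusterSpectra <- function(x, ...) {
  pk <- try(peakWavelengths(x$extinction), silent = TRUE)
  cat(sprintf("ClusterSpectra: %d particles, %d wavelengths (%g-%g nm)\n",
              x$n_particles, length(x$wavelength), min(x$wavelength),
              max(x$wavelength)))
  if (!inherits(pk, "try-error") && nrow(pk))
    cat("  extinction peaks at:",
        paste(sprintf("%.1f nm", pk$wavelength), collapse = ", "), "\n")
  invisible(x)
}

#' Per-particle cluster spectrum
#'
#' Divides a whole-cluster spectrum by the particle count, giving the
#' cross section per gold nanoparticle — the quantity mixed with the
#' single-particle spectrum in two-population analyses.
#'
#' @param cluster A `ClusterSpectra` result.
#' @param channel Which channel to extract.
#' @return A [Spectrum].
#' @export
perParticleSpectrum <- function(cluster,
                                channel = c("extinction", "absorption",
                                            "scattering")) {
  channel <- match.arg(channel)
  s <- cluster[[channel]]
  Spectrum(s$wavelength, s$value / cluster$n_particles, channel)
}

#' Electric-field enhancement map
#'
#' Solves the coupled-dipole system at one wavelength and evaluates the
#' total field (incident + all dipole fields) on a grid of points in a
#' plane, returning the enhancement |E|/E0. Points inside a sphere are
#' masked (`NA`).
#'
#' @param geometry A `ClusterGeometry`.
#' @param wavelength_nm Single wavelength (nm).
#' @param x,y Numeric vectors of grid coordinates (nm); the map is
#'   evaluated on their outer product at height `z`.
#' @param z Plane height (nm, default 0).
#' @param medium A [Medium].
#' @param settings [solverSettings()]; for the unpolarized default the Ex
#'   solve is used (enhancement maps are polarization-specific).
#' @param model Dielectric model.
#' @return A matrix `length(x) x length(y)` of |E|/E0 values.
#' @export
fieldEnhancementMap <- function(geometry, wavelength_nm, x, y, z = 0,
                                medium = Medium(),
                                settings = solverSettings("Ex"),
                                model = goldDielectric()) {
  stopifnot(length(wavelength_nm) == 1L)
  pol <- if (settings$polarization == "Ey") "Ey" else "Ex"
  prep <- .cdaPrep(geometry)
  em <- medium$permittivity
  k <- 2 * pi * medium$n / wavelength_nm
  eps <- goldPermittivity(wavelength_nm, model)
  sol <- .cdaSolve(prep, attr(geometry, "radius"), eps, em, k,
                   settings$correction, pol)
  p <- matrix(sol$p[, 1], nrow = 3L)  # 3 x N
  pvec <- if (pol == "Ex") c(1, 0, 0) else c(0, 1, 0)
  out <- matrix(NA_real_, length(x), length(y))
  xyz <- prep$xyz
  radius <- geometry$radius
  for (ix in seq_along(x)) for (iy in seq_along(y)) {
    r0 <- c(x[ix], y[iy], z)
    dd <- sqrt(colSums((t(xyz) - r0)^2))
    if (any(dd < radius)) next  # masked: inside a sphere
    E <- pvec * exp(1i * k * r0[3])
    for (j in seq_len(prep$n)) {
      rv <- r0 - xyz[j, ]
      r <- sqrt(sum(rv^2))
      rhat <- rv / r
      pj <- p[, j]
      pr <- sum(rhat * pj)
      E <- E + exp(1i * k * r) *
        (k^2 / r * (pj - rhat * pr) +
           (1 / r^3 - 1i * k / r^2) * (3 * rhat * pr - pj))
    }
    out[ix, iy] <- sqrt(sum(Mod(E)^2))
  }
  out
}
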