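# Synthetic-data generators with recorded ground truth: concentration
# series of mixture spectra, noisy SAXS curves and sigmoid calibration
# sets. Every stochastic output is reproducible from (scenario, seed).

withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Spectral mixture scenario
#'
#' Defines a concentration series of gold nanoparticles incubated with an
#' increasing amount of template vesicles. The coupled fraction follows
#' the saturation law `f = min(1, c_template * N_sat / c_AuNP)`: while
#' nanoparticles are in excess, every added vesicle is saturated with
#' `N_sat` particles, so the clustered fraction grows linearly; beyond
#' saturation, cluster-size heterogeneity sets in and destroys the
#' isosbestic feature.
#'
#' @param aunp_concentration Gold nanoparticle concentration,
#'   particles/mL (default 4.4e12).
#' @param template_concentrations Vesicle concentrations, particles/mL
#'   (default 8 steps over 6e10-3.2e11, spanning number ratios of about
#'   74/1 down to 14/1 nanoparticles per vesicle).
#' @param n_sat Saturation capacity: nanoparticles per vesicle at maximal
#'   clustering (default 14).
#' @param sp_nm Average interparticle spacing within clusters (nm).
#' @param endpoint_source `"parametric"` (Lorentzian endpoint model) or
#'   `"solver"` (coupled-dipole endpoints).
#' @param noise_sd Additive Gaussian noise, absorbance units
#'   (photometric instrument noise; default 5e-4, typical of a benchtop
#'   spectrophotometer near 1 AU).
#' @param het_onset Relative template excess beyond exact saturation at
#'   which cluster-size heterogeneity (and with it the loss of the
#'   isosbestic point) sets in (default 0.1).
#' @param seed RNG seed.
#' @param wavelength Shared wavelength grid (nm).
#' @return A `SpectralScenario` list.
#' @export
spectralScenario <- function(aunp_concentration = 4.4e12,
                             template_concentrations =
                               seq(6e10, 3.2e11, length.out = 8),
                             n_sat = 14, sp_nm = 0.3,
                             endpoint_source = c("parametric", "solver"),
                             noise_sd = 5e-4, het_onset = 0.1, seed = 1,
                             wavelength = seq(400, 800, by = 1)) {
  stopifnot(aunp_concentration > 0, all(template_concentrations > 0),
            n_sat > 0, noise_sd >= 0, het_onset >= 0)
  structure(list(aunp_concentration = aunp_concentration,
                 template_concentrations = sort(template_concentrations),
                 n_sat = n_sat, sp_nm = sp_nm,
                 endpoint_source = match.arg(endpoint_source),
                 noise_sd = noise_sd, het_onset = het_onset, seed = seed,
                 wavelength = wavelength),
            class = "SpectralScenario")
}

#' Generate a concentration series of mixture spectra
#'
#' Each template concentration yields the two-population mixture spectrum
#' with its saturation-law coupled fraction plus i.i.d. Gaussian noise. In
#' the excess-template regime (nominal `f > 1`) the coupled endpoint is
#' replaced per-spectrum by a heterogeneous-cluster variant (randomly
#' reduced red shift), so the isosbestic point is lost there. The machine-
#' readable ground truth (fractions, regime labels, endpoints, noise-free
#' crossing) is attached as the `truth` element.
#'
#' @param scenario A [spectralScenario()].
#' @return A `MixtureSeries` with an extra `truth` element.
#' @export
generateMixtureSeries <- function(scenario) {
  stopifnot(inherits(scenario, "SpectralScenario"))
  wl <- scenario$wavelength
  if (scenario$endpoint_source == "parametric") {
    ep <- parametricEndpoints(scenario$sp_nm, wl)
    coupled <- ep$coupled; uncoupled <- ep$uncoupled
  } else {
    geom <- buildRadialGeometry(scenario$sp_nm)
    coupled <- suppressWarnings(perParticleSpectrum(
      solveClusterSpectrum(geom, wavelength = wl)))
    xs <- mieCrossSections(attr(geom, "radius"), wavelength = wl)
    uncoupled <- xs$extinction
  }
  fnom <- scenario$template_concentrations * scenario$n_sat /
    scenario$aunp_concentration
  f <- pmin(1, fnom)
  regime <- ifelse(fnom <= 1 + scenario$het_onset, "saturation",
                   "excess_template")
  withSeed(scenario$seed, {
    spectra <- vector("list", length(f))
    het <- numeric(length(f))
    for (i in seq_along(f)) {
      if (regime[i] == "excess_template") {
        # heterogeneous clusters: compress the coupled endpoint's red
        # shift toward the primary band and rescale the per-particle
        # amplitude, both by random per-spectrum factors, so consecutive
        # spectra no longer share a common crossing
        het[i] <- stats::runif(1, 0.4, 0.9)
        amp <- stats::runif(1, 0.8, 1.2)
        vi <- amp * stats::approx(wl, coupled$value,
                                  xout = 524 + (wl - 524) / het[i],
                                  rule = 2)$y
        cou_i <- Spectrum(wl, vi, channel = coupled$channel)
        sp_i <- mixtureSpectrum(1, cou_i, uncoupled)
      } else {
        sp_i <- mixtureSpectrum(f[i], coupled, uncoupled)
      }
      noise <- stats::rnorm(length(wl), sd = scenario$noise_sd)
      spectra[[i]] <- Spectrum(wl, sp_i$value + noise, "absorbance")
    }
    series <- mixtureSeries(spectra, f = f,
                            template_concentration =
                              scenario$template_concentrations,
                            aunp_concentration =
                              scenario$aunp_concentration)
    truth_cross <- tryCatch(findIsosbestic(coupled, uncoupled),
                            error = function(e) NULL)
    series$truth <- list(f = f, f_nominal = fnom, regime = regime,
                         heterogeneity = het,
                         coupled = coupled, uncoupled = uncoupled,
                         lambda_iso =
                           if (!is.null(truth_cross) && truth_cross$present)
                             truth_cross$lambda_iso else NA_real_)
    series
  })
}

#' SAXS scenario
#'
#' @param mean_radius,polydispersity Schulz sphere parameters (defaults
#'   6.9 nm, 0.13: the free-nanoparticle core fit).
#' @param volume_fraction,stickiness Sticky-hard-sphere truth (`NULL`
#'   volume fraction = free particles).
#' @param hard_core_diameter Hard-core diameter (default `2 * R`).
#' @param well_width Relative well width (default 0.02).
#' @param scale,background Intensity scale and flat background.
#' @param Q Scattering grid, 1/nm (default 200 log-spaced points over
#'   0.3-3).
#' @param noise_fraction Multiplicative Gaussian noise fraction
#'   (counting-statistics-like; default 0).
#' @param seed RNG seed.
#' @return A `SAXSScenario` list.
#' @export
saxsScenario <- function(mean_radius = 6.9, polydispersity = 0.13,
                         volume_fraction = 0.0189, stickiness = 0.0634,
                         hard_core_diameter = 2 * mean_radius,
                         well_width = 0.02, scale = 1, background = 0,
                         Q = exp(seq(log(0.3), log(3), length.out = 200)),
                         noise_fraction = 0, seed = 1) {
  structure(list(mean_radius = mean_radius,
                 polydispersity = polydispersity,
                 volume_fraction = volume_fraction,
                 stickiness = stickiness,
                 hard_core_diameter = hard_core_diameter,
                 well_width = well_width, scale = scale,
                 background = background, Q = Q,
                 noise_fraction = noise_fraction, seed = seed),
            class = "SAXSScenario")
}

#' Reference sticky-hard-sphere parameter sets
#'
#' Volume fraction, stickiness and effective pair potential for
#' vesicle-nanoparticle assemblies over a membrane-stiffness series of
#' phosphatidylcholine compositions, ordered from the softest (DOPC) to
#' the stiffest (POPC/DSPC) template.
#'
#' @return Data frame with columns `sample`, `volume_fraction`,
#'   `stickiness`, `u0`.
#' @export
shsPresets <- function() {
  data.frame(
    sample = c("DOPC", "DOPC/POPC", "POPC", "POPC/DPPC", "POPC/DSPC"),
    volume_fraction = c(0.0189, 0.0531, 0.0946, 0.1130, 0.1515),
    stickiness = c(0.0634, 0.0884, 0.1028, 0.2017, 0.5930),
    u0 = c(-4.190, -3.450, -3.010, -2.110, -0.851))
}

#' Generate a synthetic SAXS profile
#'
#' `I = scale * P * S + background` with optional multiplicative Gaussian
#' noise; the generating parameters are attached as the `truth` attribute.
#'
#' @param scenario A [saxsScenario()]; use `preset` to select a reference
#'   parameter row by sample name.
#' @param preset Optional sample name from [shsPresets()].
#' @return A [SAXSProfile] with attribute `truth`.
#' @export
generateSAXSProfile <- function(scenario = saxsScenario(), preset = NULL) {
  stopifnot(inherits(scenario, "SAXSScenario"))
  if (!is.null(preset)) {
    tab <- shsPresets()
    row <- tab[tab$sample == preset, ]
    if (!nrow(row)) stop("unknown preset: ", preset)
    scenario$volume_fraction <- row$volume_fraction
    scenario$stickiness <- row$stickiness
  }
  model <- saxsIntensity(scenario$Q, scenario$scale, scenario$background,
                         scenario$mean_radius, scenario$polydispersity,
                         scenario$volume_fraction, scenario$stickiness,
                         scenario$hard_core_diameter)
  I <- model$I
  dI <- NULL
  if (scenario$noise_fraction > 0) {
    I <- withSeed(scenario$seed,
                  I * (1 + stats::rnorm(length(I),
                                        sd = scenario$noise_fraction)))
    dI <- scenario$noise_fraction * model$I  # reported like counting errors
  }
  out <- SAXSProfile(scenario$Q, I, dI = dI)
  attr(out, "truth") <- scenario
  out
}

#' Generate a sigmoid calibration dataset
#'
#' Evaluates the decreasing sigmoid at the given spacings and adds
#' Gaussian noise; the generating parameters are attached as attribute
#' `truth`.
#'
#' @param lambda_A,lambda_B,sp0,k Sigmoid parameters (defaults 538, 526,
#'   0.7, 0.25).
#' @param sp Spacing grid, nm.
#' @param noise_sd Gaussian noise on `lambda_iso`, nm.
#' @param seed RNG seed.
#' @return Data frame `(sp, lambda_iso)` with attribute `truth`.
#' @export
generateCalibrationSet <- function(lambda_A = 538, lambda_B = 526,
                                   sp0 = 0.7, k = 0.25,
                                   sp = seq(0.05, 1.6, length.out = 20),
                                   noise_sd = 0, seed = 1) {
  par <- c(lambda_A = lambda_A, lambda_B = lambda_B, x0 = sp0, k = k)
  lam <- .sigmoidPredict(par, sp)
  if (noise_sd > 0)
    lam <- withSeed(seed, lam + stats::rnorm(length(sp), sd = noise_sd))
  out <- data.frame(sp = sp, lambda_iso = lam)
  attr(out, "truth") <- as.list(par)
  out
}
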