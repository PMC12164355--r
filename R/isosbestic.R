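# Isosbestic-point detection and two-population mixture analysis.

#' Convex mixture of two endpoint spectra
#'
#' `f * coupled + (1 - f) * uncoupled`, pointwise on a shared grid — the
#' spectrum of a system in which a fraction `f` of the nanoparticles is
#' plasmonically coupled in clusters and the rest remains dispersed.
#'
#' @param f Coupled fraction in `[0, 1]`.
#' @param coupled,uncoupled [Spectrum] endpoints on the same grid.
#' @return A [Spectrum].
#' @export
mixtureSpectrum <- function(f, coupled, uncoupled) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  stopifnot(inherits(coupled, "Spectrum"), inherits(uncoupled, "Spectrum"))
  if (!sameGrid(coupled, uncoupled))
    stop("endpoint spectra are not on the same wavelength grid")
  Spectrum(coupled$wavelength,
           f * coupled$value + (1 - f) * uncoupled$value,
           channel = coupled$channel)
}

#' Ordered family of mixture spectra
#'
#' @param spectra List of [Spectrum] objects on one shared grid.
#' @param f Optional coupled fractions, one per spectrum.
#' @param template_concentration Optional template (vesicle)
#'   concentrations, particles/mL, one per spectrum.
#' @param aunp_concentration Gold nanoparticle concentration, particles/mL.
#' @return A `MixtureSeries`.
#' @export
mixtureSeries <- function(spectra, f = NULL, template_concentration = NULL,
                          aunp_concentration = NA_real_) {
  stopifnot(is.list(spectra), length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "Spectrum")))
  for (s in spectra[-1L])
    if (!sameGrid(spectra[[1L]], s))
      stop("all spectra in a series must share one wavelength grid")
  if (!is.null(f) && length(f) != length(spectra))
    stop("f must have one value per spectrum")
  if (!is.null(template_concentration) &&
      length(template_concentration) != length(spectra))
    stop("template_concentration must have one value per spectrum")
  structure(list(spectra = spectra, f = f,
                 template_concentration = template_concentration,
                 aunp_concentration = aunp_concentration),
            class = "MixtureSeries")
}

#' @export
print.MixtureSeries <- function(x, ...) {
  cat(sprintf("MixtureSeries: %d spectra, %d wavelengths\n",
              length(x$spectra), length(x$spectra[[1]]$wavelength)))
  if (!is.null(x$f))
    cat("  coupled fractions:", paste(signif(x$f, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.MixtureSeries <- function(x) length(x$spectra)

#' Find the isosbestic crossing of two spectra
#'
#' Locates sign changes of `A - B` within a wavelength window, refining
#' each crossing by linear interpolation between the bracketing grid
#' points. With multiple crossings, the one closest to the primary peak of
#' `spec_B` (the uncoupled pivot) is reported, together with the count.
#'
#' @param spec_A,spec_B [Spectrum] objects on one shared grid.
#' @param window Wavelength window (nm) searched for crossings.
#' @return An `isosbestic` list: `lambda_iso` (nm, `NA` when no crossing),
#'   `present`, `n_crossings`, `crossings` (all crossing wavelengths).
#' @export
findIsosbestic <- function(spec_A, spec_B, window = c(450, 650)) {
  stopifnot(inherits(spec_A, "Spectrum"), inherits(spec_B, "Spectrum"))
  if (!sameGrid(spec_A, spec_B))
    stop("spectra are not on the same wavelength grid")
  sel <- spec_A$wavelength >= window[1] & spec_A$wavelength <= window[2]
  if (sum(sel) < 2L) stop("window contains fewer than 2 grid points")
  w <- spec_A$wavelength[sel]
  d <- spec_A$value[sel] - spec_B$value[sel]
  if (all(d == 0))
    stop("degenerate input: spectra are identical within the window")
  idx <- which(d[-length(d)] * d[-1L] < 0)
  crossings <- w[which(d == 0)]
  for (i in idx)
    crossings <- c(crossings,
                   w[i] - d[i] * (w[i + 1L] - w[i]) / (d[i + 1L] - d[i]))
  crossings <- sort(unique(crossings))
  if (!length(crossings))
    return(structure(list(lambda_iso = NA_real_, present = FALSE,
                          n_crossings = 0L, crossings = numeric(0)),
                     class = "isosbestic"))
  pivot <- tryCatch({
    pk <- peakWavelengths(spec_B)
    if (nrow(pk)) pk$wavelength[which.max(pk$prominence)] else
      spec_B$wavelength[which.max(spec_B$value)]
  }, error = function(e) spec_B$wavelength[which.max(spec_B$value)])
  structure(list(lambda_iso = crossings[which.min(abs(crossings - pivot))],
                 present = TRUE, n_crossings = length(crossings),
                 crossings = crossings),
            class = "isosbestic")
}

#' @export
print.isosbestic <- function(x, ...) {
  if (x$present)
    cat(sprintf("isosbestic point at %.2f nm (%d crossing%s)\n",
                x$lambda_iso, x$n_crossings,
                if (x$n_crossings > 1) "s" else ""))
  else cat("no isosbestic crossing in window\n")
  invisible(x)
}

#' Isosbestic wavelength of a spectral family
#'
#' Crossings are computed for consecutive pairs of spectra; the family has
#' an isosbestic point when every pair crosses and the dispersion (standard
#' deviation) of the crossing wavelengths is at most `threshold`.
#'
#' @param series A `MixtureSeries` (or plain list of spectra) with at
#'   least 3 members.
#' @param window Search window (nm).
#' @param threshold Dispersion threshold in nm for the isosbestic flag
#'   (default 1.5, slightly looser than the +-1 nm experimental
#'   reproducibility).
#' @return List with `lambda_iso` (mean crossing), `dispersion` (sd, nm),
#'   `is_isosbestic` flag and the per-pair crossing wavelengths.
#' @export
isosbesticFromFamily <- function(series, window = c(450, 650),
                                 threshold = 1.5) {
  spectra <- if (inherits(series, "MixtureSeries")) series$spectra else series
  if (length(spectra) < 3L)
    stop("a spectral family needs at least 3 spectra")
  per <- numeric(0)
  all_present <- TRUE
  for (i in seq_len(length(spectra) - 1L)) {
    r <- tryCatch(findIsosbestic(spectra[[i]], spectra[[i + 1L]], window),
                  error = function(e) NULL)
    if (is.null(r) || !r$present) { all_present <- FALSE; next }
    per <- c(per, r$lambda_iso)
  }
  disp <- if (length(per) >= 2L) stats::sd(per) else Inf
  list(lambda_iso = if (length(per)) mean(per) else NA_real_,
       dispersion = disp,
       is_isosbestic = all_present && length(per) >= 2L &&
         disp <= threshold,
       crossings = per)
}

#' Parametric two-population endpoint spectra
#'
#' Lorentzian endpoint model independent of the electromagnetic solver.
#' The uncoupled endpoint is a single band at 524 nm. The coupled endpoint
#' is a two-band spectrum: a reduced primary band plus a red-shifted
#' coupling band whose center decays exponentially with the interparticle
#' spacing (anchored at 609 nm for sp = 0.3 nm and 553 nm for
#' sp = 0.8 nm). The primary-band weight is chosen in closed form so the
#' two endpoints cross exactly at the isosbestic wavelength given by the
#' sigmoidal spacing law `iso_params`, making the generated families
#' consistent with the calibration generator by construction.
#'
#' @param sp_nm Average interparticle spacing in nm.
#' @param wavelength Wavelength grid (nm).
#' @param primary_nm Primary (single-particle) band center.
#' @param width_primary,width_coupled Lorentzian half-widths (nm).
#' @param coupled_weight Weight of the coupling band in the coupled
#'   endpoint.
#' @param iso_params Sigmoid parameters (`lambda_A, lambda_B, x0, k`)
#'   fixing the crossing wavelength as a function of spacing.
#' @return List with [Spectrum] elements `coupled` and `uncoupled`, the
#'   coupling-band center `lambda2` and the designed crossing
#'   `lambda_iso`.
#' @export
parametricEndpoints <- function(sp_nm, wavelength = seq(400, 800, by = 1),
                                primary_nm = 524, width_primary = 30,
                                width_coupled = 55, coupled_weight = 0.55,
                                iso_params = c(lambda_A = 538,
                                               lambda_B = 526,
                                               x0 = 0.7, k = 0.25)) {
  # exponential spacing law through the (0.3, 609) and (0.8, 553) anchors
  ell <- 0.5 / log((609 - primary_nm) / (553 - primary_nm))
  A <- (609 - primary_nm) * exp(0.3 / ell)
  lambda2 <- primary_nm + A * exp(-sp_nm / ell)
  lambda_iso <- .sigmoidPredict(as.list(iso_params), sp_nm)
  lor <- function(x, center, width) 1 / (1 + ((x - center) / width)^2)
  # primary-band weight such that coupled(lambda_iso) = uncoupled(lambda_iso)
  a <- 1 - coupled_weight * lor(lambda_iso, lambda2, width_coupled) /
    lor(lambda_iso, primary_nm, width_primary)
  unc <- lor(wavelength, primary_nm, width_primary)
  cou <- a * lor(wavelength, primary_nm, width_primary) +
    coupled_weight * lor(wavelength, lambda2, width_coupled)
  list(coupled = Spectrum(wavelength, cou, "absorbance"),
       uncoupled = Spectrum(wavelength, unc, "absorbance"),
       lambda2 = lambda2, lambda_iso = lambda_iso)
}

#' Sweep the isosbestic wavelength against interparticle spacing
#'
#' For each spacing, the coupled endpoint is the per-particle cluster
#' spectrum (coupled-dipole solver) or the parametric Lorentzian model,
#' the uncoupled endpoint is the corresponding single-particle spectrum,
#' and the isosbestic wavelength is located from the mixture family over
#' `f_grid`.
#'
#' @param sp_values Spacings in nm (`> 0`).
#' @param endpoint `"parametric"` or `"solver"`.
#' @param arrangement Cluster arrangement for the solver endpoint.
#' @param radius_nm Particle radius (solver endpoint).
#' @param n_particles Chain length when `arrangement = "chain_1d"`.
#' @param medium,settings,model Solver configuration.
#' @param wavelength Wavelength grid (nm).
#' @param f_grid Coupled fractions used to build the family.
#' @param window Crossing search window (nm).
#' @return Data frame with columns `sp`, `lambda_iso`, `dispersion`,
#'   `present`.
#' @export
isosbesticSweep <- function(sp_values,
                            endpoint = c("parametric", "solver"),
                            arrangement = c("radial_2d", "chain_1d"),
                            radius_nm = 6, n_particles = 3,
                            medium = Medium(),
                            settings = solverSettings(),
                            model = goldDielectric(),
                            wavelength = seq(400, 800, by = 2),
                            f_grid = seq(0.2, 1, by = 0.2),
                            window = c(450, 650)) {
  endpoint <- match.arg(endpoint)
  arrangement <- match.arg(arrangement)
  stopifnot(all(sp_values > 0))
  if (endpoint == "solver") {
    single <- newClusterGeometry(
      data.frame(id = 1L, x = 0, y = 0, z = 0, radius = radius_nm,
                 subgroup = 1L),
      sp_nominal = 1, arrangement = "radial_2d", radius = radius_nm)
    unc <- perParticleSpectrum(
      solveClusterSpectrum(single, medium, wavelength, settings, model))
  } else {
    unc <- NULL
  }
  rows <- lapply(sp_values, function(sp) {
    if (endpoint == "parametric") {
      ep <- parametricEndpoints(sp, wavelength)
      cou <- ep$coupled; un <- ep$uncoupled
    } else {
      geom <- if (arrangement == "radial_2d")
        buildRadialGeometry(sp, radius_nm)
      else buildChainGeometry(sp, radius_nm, n_particles)
      cou <- suppressWarnings(perParticleSpectrum(
        solveClusterSpectrum(geom, medium, wavelength, settings, model)))
      un <- unc
    }
    fam <- lapply(sort(unique(c(0, f_grid))), mixtureSpectrum,
                  coupled = cou, uncoupled = un)
    res <- isosbesticFromFamily(fam, window)
    data.frame(sp = sp, lambda_iso = res$lambda_iso,
               dispersion = res$dispersion,
               present = res$is_isosbestic)
  })
  do.call(rbind, rows)
}

#' Aggregation index of an extinction spectrum
#'
#' Scalar descriptor of nanoparticle clustering. The default
#' `"band_ratio"` definition is the integral over 600-700 nm divided by
#' the integral over 500-600 nm; `"peak_ratio"` is the value at 650 nm
#' divided by the value at the primary peak. The definition used is
#' recorded in the result.
#'
#' @param spectrum A [Spectrum] covering at least 500-700 nm.
#' @param definition `"band_ratio"` or `"peak_ratio"`.
#' @return Numeric aggregation index with attribute `definition`.
#' @export
aggregationIndex <- function(spectrum,
                             definition = c("band_ratio", "peak_ratio")) {
  definition <- match.arg(definition)
  stopifnot(inherits(spectrum, "Spectrum"))
  w <- spectrum$wavelength
  if (min(w) > 500 || max(w) < 700)
    stop("spectrum must cover 500-700 nm for the aggregation index")
  trapz <- function(lo, hi) {
    grid <- sort(unique(c(lo, hi, w[w >= lo & w <= hi])))
    v <- stats::approx(w, spectrum$value, xout = grid)$y
    sum(diff(grid) * (v[-1L] + v[-length(v)]) / 2)
  }
  ai <- if (definition == "band_ratio") {
    trapz(600, 700) / trapz(500, 600)
  } else {
    v650 <- stats::approx(w, spectrum$value, xout = 650)$y
    pk <- peakWavelengths(spectrum)
    vpk <- if (nrow(pk)) {
      stats::approx(w, spectrum$value,
                    xout = pk$wavelength[which.max(pk$prominence)])$y
    } else max(spectrum$value)
    v650 / vpk
  }
  structure(ai, definition = definition)
}

#' Classify concentration regimes of a mixture series
#'
#' In the low template-concentration (nanoparticle excess, "saturation")
#' regime the aggregation index grows with concentration and the
#' isosbestic point is valid; beyond the AI maximum the series enters the
#' excess-template regime where cluster heterogeneity destroys the
#' isosbestic feature.
#'
#' @param series A `MixtureSeries` with template concentrations attached,
#'   ordered increasing.
#' @param definition Aggregation-index definition.
#' @return List with a per-spectrum table (`concentration`, `AI`,
#'   `regime`) and the boundary concentration.
#' @export
classifyConcentrationRegime <- function(series,
                                        definition = c("band_ratio",
                                                       "peak_ratio")) {
  stopifnot(inherits(series, "MixtureSeries"))
  conc <- series$template_concentration
  if (is.null(conc)) stop("series has no template concentrations attached")
  if (any(diff(conc) <= 0)) stop("template concentrations must be ordered increasing")
  ai <- vapply(series$spectra, function(s)
    as.numeric(aggregationIndex(s, definition)), numeric(1))
  imax <- which.max(ai)
  regime <- ifelse(seq_along(conc) <= imax, "saturation", "excess_template")
  list(table = data.frame(concentration = conc, AI = ai, regime = regime),
       boundary = conc[imax],
       definition = match.arg(definition))
}
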