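# Small-angle X-ray scattering analysis: Schulz-polydisperse sphere form
# factor, Baxter sticky-hard-sphere structure factor in the Percus-Yevick
# closure, combined intensity fitting, structure-factor extraction and the
# stickiness -> pair-potential conversion.
#
# All Q values are stored internally in 1/nm (1/nm = 10 x 1/Angstrom).

#' SAXS profile container
#'
#' @param Q Scattering vector, strictly increasing and positive.
#' @param I Intensities, finite.
#' @param dI Optional intensity uncertainties.
#' @param q_unit Unit of the supplied `Q` (`"nm^-1"` or `"A^-1"`);
#'   Angstrom input is converted to 1/nm exactly once and the conversion
#'   is recorded in the `converted` attribute.
#' @param absolute Logical flag: intensities on an absolute scale.
#' @return A `SAXSProfile`.
#' @export
SAXSProfile <- function(Q, I, dI = NULL, q_unit = c("nm^-1", "A^-1"),
                        absolute = FALSE) {
  q_unit <- match.arg(q_unit)
  converted <- q_unit == "A^-1"
  if (converted) Q <- Q * 10
  if (any(!is.finite(Q)) || any(Q <= 0) || any(diff(Q) <= 0))
    stop("Q must be positive, finite and strictly increasing")
  if (any(!is.finite(I))) stop("intensities must be finite")
  if (!is.null(dI) && (length(dI) != length(I) || any(dI < 0)))
    stop("dI must be non-negative and match I in length")
  if (length(Q) != length(I)) stop("Q and I must have the same length")
  structure(list(Q = Q, I = I, dI = dI),
            class = "SAXSProfile", q_unit = "nm^-1",
            converted = converted, absolute = absolute)
}

#' @export
print.SAXSProfile <- function(x, ...) {
  cat(sprintf("SAXSProfile: %d points, Q %.4g-%.4g nm^-1%s%s\n",
              length(x$Q), min(x$Q), max(x$Q),
              if (is.null(x$dI)) "" else ", with uncertainties",
              if (attr(x, "converted")) " (converted from 1/Angstrom)" else ""))
  invisible(x)
}

#' @export
plot.SAXSProfile <- function(x, ..., log = "xy", xlab = "Q (1/nm)",
                             ylab = "I(Q)") {
  graphics::plot(x$Q, x$I, log = log, xlab = xlab, ylab = ylab, type = "l",
                 ...)
  invisible(x)
}

# Gamma moments of the Schulz radius distribution R ~ Gamma(Z+1, rate beta):
# E[R^m] and E[R^m e^{2iQR}] have closed forms, giving an exact analytic
# Schulz average of the sphere intensity.
#' Schulz-averaged sphere form factor
#'
#' Analytic closed form of the intensity-weighted sphere form factor
#' averaged over a Schulz size distribution, normalized so `P(0) = 1`.
#' In the monodisperse limit (`p -> 0`) it reduces to the single-sphere
#' form factor `[3 (sin QR - QR cos QR)/(QR)^3]^2`.
#'
#' @param Q Scattering vector in 1/nm (vectorized).
#' @param mean_radius Mean sphere radius R in nm.
#' @param polydispersity Relative width `p = sigma_R / R`, `0 <= p < 0.5`.
#' @return `P(Q)` values.
#' @examples
#' schulzFormFactor(c(0.3, 0.651), 6.9, 0.13)
#' @export
schulzFormFactor <- function(Q, mean_radius, polydispersity) {
  stopifnot(mean_radius > 0)
  p <- polydispersity
  if (p < 0 || p >= 0.5)
    stop("polydispersity must lie in [0, 0.5) for the closed form")
  if (p < 1e-3) {
    x <- Q * mean_radius
    F <- ifelse(x < 1e-4, 1 - x^2 / 10,
                3 * (sin(x) - x * cos(x)) / x^3)
    return(F^2)
  }
  Z <- 1 / p^2 - 1
  beta <- (Z + 1) / mean_radius
  lmom <- function(m) exp(lgamma(Z + 1 + m) - lgamma(Z + 1)) / beta^m
  ER2 <- lmom(2); ER6 <- lmom(6); ER8 <- lmom(8); ER10 <- lmom(10)
  out <- numeric(length(Q))
  small <- Q * mean_radius * (1 + 6 * p) < 0.1
  # series branch avoids catastrophic cancellation at small QR
  out[small] <- 1 - Q[small]^2 * ER8 / (5 * ER6) +
    3 * Q[small]^4 * ER10 / (175 * ER6)
  if (any(!small)) {
    q <- Q[!small]
    w <- complex(real = 1, imaginary = -2 * q / beta)
    G0 <- exp(-(Z + 1) * log(w))
    G1 <- lmom(1) * exp(-(Z + 2) * log(w))
    G2 <- lmom(2) * exp(-(Z + 3) * log(w))
    Eg2 <- 0.5 * (1 - Re(G0)) - q * Im(G1) + q^2 * 0.5 * (ER2 + Re(G2))
    out[!small] <- 9 * Eg2 / (q^6 * ER6)
  }
  out
}

#' Baxter sticky-hard-sphere structure factor
#'
#' Percus-Yevick closed form for Baxter's adhesive-sphere potential. The
#' stickiness parameter `tau` inversely reflects the attraction strength;
#' `tau -> Inf` recovers the Percus-Yevick hard-sphere fluid and
#' `phi -> 0` the ideal `S(Q) = 1` limit. The quadratic for Baxter's
#' lambda must have a real root; parameter pairs inside the forbidden
#' region raise an error.
#'
#' @param Q Scattering vector in 1/nm (vectorized).
#' @param volume_fraction Hard-sphere volume fraction `phi` in (0, 0.74).
#' @param stickiness Baxter stickiness `tau > 0`.
#' @param hard_core_diameter Hard-core diameter `sigma_hc` in nm.
#' @param well_width Relative well width `eps` in (0, 0.1]; used only when
#'   `rescale = TRUE`.
#' @param rescale Apply the perturbative well-width rescaling
#'   `eta = phi/(1-eps)^3` of the SasView convention (default `FALSE`:
#'   plain Baxter `(phi, tau)` parameters).
#' @return `S(Q)` values.
#' @examples
#' shsStructureFactor(seq(0.3, 3, 0.3), 0.1515, 0.5930, 13.8)
#' @export
shsStructureFactor <- function(Q, volume_fraction, stickiness,
                               hard_core_diameter, well_width = 0,
                               rescale = FALSE) {
  phi <- volume_fraction; tau <- stickiness
  if (phi <= 0 || phi >= 0.74) stop("volume fraction must lie in (0, 0.74)")
  if (tau <= 0) stop("stickiness must be positive")
  eps <- if (rescale) well_width else 0
  eta <- phi / (1 - eps)^3
  sig <- hard_core_diameter / (1 - eps)
  e1 <- 1 - eta
  qa <- eta / 12
  qb <- -(tau + eta / e1)
  qc <- (1 + eta / 2) / e1^2
  radic <- qb^2 - 4 * qa * qc
  if (radic < 0)
    stop(sprintf(
      "no physical Baxter root for phi = %.4g, tau = %.4g (forbidden region)",
      phi, tau))
  lam <- min((-qb - sqrt(radic)) / (2 * qa), (-qb + sqrt(radic)) / (2 * qa))
  mu <- lam * eta * e1
  alpha <- (1 + 2 * eta - mu) / e1^2
  beta <- (mu - 3 * eta) / (2 * e1^2)
  kk <- Q * sig
  S <- numeric(length(Q))
  big <- kk >= 0.02
  if (any(big)) {
    x <- kk[big]; s <- sin(x); cc <- cos(x)
    A <- 1 + 12 * eta * (alpha * (s - x * cc) / x^3 +
                           beta * (1 - cc) / x^2 - lam * s / (12 * x))
    B <- 12 * eta * (alpha * (0.5 / x - s / x^2 + (1 - cc) / x^3) +
                       beta * (1 / x - s / x^2) - lam * (1 - cc) / (12 * x))
    S[big] <- 1 / (A^2 + B^2)
  }
  if (any(!big)) {
    x <- kk[!big]
    A <- 1 + 12 * eta * (alpha * (1 / 3 - x^2 / 30) +
                           beta * (0.5 - x^2 / 24) - lam / 12 * (1 - x^2 / 6))
    B <- 12 * eta * (alpha * (x / 8 - x^3 / 144) +
                       beta * (x / 6 - x^3 / 120) -
                       lam / 12 * (x / 2 - x^3 / 24))
    S[!big] <- 1 / (A^2 + B^2)
  }
  S
}

#' Sticky-hard-sphere intensity model
#'
#' `I(Q) = scale * P(Q) * S(Q) + background` in the decoupling
#' approximation (polydispersity carried by the form factor only), the
#' convention of the SasView model family. With `volume_fraction = NULL`
#' the structure factor is 1 (free particles).
#'
#' @param Q Scattering vector, 1/nm.
#' @param scale,background Non-negative scale and flat background.
#' @param mean_radius,polydispersity Schulz sphere parameters.
#' @param volume_fraction,stickiness Sticky-hard-sphere parameters
#'   (`NULL` for form factor only).
#' @param hard_core_diameter Hard-core diameter (default `2 * mean_radius`).
#' @param well_width,rescale Passed to [shsStructureFactor()].
#' @return A [SAXSProfile] of model intensities.
#' @export
saxsIntensity <- function(Q, scale = 1, background = 0, mean_radius,
                          polydispersity, volume_fraction = NULL,
                          stickiness = NULL,
                          hard_core_diameter = 2 * mean_radius,
                          well_width = 0, rescale = FALSE) {
  if (scale < 0 || background < 0)
    stop("scale and background must be non-negative")
  P <- schulzFormFactor(Q, mean_radius, polydispersity)
  S <- if (is.null(volume_fraction)) 1 else
    shsStructureFactor(Q, volume_fraction, stickiness, hard_core_diameter,
                       well_width, rescale)
  SAXSProfile(Q, scale * P * S + background)
}

#' Fit the sticky-hard-sphere model to a SAXS profile
#'
#' Weighted nonlinear least squares of
#' `I(Q) = scale * P(Q; R, p) * S(Q; phi, tau) + background` with the
#' form-factor parameters fixed (taken from a separate free-particle fit,
#' mirroring the standard protocol) and `scale`, `background`, `phi`,
#' `tau` free. Weights are `1/dI^2` when uncertainties are present, else
#' `1/I`.
#'
#' @param profile A [SAXSProfile].
#' @param mean_radius,polydispersity Fixed Schulz parameters.
#' @param hard_core_diameter Fixed hard-core diameter (default `2 * R`).
#' @param well_width Relative well width used for the pair-potential
#'   conversion (default 0.02) and, when `rescale = TRUE`, for `S(Q)`.
#' @param rescale Passed to [shsStructureFactor()].
#' @param start Optional named start values (`scale`, `background`,
#'   `volume_fraction`, `stickiness`).
#' @return An `SHSFit` with the fitted `SHSParams` (phi, tau, u0), standard
#'   errors, covariance, `chi2_dof` and a fit report.
#' @export
fitStickyHardSphere <- function(profile, mean_radius, polydispersity,
                                hard_core_diameter = 2 * mean_radius,
                                well_width = 0.02, rescale = FALSE,
                                start = NULL) {
  stopifnot(inherits(profile, "SAXSProfile"))
  Q <- profile$Q; I <- profile$I
  w <- if (!is.null(profile$dI) && all(profile$dI > 0)) 1 / profile$dI^2
  else {
    if (any(I <= 0)) stop("intensities must be positive for 1/I weighting")
    1 / I
  }
  P <- schulzFormFactor(Q, mean_radius, polydispersity)
  if (is.null(start))
    start <- list(scale = max(I) / max(P), background = min(I) * 0.5 + 1e-12,
                  volume_fraction = 0.05, stickiness = 0.2)
  lower <- c(scale = 1e-12, background = 0, volume_fraction = 1e-6,
             stickiness = 1e-4)
  upper <- c(scale = Inf, background = Inf, volume_fraction = 0.6,
             stickiness = 1e4)
  sw <- sqrt(w)
  residFn <- function(par) {
    S <- tryCatch(
      shsStructureFactor(Q, par[["volume_fraction"]], par[["stickiness"]],
                         hard_core_diameter, well_width, rescale),
      error = function(e) rep(1e6, length(Q)))
    sw * (I - (par[["scale"]] * P * S + par[["background"]]))
  }
  fit <- minpack.lm::nls.lm(
    par = unlist(start), fn = residFn,
    lower = lower[names(start)], upper = upper[names(start)],
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 2000))
  if (fit$info %in% c(0, 5, 9))
    warning("sticky-hard-sphere fit did not converge: ", fit$message,
            call. = FALSE)
  par <- stats::coef(fit)
  dof <- length(I) - length(par)
  chi2_dof <- fit$deviance / dof
  cov <- tryCatch(solve(fit$hessian) * chi2_dof, error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else
    rep(NA_real_, length(par))
  names(se) <- names(par)
  pinned <- names(par)[par >= upper[names(par)] * (1 - 1e-6) |
                         (lower[names(par)] > 0 &
                            par <= lower[names(par)] * (1 + 1e-6))]
  pinned <- setdiff(pinned, "background")  # zero background is legitimate
  warn <- character(0)
  if (length(pinned))
    warn <- sprintf("parameter(s) pinned at bounds: %s",
                    paste(pinned, collapse = ", "))
  u0 <- tauToPairPotential(par[["stickiness"]], well_width)
  structure(list(
    params = list(volume_fraction = par[["volume_fraction"]],
                  stickiness = par[["stickiness"]],
                  well_width = well_width,
                  hard_core_diameter = hard_core_diameter,
                  u0 = u0),
    scale = par[["scale"]], background = par[["background"]],
    se = se, cov = cov,
    chi2_dof = chi2_dof, warnings = warn, fit = fit,
    fixed = list(mean_radius = mean_radius,
                 polydispersity = polydispersity)),
    class = "SHSFit")
}

#' @export
print.SHSFit <- function(x, ...) {
  cat("Sticky-hard-sphere fit\n")
  cat(sprintf("  volume fraction phi = %.4g +- %.2g\n",
              x$params$volume_fraction, x$se[["volume_fraction"]]))
  cat(sprintf("  stickiness tau      = %.4g +- %.2g\n",
              x$params$stickiness, x$se[["stickiness"]]))
  cat(sprintf("  u0 (eps = %.3g)     = %.4g kBT\n", x$params$well_width,
              x$params$u0))
  cat(sprintf("  chi2/dof = %.4g\n", x$chi2_dof))
  for (w in x$warnings) cat("  WARNING:", w, "\n")
  invisible(x)
}

#' Extract the structure factor from mixture and free-particle profiles
#'
#' `S(Q) = I_mix(Q) / (c * I_free(Q))` on the common Q support (linear
#' resampling to the coarser grid), with `c` chosen so that the mean of
#' `S` over the top decade of Q equals 1 (structure correlations have died
#' out there).
#'
#' @param mixture,free_particles [SAXSProfile] objects.
#' @param background Optional flat background subtracted from both.
#' @return A [SAXSProfile] holding `S(Q)`.
#' @export
extractStructureFactor <- function(mixture, free_particles, background = 0) {
  stopifnot(inherits(mixture, "SAXSProfile"),
            inherits(free_particles, "SAXSProfile"))
  qlo <- max(min(mixture$Q), min(free_particles$Q))
  qhi <- min(max(mixture$Q), max(free_particles$Q))
  if (qlo >= qhi) stop("profiles have no common Q support")
  # resample to the coarser of the two grids
  qm <- mixture$Q[mixture$Q >= qlo & mixture$Q <= qhi]
  qf <- free_particles$Q[free_particles$Q >= qlo & free_particles$Q <= qhi]
  Q <- if (length(qm) <= length(qf)) qm else qf
  Imix <- stats::approx(mixture$Q, mixture$I, xout = Q)$y - background
  Ifree <- stats::approx(free_particles$Q, free_particles$I,
                         xout = Q)$y - background
  if (any(Ifree <= 0))
    stop("free-particle intensity non-positive on the common support")
  ratio <- Imix / Ifree
  top <- Q >= max(Q) / 10  # top decade of Q
  cc <- mean(ratio[top])
  SAXSProfile(Q, ratio / cc)
}

#' Convert stickiness to an effective pair potential
#'
#' Baxter's stickiness parameterizes a narrow square well of relative
#' width `eps` and depth `u0` through `tau = exp(u0/kBT) / (12 eps)`,
#' giving `u0/kBT = log(12 tau eps)`; attractive wells have `u0 < 0`.
#'
#' @param tau Stickiness `> 0`.
#' @param eps Relative well width in (0, 0.1]. The spacing-based
#'   convention `eps = sp / (sigma_hc + sp)` is provided by
#'   [wellWidthFromSpacing()].
#' @return `u0` in units of `kB T`.
#' @examples
#' tauToPairPotential(0.0634, 0.02)  # about -4.19 kBT
#' @export
tauToPairPotential <- function(tau, eps) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(eps <= 0 | eps > 0.1)) stop("eps must lie in (0, 0.1]")
  log(12 * tau * eps)
}

#' Relative well width from the interparticle spacing
#'
#' `eps = sp / (sigma_hc + sp)`: the surface gap as a fraction of the
#' outer well diameter.
#'
#' @param sp_nm Average surface-to-surface spacing (nm).
#' @param hard_core_diameter Hard-core diameter (nm).
#' @return Relative well width.
#' @export
wellWidthFromSpacing <- function(sp_nm, hard_core_diameter) {
  stopifnot(sp_nm > 0, hard_core_diameter > 0)
  sp_nm / (hard_core_diameter + sp_nm)
}
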