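# Sigmoidal calibration of the isosbestic wavelength against interparticle
# spacing, its algebraic inversion with first-order error propagation, and
# the analogous monotone map against membrane stiffness.
#
# Model: lambda_iso(x) = (lambda_A - lambda_B) / (1 + exp((x - x0)/k))
#                        + lambda_B,  k > 0
# lambda_A is the upper (small-spacing) limit, lambda_B the lower limit,
# x0 the inflection abscissa and k the slope factor; the predicted
# lambda_iso is strictly decreasing in x.

.sigmoidPredict <- function(par, x)
  (par[["lambda_A"]] - par[["lambda_B"]]) /
  (1 + exp((x - par[["x0"]]) / par[["k"]])) + par[["lambda_B"]]

.fitSigmoidCore <- function(x, y, weights, xname, min_points = 5L) {
  if (length(x) < min_points)
    stop("at least ", min_points,
         " calibration points spanning the transition are needed")
  if (is.null(weights)) weights <- rep(1, length(x))
  # initialization: limits from the data range, inflection at the steepest
  # numerical gradient, slope factor from the quartile spread
  o <- order(x)
  gr <- diff(y[o]) / diff(x[o])
  x0_init <- mean(x[o][which.min(gr) + 0:1])
  k_init <- max(stats::IQR(x) / 4, diff(range(x)) / 20)
  start <- list(lambda_A = max(y), lambda_B = min(y),
                x0 = x0_init, k = k_init)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (lambda_A - lambda_B) / (1 + exp((x - x0) / k)) + lambda_B,
      data = data.frame(x = x, y = y), start = start, weights = weights,
      lower = c(lambda_A = -Inf, lambda_B = -Inf, x0 = -Inf, k = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("sigmoid fit did not converge (start: ",
           paste(sprintf("%s=%.4g", names(start), unlist(start)),
                 collapse = ", "), "): ", conditionMessage(e)))
  par <- stats::coef(fit)
  if (par[["lambda_A"]] <= par[["lambda_B"]])
    stop("fitted upper limit does not exceed the lower limit; ",
         "data do not support a decreasing sigmoid")
  cov <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 4, 4, dimnames = list(names(par), names(par))))
  structure(list(par = par, cov = cov, fit = fit,
                 residuals = stats::residuals(fit),
                 data = data.frame(x = x, y = y), xname = xname),
            class = "SigmoidCalibration")
}

#' Fit the sigmoidal spacing calibration
#'
#' Nonlinear least squares of the four-parameter decreasing sigmoid
#' relating the isosbestic wavelength to the average interparticle
#' spacing.
#'
#' @param sp Average interparticle spacings (nm), at least 5 values
#'   spanning the transition.
#' @param lambda_iso Isosbestic wavelengths (nm).
#' @param weights Optional fit weights.
#' @return A `SigmoidCalibration` with elements `par`
#'   (`lambda_A, lambda_B, x0, k` — `x0` is the inflection spacing `sp0`),
#'   `cov` (parameter covariance), `residuals` and the underlying fit.
#' @examples
#' d <- generateCalibrationSet(noise_sd = 0)
#' cal <- fitSigmoid(d$sp, d$lambda_iso)
#' cal$par
#' @export
fitSigmoid <- function(sp, lambda_iso, weights = NULL)
  .fitSigmoidCore(sp, lambda_iso, weights, "sp")

#' @export
print.SigmoidCalibration <- function(x, ...) {
  se <- sqrt(diag(x$cov))
  cat(sprintf("SigmoidCalibration (abscissa: %s)\n", x$xname))
  for (nm in names(x$par))
    cat(sprintf("  %-9s %10.4f +- %.4f\n", nm, x$par[[nm]], se[[nm]]))
  invisible(x)
}

#' Predict the isosbestic wavelength from a calibration
#'
#' @param object A `SigmoidCalibration`.
#' @param newdata Abscissa values (spacing nm or stiffness N/m).
#' @param ... Unused.
#' @return Predicted wavelengths (nm).
#' @export
predict.SigmoidCalibration <- function(object, newdata, ...)
  .sigmoidPredict(object$par, newdata)

.invertSigmoidCore <- function(lambda_iso, cal, sigma_lambda) {
  p <- cal$par
  lA <- p[["lambda_A"]]; lB <- p[["lambda_B"]]
  x0 <- p[["x0"]]; k <- p[["k"]]
  if (any(lambda_iso <= lB) || any(lambda_iso >= lA))
    stop(sprintf(
      "lambda_iso outside the open calibration interval (%.3f, %.3f) nm",
      lB, lA))
  u <- (lA - lB) / (lambda_iso - lB) - 1
  x <- x0 + k * log(u)
  # first-order propagation: measurement variance plus parameter covariance
  dldu <- k / u
  g_lam <- dldu * (-(lA - lB) / (lambda_iso - lB)^2)
  g <- rbind(lambda_A = dldu / (lambda_iso - lB),
             lambda_B = dldu * (-1 / (lambda_iso - lB) +
                                  (lA - lB) / (lambda_iso - lB)^2),
             x0 = rep(1, length(lambda_iso)),
             k = log(u))
  varpar <- if (all(is.finite(cal$cov))) {
    vapply(seq_along(lambda_iso), function(i)
      drop(t(g[, i]) %*% cal$cov[rownames(g), rownames(g)] %*% g[, i]),
      numeric(1))
  } else rep(0, length(lambda_iso))
  list(x = x, sd = sqrt(pmax(varpar + (g_lam * sigma_lambda)^2, 0)))
}

#' Invert the spacing calibration
#'
#' Closed-form inverse of the sigmoid:
#' `sp = sp0 + k * log((lambda_A - lambda_B)/(lambda_iso - lambda_B) - 1)`,
#' with uncertainty from first-order propagation of the measurement error
#' and the parameter covariance. Values outside the open interval
#' `(lambda_B, lambda_A)` raise an out-of-calibration error (no clamping).
#'
#' @param lambda_iso Measured isosbestic wavelength(s), nm.
#' @param cal A `SigmoidCalibration` from [fitSigmoid()].
#' @param sigma_lambda Standard error of `lambda_iso` in nm (default 0).
#' @return List with `sp` (nm) and `sd` (nm).
#' @export
invertSigmoid <- function(lambda_iso, cal, sigma_lambda = 0) {
  stopifnot(inherits(cal, "SigmoidCalibration"))
  r <- .invertSigmoidCore(lambda_iso, cal, sigma_lambda)
  list(sp = r$x, sd = r$sd)
}

#' Fit the membrane-stiffness calibration
#'
#' Same sigmoid family with membrane stiffness as the abscissa: soft
#' vesicles produce compact clusters (small spacing, red isosbestic),
#' stiff vesicles loose clusters (larger spacing, blue isosbestic), so
#' `lambda_iso` decreases monotonically with stiffness.
#'
#' @param stiffness Membrane stiffness values (N/m), at least 4, with a
#'   monotone decreasing `lambda_iso` trend.
#' @param lambda_iso Isosbestic wavelengths (nm).
#' @param weights Optional fit weights.
#' @return A `StiffnessCalibration` (inherits `SigmoidCalibration`).
#' @export
fitStiffnessMap <- function(stiffness, lambda_iso, weights = NULL) {
  if (length(stiffness) < 4L) stop("at least 4 calibration pairs required")
  tau <- stats::cor(stiffness, lambda_iso, method = "kendall")
  if (is.na(tau) || tau > -0.3)
    stop("lambda_iso does not decrease monotonically with stiffness ",
         "beyond noise tolerance; calibration refused")
  cal <- .fitSigmoidCore(stiffness, lambda_iso, weights, "stiffness",
                         min_points = 4L)
  class(cal) <- c("StiffnessCalibration", class(cal))
  cal
}

#' Invert the stiffness calibration
#'
#' @param lambda_iso Measured isosbestic wavelength(s), nm, strictly
#'   inside the open interval between the fitted asymptotes.
#' @param cal A `StiffnessCalibration`.
#' @param sigma_lambda Standard error of `lambda_iso` (nm).
#' @return List with `stiffness` (N/m) and `sd`.
#' @export
invertStiffness <- function(lambda_iso, cal, sigma_lambda = 0) {
  stopifnot(inherits(cal, "StiffnessCalibration"))
  r <- .invertSigmoidCore(lambda_iso, cal, sigma_lambda)
  list(stiffness = r$x, sd = r$sd)
}

#' Write / read a calibration as key/value text
#'
#' Flat `key value` lines: the four parameters, the abscissa name and the
#' row-major parameter covariance.
#'
#' @param cal A `SigmoidCalibration`.
#' @param path File path.
#' @return `readCalibration` returns the calibration object (without the
#'   original fit object).
#' @export
writeCalibration <- function(cal, path) {
  stopifnot(inherits(cal, "SigmoidCalibration"))
  ln <- c(sprintf("xname %s", cal$xname),
          sprintf("class %s", class(cal)[1L]),
          sprintf("%s %.15g", names(cal$par), cal$par),
          sprintf("cov %s", paste(sprintf("%.15g", as.vector(cal$cov)),
                                  collapse = " ")))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, " +")
  keys <- vapply(kv, `[[`, "", 1L)
  val <- function(key) kv[[match(key, keys)]][-1L]
  par <- vapply(c("lambda_A", "lambda_B", "x0", "k"),
                function(k) as.numeric(val(k)[1L]), numeric(1))
  cov <- matrix(as.numeric(val("cov")), 4, 4,
                dimnames = list(names(par), names(par)))
  out <- structure(list(par = par, cov = cov, fit = NULL,
                        residuals = NULL, data = NULL,
                        xname = val("xname")[1L]),
                   class = "SigmoidCalibration")
  if (val("class")[1L] == "StiffnessCalibration")
    class(out) <- c("StiffnessCalibration", class(out))
  out
}
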