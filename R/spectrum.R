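#' Optical spectrum container
#'
#' A `Spectrum` holds per-wavelength values of an optical quantity on a
#' strictly increasing wavelength grid (nm). The value channel is either a
#' cross section (`"extinction"`, `"absorption"`, `"scattering"`, in nm^2)
#' or a dimensionless `"absorbance"`.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param value Numeric vector of the same length; finite. Cross-section
#'   channels must be non-negative.
#' @param channel Character label of the value channel.
#' @param normalized Logical; `TRUE` when the spectrum has been divided by
#'   its value at the 350 nm anchor.
#' @return An object of class `Spectrum`.
#' @examples
#' s <- Spectrum(400:500, exp(-((400:500 - 450)/20)^2), channel = "absorbance")
#' print(s)
#' @export
Spectrum <- function(wavelength, value,
                     channel = c("extinction", "absorption", "scattering",
                                 "absorbance"),
                     normalized = FALSE) {
  channel <- match.arg(channel)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have the same length")
  if (length(wavelength) < 2L)
    stop("a Spectrum needs at least 2 samples")
  if (any(!is.finite(wavelength)) || any(diff(wavelength) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  if (any(!is.finite(value)))
    stop("spectrum values must be finite")
  if (channel != "absorbance" && any(value < -1e-9 * max(abs(value), 1)))
    stop("cross sections must be non-negative")
  structure(list(wavelength = wavelength, value = value,
                 channel = channel, normalized = isTRUE(normalized)),
            class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d points, %.6g-%.6g nm, channel '%s'%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$channel, if (x$normalized) " (normalized at 350 nm)" else ""))
  cat(sprintf("  value range: %.4g to %.4g\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.Spectrum <- function(x, ...) {
  data.frame(wavelength = x$wavelength, value = x$value)
}

#' @export
plot.Spectrum <- function(x, ..., xlab = "wavelength (nm)", ylab = x$channel,
                          type = "l") {
  graphics::plot(x$wavelength, x$value, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Interpolate a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the target grid must lie within the source range.
#'
#' @param spectrum A [Spectrum].
#' @param wavelength Target grid (nm), strictly increasing.
#' @return A [Spectrum] on the new grid.
#' @export
resampleSpectrum <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "Spectrum"))
  if (min(wavelength) < min(spectrum$wavelength) - 1e-9 ||
      max(wavelength) > max(spectrum$wavelength) + 1e-9)
    stop("target grid extends outside the spectrum's wavelength range")
  v <- stats::approx(spectrum$wavelength, spectrum$value, xout = wavelength)$y
  Spectrum(wavelength, v, channel = spectrum$channel,
           normalized = spectrum$normalized)
}

#' Normalize a spectrum at the 350 nm anchor
#'
#' Divides all values by the value at the grid point nearest to `at`
#' (within `tol` nm), the standard pre-processing for experimental UV-vis
#' extinction spectra before cross-sample comparison.
#'
#' @param spectrum A [Spectrum].
#' @param at Anchor wavelength in nm (default 350).
#' @param tol Maximum distance (nm) between `at` and the nearest grid point.
#' @return The normalized [Spectrum] (channel becomes `"absorbance"`).
#' @export
normalizeSpectrum <- function(spectrum, at = 350, tol = 1) {
  stopifnot(inherits(spectrum, "Spectrum"))
  i <- which.min(abs(spectrum$wavelength - at))
  if (abs(spectrum$wavelength[i] - at) > tol)
    stop(sprintf("no grid point within %g nm of the %g nm anchor", tol, at))
  v0 <- spectrum$value[i]
  if (!is.finite(v0) || v0 == 0)
    stop("anchor value is zero; cannot normalize")
  Spectrum(spectrum$wavelength, spectrum$value / v0,
           channel = "absorbance", normalized = TRUE)
}

# shared-grid check used by every two-spectrum operation
sameGrid <- function(a, b, tol = 1e-9) {
  length(a$wavelength) == length(b$wavelength) &&
    max(abs(a$wavelength - b$wavelength)) <= tol
}
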