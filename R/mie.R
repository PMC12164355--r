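# Mie theory for an isolated gold nanosphere and spectral peak utilities.

#' Incident irradiance of a plane wave
#'
#' `I = E0^2 / (2 Z0)` for field amplitude `E0` (V/m) and system impedance
#' `Z0` (Ohm).
#'
#' @param E0 Incident field amplitude in V/m (`>= 0`).
#' @param Z0 Impedance in Ohm (default free-space 376.73).
#' @return Irradiance in W/m^2.
#' @examples
#' incidentIrradiance(1e5)  # 1.33e7 W/m^2
#' @export
incidentIrradiance <- function(E0, Z0 = 376.73) {
  if (any(E0 < 0)) stop("E0 must be non-negative")
  if (any(Z0 <= 0)) stop("Z0 must be positive")
  E0^2 / (2 * Z0)
}

# Mie coefficients a_n, b_n for one size parameter / relative index,
# log-derivative downward recurrence (Bohren-Huffman scheme).
.mieCoefs <- function(x, m, nmax) {
  nmx <- nmax + 16L
  mx <- m * x
  # downward recurrence for the logarithmic derivative D_n(mx);
  # after step i the value is D_{i-1}, stored so that D[n+1] = D_n
  D <- complex(length.out = nmax + 1L)
  Dn <- 0 + 0i
  for (i in nmx:1) {
    Dn <- i / mx - 1 / (Dn + i / mx)
    if (i <= nmax + 1L) D[i] <- Dn
  }
  a <- b <- complex(length.out = nmax)
  psi0 <- cos(x); psi1 <- sin(x)
  chi0 <- -sin(x); chi1 <- cos(x)
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi1 - psi0
    chi <- (2 * n - 1) / x * chi1 - chi0
    xi <- complex(real = psi, imaginary = -chi)
    xi1 <- complex(real = psi1, imaginary = -chi1)
    Dn <- D[n + 1L]
    da <- Dn / m + n / x
    db <- Dn * m + n / x
    a[n] <- (da * psi - psi1) / (da * xi - xi1)
    b[n] <- (db * psi - psi1) / (db * xi - xi1)
    psi0 <- psi1; psi1 <- psi
    chi0 <- chi1; chi1 <- chi
  }
  list(a = a, b = b)
}

#' Mie cross sections of an isolated gold nanosphere
#'
#' Full multipole Mie solution for a homogeneous sphere in a lossless
#' medium. The series is truncated at the size-adaptive Wiscombe order
#' `nmax = ceiling(x + 4 x^(1/3) + 2)`.
#'
#' @param radius_nm Sphere radius in nm (`> 0`).
#' @param medium A [Medium].
#' @param wavelength Wavelength grid in nm (default 400-800 nm, 1 nm step).
#' @param model Dielectric model for the sphere material.
#' @return A list with [Spectrum] elements `absorption`, `scattering`,
#'   `extinction` (cross sections in nm^2) and the truncation order `nmax`.
#' @examples
#' xs <- mieCrossSections(6, Medium(1.343), seq(480, 560, 2))
#' peakWavelengths(xs$extinction)
#' @export
mieCrossSections <- function(radius_nm, medium = Medium(),
                             wavelength = seq(400, 800, by = 1),
                             model = goldDielectric()) {
  stopifnot(radius_nm > 0, inherits(medium, "Medium"))
  eps <- goldPermittivity(wavelength, model)
  nmed <- medium$n
  xs <- 2 * pi * nmed * radius_nm / wavelength
  nmax <- max(3L, ceiling(max(xs) + 4 * max(xs)^(1 / 3) + 2))
  if (nmax > 150L)
    stop("Mie series does not converge at the documented maximum order; ",
         "radius too large for this solver")
  cext <- csca <- numeric(length(wavelength))
  for (i in seq_along(wavelength)) {
    m <- sqrt(eps[i]) / nmed
    x <- xs[i]
    cf <- .mieCoefs(x, m, nmax)
    n <- seq_len(nmax)
    k <- 2 * pi * nmed / wavelength[i]
    cext[i] <- 2 * pi / k^2 * sum((2 * n + 1) * Re(cf$a + cf$b))
    csca[i] <- 2 * pi / k^2 * sum((2 * n + 1) * (Mod(cf$a)^2 + Mod(cf$b)^2))
  }
  cabs <- pmax(cext - csca, 0)
  list(absorption = Spectrum(wavelength, cabs, "absorption"),
       scattering = Spectrum(wavelength, csca, "scattering"),
       extinction = Spectrum(wavelength, cabs + csca, "extinction"),
       nmax = nmax)
}

#' Locate spectral peaks
#'
#' Finds local maxima with relative prominence at least `min_prominence`
#' (as a fraction of the spectrum maximum) and refines each position by a
#' quadratic fit through the three samples around the maximum. A monotone
#' or flat spectrum yields an empty result.
#'
#' @param spectrum A [Spectrum] with at least 5 samples.
#' @param min_prominence Minimum prominence as a fraction of the spectrum
#'   maximum (default 0.02).
#' @return A data frame with columns `wavelength` (nm, sub-grid refined)
#'   and `prominence` (same units as the spectrum values), sorted by
#'   wavelength.
#' @export
peakWavelengths <- function(spectrum, min_prominence = 0.02) {
  stopifnot(inherits(spectrum, "Spectrum"))
  w <- spectrum$wavelength; v <- spectrum$value
  n <- length(v)
  if (n < 5L) stop("spectrum needs at least 5 samples")
  out <- data.frame(wavelength = numeric(0), prominence = numeric(0))
  if (max(v) == min(v)) return(out)
  imax <- which(diff(sign(diff(v))) < 0) + 1L
  if (!length(imax)) return(out)
  for (i in imax) {
    # classic prominence: walk out each side until a higher point, take the
    # lowest valley on the higher of the two sides
    left <- v[seq_len(i - 1L)]
    right <- v[seq.int(i + 1L, n)]
    hleft <- which(left > v[i])
    vleft <- if (length(hleft)) min(left[seq.int(max(hleft), i - 1L)]) else min(left)
    hright <- which(right > v[i])
    vright <- if (length(hright)) min(right[seq_len(min(hright))]) else min(right)
    prom <- v[i] - max(vleft, vright)
    if (prom < min_prominence * max(v)) next
    # quadratic refinement through the 3 points around the maximum
    y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
    x1 <- w[i - 1L]; x2 <- w[i]; x3 <- w[i + 1L]
    denom <- (y1 - 2 * y2 + y3)
    wpk <- if (abs(denom) > 0) {
      # uniform-grid vertex formula generalized to possibly uneven spacing
      d21 <- x2 - x1; d32 <- x3 - x2
      if (abs(d32 - d21) < 1e-9) {
        x2 + 0.5 * d21 * (y1 - y3) / denom
      } else {
        # exact parabola vertex through the three points
        aa <- ((y3 - y2) / d32 - (y2 - y1) / d21) / (d32 + d21) * 2
        bb <- (y3 - y2) / d32 - aa * (x3 + x2) / 2
        -bb / aa
      }
    } else x2
    out <- rbind(out, data.frame(wavelength = wpk, prominence = prom))
  }
  out[order(out$wavelength), , drop = FALSE]
}
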