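# Plain-text readers and writers for spectra and SAXS profiles, and the
# resolved run configuration embedded in analysis outputs.

#' Read a spectrum from two-column delimited text
#'
#' Lines starting with `#` are comments; columns are wavelength (nm) and
#' value, whitespace- or comma-separated. Wavelengths are sorted
#' ascending; duplicates are rejected with the offending line number.
#'
#' @param path File path.
#' @param channel Value channel label.
#' @param normalize Divide by the value at the 350 nm anchor
#'   (nearest grid point within 1 nm) after reading.
#' @return A [Spectrum].
#' @export
readSpectrum <- function(path, channel = "absorbance", normalize = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  txt <- gsub(",", " ", lines[keep])
  parts <- strsplit(trimws(txt), "[[:space:]]+")
  bad <- which(vapply(parts, function(p)
    length(p) < 2L || anyNA(suppressWarnings(as.numeric(p[1:2]))), TRUE))
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: non-numeric content",
                 rows[bad[1L]], path))
  w <- vapply(parts, function(p) as.numeric(p[1L]), numeric(1))
  v <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1))
  if (length(w) < 5L)
    stop("a spectrum file needs at least 5 data rows")
  o <- order(w)
  w <- w[o]; v <- v[o]
  if (any(diff(w) == 0)) {
    i <- which(diff(w) == 0)[1L]
    stop(sprintf("duplicate wavelength %.6g (line %d)", w[i],
                 rows[o[i + 1L]]))
  }
  s <- Spectrum(w, v, channel = channel)
  if (normalize) s <- normalizeSpectrum(s)
  s
}

#' Write a spectrum as two-column delimited text
#'
#' The header comment names the value channel.
#'
#' @param spectrum A [Spectrum].
#' @param path File path.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "Spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# channel %s%s", spectrum$channel,
                       if (spectrum$normalized) " (normalized at 350 nm)"
                       else ""),
               "# wavelength_nm value"), con)
  utils::write.table(
    data.frame(w = sprintf("%.15g", spectrum$wavelength),
               v = sprintf("%.15g", spectrum$value)),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write SAXS profiles as delimited text
#'
#' Two or three columns `Q I [dI]`, whitespace- or comma-separated, `#`
#' comments. The Q unit is taken from `q_unit`, or sniffed from a header
#' comment containing `1/A`, `A^-1` or `nm^-1` when `q_unit = "auto"`.
#'
#' @param path File path.
#' @param q_unit `"auto"`, `"nm^-1"` or `"A^-1"`.
#' @return A [SAXSProfile] (Q in 1/nm).
#' @export
readSAXSProfile <- function(path, q_unit = c("auto", "nm^-1", "A^-1")) {
  q_unit <- match.arg(q_unit)
  lines <- readLines(path)
  hdr <- grep("^[[:space:]]*#", lines, value = TRUE)
  if (q_unit == "auto") {
    q_unit <- if (any(grepl("1/A|A\\^-1|Ang", hdr))) "A^-1" else "nm^-1"
  }
  txt <- gsub(",", " ", lines[!grepl("^[[:space:]]*#", lines)])
  m <- utils::read.table(text = txt)
  SAXSProfile(m[[1L]], m[[2L]],
              dI = if (ncol(m) >= 3L) m[[3L]] else NULL,
              q_unit = q_unit)
}

#' @rdname readSAXSProfile
#' @param profile A [SAXSProfile].
#' @export
writeSAXSProfile <- function(profile, path) {
  stopifnot(inherits(profile, "SAXSProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Q_nm^-1 I dI", ""), con)
  df <- data.frame(Q = sprintf("%.15g", profile$Q),
                   I = sprintf("%.15g", profile$I))
  if (!is.null(profile$dI)) df$dI <- sprintf("%.15g", profile$dI)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Resolved run configuration
#'
#' Collects the analysis settings so every output can embed the full
#' configuration it was produced with (auditability: a result directory
#' is regenerable from its embedded config and seed alone).
#'
#' @param medium_index Medium refractive index.
#' @param wavelength Wavelength grid (nm).
#' @param window Isosbestic crossing window (nm).
#' @param dispersion_threshold Isosbestic dispersion threshold (nm).
#' @param ai_definition Aggregation-index definition.
#' @param eps_rule Well-width convention for the pair potential.
#' @param sigma_hc Hard-core diameter (nm).
#' @param seed RNG seed.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(medium_index = 1.343,
                      wavelength = seq(400, 800, by = 1),
                      window = c(450, 650), dispersion_threshold = 1.5,
                      ai_definition = "band_ratio",
                      eps_rule = "sp/(sigma_hc+sp)", sigma_hc = 13.8,
                      seed = 1) {
  structure(list(medium_index = medium_index,
                 wavelength_min = min(wavelength),
                 wavelength_max = max(wavelength),
                 wavelength_step = if (length(wavelength) > 1)
                   wavelength[2] - wavelength[1] else NA_real_,
                 window = window,
                 dispersion_threshold = dispersion_threshold,
                 ai_definition = ai_definition, eps_rule = eps_rule,
                 sigma_hc = sigma_hc, seed = seed),
            class = "RunConfig")
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  for (nm in names(x))
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
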