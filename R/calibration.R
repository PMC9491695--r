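# Per-band calibration of the camera/filter/lamp spectral response.
#
# A blank field-of-view acquisition together with a reference spectrometer
# reading of the lamp yields one multiplicative coefficient per band:
#   coefficient(lambda) = mean blank image intensity at lambda
#                         / spectrometer intensity at lambda .
# Calibration divides image intensities by the coefficient, so calibrating a
# blank acquisition of the same lamp flattens its spectral profile.

#' Construct a calibration table
#'
#' @param wavelengths band-centre wavelengths in nm, strictly increasing
#' @param coefficients unitless positive per-band multipliers
#' @param source provenance tag, `"blank_slide+spectrometer"` or `"unity"`
#' @return an object of class `calibration_table`
#' @export
calibration_table <- function(wavelengths, coefficients,
                              source = "blank_slide+spectrometer") {
  wavelengths <- as.numeric(wavelengths)
  coefficients <- as.numeric(coefficients)
  if (length(wavelengths) != length(coefficients))
    stopf("wavelengths (%d) and coefficients (%d) differ in length",
          length(wavelengths), length(coefficients))
  if (any(diff(wavelengths) <= 0))
    stopf("wavelength axis must be strictly increasing")
  if (!all(is.finite(coefficients)) || any(coefficients <= 0))
    stopf("calibration coefficients must be finite and > 0")
  structure(list(wavelengths = wavelengths, coefficients = coefficients,
                 source = source),
            class = "calibration_table")
}

#' Unity calibration (identity) for a wavelength axis
#' @param wavelengths band-centre wavelengths in nm
#' @return a `calibration_table` of all-ones coefficients
#' @export
unity_calibration <- function(wavelengths) {
  calibration_table(wavelengths, rep(1, length(wavelengths)),
                    source = "unity")
}

#' Estimate calibration coefficients from a blank acquisition
#'
#' Divides the per-band mean intensity of a blank-FOV hypercube by the
#' spectrometer reading of the lamp, linearly interpolated onto the cube's
#' wavelength axis.
#'
#' @param blank_cube a [hypercube()] of a blank (tissue-free) field of view
#' @param spectrometer two-column data.frame or matrix
#'   `(wavelength_nm, intensity)`; must cover the cube's axis with positive
#'   intensities
#' @return a [calibration_table()]
#' @export
estimate_coefficients <- function(blank_cube, spectrometer) {
  stopifnot(inherits(blank_cube, "hypercube"))
  spectrometer <- as.matrix(spectrometer)
  if (ncol(spectrometer) < 2L)
    stopf("spectrometer table needs columns (wavelength_nm, intensity)")
  sw <- spectrometer[, 1]; si <- spectrometer[, 2]
  wl <- blank_cube$wavelengths
  if (min(wl) < min(sw) || max(wl) > max(sw))
    stopf(paste0("spectrometer coverage gap: cube spans %g-%g nm but ",
                 "readings span %g-%g nm"),
          min(wl), max(wl), min(sw), max(sw))
  needed <- sw >= min(wl) - max(diff(sw)) & sw <= max(wl) + max(diff(sw))
  if (any(si[needed] <= 0) || any(!is.finite(si[needed])))
    stopf("spectrometer intensity is zero/negative at a needed wavelength (%g nm)",
          sw[needed][which(si[needed] <= 0 | !is.finite(si[needed]))[1]])
  ref <- approx(sw, si, xout = wl)$y
  band_means <- apply(blank_cube$data, 3L, mean)
  calibration_table(wl, band_means / ref)
}

#' Apply a calibration table
#'
#' Divides each band (of a hypercube) or each element (of a spectrum) by its
#' calibration coefficient. Wavelength axes must match exactly.
#'
#' @param x a [hypercube()] or a numeric per-band spectrum
#' @param table a [calibration_table()]
#' @return the calibrated object, same class as `x`
#' @export
apply_calibration <- function(x, table) {
  stopifnot(inherits(table, "calibration_table"))
  if (inherits(x, "hypercube")) {
    if (!isTRUE(all.equal(x$wavelengths, table$wavelengths)))
      stopf("wavelength axis mismatch between hypercube and calibration table")
    data <- sweep(x$data, 3L, table$coefficients, `/`)
    return(hypercube(data, x$wavelengths, x$meta))
  }
  if (is.numeric(x)) {
    if (length(x) != length(table$coefficients))
      stopf("spectrum length (%d) does not match table (%d)",
            length(x), length(table$coefficients))
    return(x / table$coefficients)
  }
  stopf("`x` must be a hypercube or a numeric spectrum")
}

#' Write / read a calibration table as two-column CSV
#' @param table a [calibration_table()]
#' @param path CSV path with columns `wavelength_nm, coefficient`
#' @return `read_calibration` returns a `calibration_table`;
#'   `write_calibration` returns `path` invisibly
#' @export
write_calibration <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  write.csv(data.frame(wavelength_nm = table$wavelengths,
                       coefficient = table$coefficients),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  df <- read.csv(path)
  calibration_table(df$wavelength_nm, df$coefficient)
}
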