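# Hypercube container and multi-page TIFF I/O with a wavelength sidecar.

#' Construct a hypercube
#'
#' A hypercube is a 3-D intensity array `(rows, cols, bands)` together with a
#' strictly increasing wavelength axis in nanometres, the `(x, y, lambda)`
#' datacube of transmission hyperspectral microscopy.
#'
#' @param data numeric array `(rows, cols, bands)` of non-negative finite
#'   intensities
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per band
#' @param meta named list of free-form acquisition notes
#' @return an object of class `hypercube`
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3-D array (rows, cols, bands)")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)) || any(data < 0))
    stopf("hypercube intensities must be finite and >= 0")
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stopf("band count (%d) does not match wavelength count (%d)",
          dim(data)[3], length(wavelengths))
  if (any(diff(wavelengths) <= 0))
    stopf("wavelength axis must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hypercube: %d x %d px, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Build an acquisition wavelength axis
#'
#' Inclusive arithmetic sequence of band centres; the default acquisition
#' covers 420-720 nm in 2 nm steps, i.e. 151 bands.
#'
#' @param start_nm,stop_nm axis endpoints in nm, `stop_nm > start_nm`
#' @param step_nm scanning step in nm; must divide `stop_nm - start_nm`
#' @return numeric vector of wavelengths, length `(stop-start)/step + 1`
#' @examples
#' length(band_axis(420, 720, 2)) # 151
#' @export
band_axis <- function(start_nm = 420, stop_nm = 720, step_nm = 2) {
  assert_scalar_number(start_nm, "start_nm")
  assert_scalar_number(stop_nm, "stop_nm")
  assert_scalar_number(step_nm, "step_nm")
  if (stop_nm <= start_nm) stopf("stop_nm must exceed start_nm")
  if (step_nm <= 0) stopf("step_nm must be > 0")
  n <- (stop_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-9)
    stopf("(stop_nm - start_nm) = %g is not divisible by step_nm = %g",
          stop_nm - start_nm, step_nm)
  seq(start_nm, stop_nm, by = step_nm)
}

#' Load a hypercube from a multi-page TIFF and a wavelength sidecar
#'
#' Each page of the TIFF stack is one spectral band; the sidecar is a plain
#' text file with one wavelength (nm) per line mapping, in order, to the TIFF
#' pages. Integer TIFF data are read as raw counts (uint8/uint16).
#'
#' @param tiff_path path to the multi-page grayscale TIFF stack
#' @param wavelength_path path to the wavelength sidecar text file
#' @return a [hypercube()]
#' @export
load_hypercube <- function(tiff_path, wavelength_path) {
  if (!file.exists(tiff_path)) stopf("TIFF file not found: %s", tiff_path)
  if (!file.exists(wavelength_path))
    stopf("wavelength sidecar not found: %s", wavelength_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  wl <- as.numeric(readLines(wavelength_path))
  wl <- wl[!is.na(wl)]
  if (length(pages) != length(wl))
    stopf("%s: page count (%d) does not match wavelength count (%d) in %s",
          tiff_path, length(pages), length(wl), wavelength_path)
  if (any(diff(wl) <= 0))
    stopf("%s: wavelength axis must be strictly increasing", wavelength_path)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L)
      stopf("%s: page %d is not single-channel grayscale", tiff_path, i)
  }
  d <- dim(pages[[1]])
  data <- array(0, c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d))
      stopf("%s: page %d geometry differs from page 1", tiff_path, i)
    data[, , i] <- pages[[i]]
  }
  hypercube(data, wl, meta = list(source = tiff_path))
}

#' Write a hypercube as a multi-page TIFF plus wavelength sidecar
#'
#' Intensities are stored as 16-bit grayscale pages (values are clipped to
#' `[0, 65535]` and rounded); the write/read round trip is lossless for
#' integer data in that range.
#'
#' @param cube a [hypercube()]
#' @param tiff_path,wavelength_path output paths
#' @return invisibly, `tiff_path`
#' @export
write_hypercube <- function(cube, tiff_path, wavelength_path) {
  stopifnot(inherits(cube, "hypercube"))
  vals <- clamp(round(cube$data), 0, 65535)
  pages <- lapply(seq_along(cube$wavelengths),
                  function(i) vals[, , i] / 65535)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  writeLines(format(cube$wavelengths, trim = TRUE, scientific = FALSE),
             wavelength_path)
  invisible(tiff_path)
}
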