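# Region-averaged spectral signatures: extraction, normalization,
# categorization, and strip scanning.
#
# A region spectrum is the per-band mean intensity over a selected pixel
# region (at least 3 pixels), calibrated and then peak-normalized (value 1
# at its maximum). Categorization scores two features of the known
# signatures: the ptau "flat hat" (elevated, flat transmittance over
# 550-650 nm) and the abeta transmission dip over 450-600 nm.

#' Extract a calibrated, peak-normalized region spectrum
#'
#' @param cube a [hypercube()]
#' @param region integer matrix with two columns `(row, col)`; at least 3
#'   pixels, all inside the cube
#' @param table a [calibration_table()] on the cube's axis
#' @param label free-text class label to attach
#' @param normalize `"peak"` (default; value 1 at the spectrum's maximum,
#'   the convention signatures are defined on) or `"area"` (unit mean over
#'   the imaging range)
#' @return an object of class `region_spectrum` with fields `label`,
#'   `pixel_count`, `raw` (uncalibrated per-band means),
#'   `calibrated_normalized` (peak value exactly 1 under peak
#'   normalization), `wavelengths`, `region`
#' @export
extract_region_spectrum <- function(cube, region, table = NULL,
                                    label = "unlabeled",
                                    normalize = c("peak", "area")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(cube, "hypercube"))
  region <- rbind(region)
  storage.mode(region) <- "integer"
  if (ncol(region) != 2L) stopf("`region` must have columns (row, col)")
  if (nrow(region) < 3L)
    stopf("region has %d pixel(s); a minimum of 3 pixels is required",
          nrow(region))
  d <- dim(cube$data)
  if (any(region[, 1] < 1 | region[, 1] > d[1] |
          region[, 2] < 1 | region[, 2] > d[2]))
    stopf("region contains out-of-bounds pixels for a %d x %d image",
          d[1], d[2])
  if (is.null(table)) table <- unity_calibration(cube$wavelengths)
  stopifnot(inherits(table, "calibration_table"))
  if (!isTRUE(all.equal(cube$wavelengths, table$wavelengths)))
    stopf("wavelength axis mismatch between cube and calibration table")
  B <- d[3]
  raw <- vapply(seq_len(B),
                function(b) mean(cube$data[, , b][region]), numeric(1))
  cal <- raw / table$coefficients
  ref <- if (normalize == "peak") max(cal) else mean(cal)
  if (ref <= 0) stopf("region spectrum has non-positive peak; cannot normalize")
  structure(list(label = label, pixel_count = nrow(region), raw = raw,
                 calibrated_normalized = cal / ref,
                 wavelengths = cube$wavelengths, region = region),
            class = "region_spectrum")
}

#' @export
print.region_spectrum <- function(x, ...) {
  cat(sprintf("region spectrum '%s': %d px, %d bands, peak %g nm\n",
              x$label, x$pixel_count, length(x$raw),
              x$wavelengths[which.max(x$calibrated_normalized)]))
  invisible(x)
}

band_window_mean <- function(values, wavelengths, lo, hi) {
  sel <- wavelengths >= lo & wavelengths <= hi
  mean(values[sel])
}

#' Default categorization thresholds
#'
#' `flatness_min`: minimum flat-hat flatness (1 - CV over 550-650 nm) for
#' ptau. `plateau_contrast_min`: minimum ratio of the 550-650 nm mean to the
#' off-plateau mean (450-500 and 660-720 nm) for ptau; this internally
#' referenced contrast is used because peak normalization pins any spectrum
#' peaking inside the plateau to ~1, making cross-spectrum level ratios
#' uninformative. `dip_min`: minimum abeta dip score
#' (1 - mean(450-600)/mean(600-700)).
#'
#' @return named list of thresholds
#' @export
categorize_defaults <- function() {
  list(flatness_min = 0.95, plateau_contrast_min = 1.32, dip_min = 0.10)
}

#' Categorize a normalized spectrum as abeta, ptau, or control
#'
#' Computes three feature scores on the peak-normalized spectrum:
#' * `flatness` = 1 - CV over 550-650 nm (1 for a perfectly flat hat);
#' * `plateau_contrast` = mean(550-650 nm) / mean(450-500 and 660-720 nm);
#' * `dip` = 1 - mean(450-600 nm) / mean(600-700 nm).
#'
#' A spectrum is `ptau` when flatness and plateau contrast both exceed their
#' thresholds, otherwise `abeta` when the dip score does, otherwise
#' `control`.
#'
#' @param s a [extract_region_spectrum()] result, or a numeric normalized
#'   spectrum (then `wavelengths` must be given)
#' @param thresholds list as in [categorize_defaults()]
#' @param wavelengths axis in nm when `s` is a bare numeric vector
#' @return list with `category` and the three feature `scores`
#' @export
categorize_spectrum <- function(s, thresholds = categorize_defaults(),
                                wavelengths = NULL) {
  if (inherits(s, "region_spectrum")) {
    v <- s$calibrated_normalized
    wavelengths <- s$wavelengths
  } else {
    v <- as.numeric(s)
    if (is.null(wavelengths))
      stopf("`wavelengths` required for a bare numeric spectrum")
  }
  if (min(wavelengths) > 450 || max(wavelengths) < 700)
    stopf("spectrum bands must cover 450-700 nm (got %g-%g nm)",
          min(wavelengths), max(wavelengths))
  hat <- v[wavelengths >= 550 & wavelengths <= 650]
  flatness <- 1 - sd(hat) / mean(hat)
  off <- c(v[wavelengths >= 450 & wavelengths <= 500],
           v[wavelengths >= 660 & wavelengths <= 720])
  plateau_contrast <- mean(hat) / mean(off)
  dip <- 1 - band_window_mean(v, wavelengths, 450, 600) /
    band_window_mean(v, wavelengths, 600, 700)
  category <- if (flatness > thresholds$flatness_min &&
                  plateau_contrast > thresholds$plateau_contrast_min) {
    "ptau"
  } else if (dip > thresholds$dip_min) {
    "abeta"
  } else {
    "control"
  }
  list(category = category,
       scores = c(flatness = flatness, plateau_contrast = plateau_contrast,
                  dip = dip))
}

#' Scan a hypercube with a window grid and categorize each window
#'
#' Tiles the cube with `window` x `window` regions spaced `stride` pixels
#' apart, extracts each region's calibrated normalized spectrum, and
#' categorizes it. Windows are matched with their occurrence coordinates.
#'
#' @param cube a [hypercube()]
#' @param stride grid spacing in px (>= 1)
#' @param table a [calibration_table()] (default unity)
#' @param window square window side in px (default 5; window area must
#'   cover at least 3 px)
#' @param thresholds categorization thresholds
#' @return data.frame with columns `row`, `col` (window top-left),
#'   `category`, `flatness`, `plateau_contrast`, `dip`
#' @export
scan_strip <- function(cube, stride, table = NULL, window = 5L,
                       thresholds = categorize_defaults()) {
  stopifnot(inherits(cube, "hypercube"))
  if (stride < 1) stopf("stride must be >= 1")
  window <- as.integer(window)
  if (window * window < 3L) stopf("window must contain at least 3 pixels")
  d <- dim(cube$data)
  if (is.null(table)) table <- unity_calibration(cube$wavelengths)
  row0 <- unique(pmin(seq(1L, d[1], by = stride), d[1] - window + 1L))
  col0 <- unique(pmin(seq(1L, d[2], by = stride), d[2] - window + 1L))
  row0 <- row0[row0 >= 1L]; col0 <- col0[col0 >= 1L]
  if (length(row0) == 0L) row0 <- 1L
  if (length(col0) == 0L) col0 <- 1L
  res <- vector("list", length(row0) * length(col0))
  k <- 1L
  for (r in row0) for (cc in col0) {
    px <- as.matrix(expand.grid(row = r:(r + window - 1L),
                                col = cc:(cc + window - 1L)))
    s <- extract_region_spectrum(cube, px, table)
    cat_res <- categorize_spectrum(s, thresholds)
    res[[k]] <- data.frame(row = r, col = cc, category = cat_res$category,
                           flatness = cat_res$scores[["flatness"]],
                           plateau_contrast =
                             cat_res$scores[["plateau_contrast"]],
                           dip = cat_res$scores[["dip"]])
    k <- k + 1L
  }
  do.call(rbind, res)
}

#' Export spectra to CSV
#' @param spectra list of `region_spectrum` objects
#' @param path output CSV with columns `wavelength_nm, value, label`
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "region_spectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(s)
    data.frame(wavelength_nm = s$wavelengths,
               value = s$calibrated_normalized, label = s$label))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
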