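# Principal-component compression of hypercubes to 3-channel images.
#
# Pixels are samples, bands are features. The top three principal
# components of the pixel-spectra covariance are mapped, in order, to the
# red, green and blue channels; each channel is min-max scaled to 8-bit
# with the scaling recorded so patches cut from one strip share a common
# mapping.

#' Fit a 3-component PCA basis on a hypercube's pixel spectra
#'
#' @param cube a [hypercube()]
#' @param crop optional `list(rows = range, cols = range)` keeping only a
#'   sub-window before fitting (e.g. trimming background so most pixels
#'   carry tissue spectra)
#' @return object of class `pca_basis`: `loadings` (bands x 3), `center`
#'   (per-band means), `explained_variance` (3 non-increasing fractions),
#'   `wavelengths`
#' @export
fit_pca <- function(cube, crop = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (d[3] < 3L) stopf("PCA needs at least 3 bands, got %d", d[3])
  data <- cube$data
  if (!is.null(crop))
    data <- data[crop$rows, crop$cols, , drop = FALSE]
  X <- matrix(data, ncol = d[3])  # pixels x bands
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  cv <- crossprod(Xc) / (nrow(Xc) - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  total <- sum(pmax(eig$values, 0))
  if (total <= 0 || sum(eig$values > 1e-12 * eig$values[1]) < 3L)
    stopf("fewer than 3 non-degenerate principal components (constant cube?)")
  loadings <- eig$vectors[, 1:3, drop = FALSE]
  # deterministic sign: largest-magnitude loading entry is positive
  for (k in 1:3) {
    m <- which.max(abs(loadings[, k]))
    if (loadings[m, k] < 0) loadings[, k] <- -loadings[, k]
  }
  structure(list(loadings = loadings, center = center,
                 explained_variance = eig$values[1:3] / total,
                 wavelengths = cube$wavelengths),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("PCA basis: %d bands -> 3 components, explained variance %s (cum %.1f%%)\n",
              nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = " + "),
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' Project a hypercube onto a PCA basis as an 8-bit RGB image
#'
#' PC1/PC2/PC3 scores go, in order, to the red, green and blue channels;
#' each channel is min-max scaled to `[0, 255]` with the offsets recorded in
#' `fit_stats`. A zero-variance (degenerate) channel maps to 0.
#'
#' @param cube a [hypercube()] on the basis' wavelength axis
#' @param basis a [fit_pca()] result
#' @param fit_stats optional recorded scaling from a previous projection of
#'   the same strip, so all its patches share one mapping
#' @return object of class `compressed_image`: `data` (H x W x 3 in
#'   `[0, 255]`), `explained_variance`, `fit_stats`
#' @export
project_to_rgb <- function(cube, basis, fit_stats = NULL) {
  stopifnot(inherits(cube, "hypercube"), inherits(basis, "pca_basis"))
  if (!isTRUE(all.equal(cube$wavelengths, basis$wavelengths)))
    stopf("wavelength axis mismatch between cube and PCA basis")
  d <- dim(cube$data)
  X <- matrix(cube$data, ncol = d[3])
  scores <- sweep(X, 2L, basis$center) %*% basis$loadings
  if (is.null(fit_stats)) {
    lo <- apply(scores, 2L, min); hi <- apply(scores, 2L, max)
    fit_stats <- list(lo = lo, hi = hi)
  }
  out <- array(0, c(d[1], d[2], 3L))
  for (k in 1:3) {
    span <- fit_stats$hi[k] - fit_stats$lo[k]
    ch <- if (span <= 0) {
      matrix(0, d[1], d[2])  # degenerate zero-variance channel
    } else {
      matrix(clamp((scores[, k] - fit_stats$lo[k]) / span, 0, 1) * 255,
             d[1], d[2])
    }
    out[, , k] <- ch
  }
  structure(list(data = out, channel_order = c("PC1" = "red", "PC2" = "green",
                                               "PC3" = "blue"),
                 explained_variance = basis$explained_variance,
                 fit_stats = fit_stats),
            class = "compressed_image")
}

#' @export
print.compressed_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("compressed image: %d x %d x 3 (PC1..3 -> RGB), cum. var %.1f%%\n",
              d[1], d[2], 100 * sum(x$explained_variance)))
  invisible(x)
}

#' Serialize / load a PCA basis and channel scaling
#' @param basis a `pca_basis`
#' @param fit_stats optional scaling list from [project_to_rgb()]
#' @param path JSON sidecar path
#' @export
write_pca_basis <- function(basis, path, fit_stats = NULL) {
  stopifnot(inherits(basis, "pca_basis"))
  payload <- list(loadings = basis$loadings, center = basis$center,
                  explained_variance = basis$explained_variance,
                  wavelengths = basis$wavelengths, fit_stats = fit_stats)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_basis
#' @export
read_pca_basis <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- structure(list(loadings = as.matrix(x$loadings),
                          center = as.numeric(x$center),
                          explained_variance = as.numeric(x$explained_variance),
                          wavelengths = as.numeric(x$wavelengths)),
                     class = "pca_basis")
  list(basis = basis, fit_stats = x$fit_stats)
}
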