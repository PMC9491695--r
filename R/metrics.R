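# Image-quality metrics: structural similarity (SSIM) and peak
# signal-to-noise ratio (PSNR), with per-model aggregation.
#
# The SSIM index between images i and j is
#
#   SSIM(i, j) = (2 mu_i mu_j + c1) (2 sigma_ij + c2)
#                / ((mu_i^2 + mu_j^2 + c1) (sigma_i^2 + sigma_j^2 + c2))
#
# with means mu, SDs sigma, covariance sigma_ij, and small regularization
# constants c1, c2 that stabilize the ratio when the moments are near zero.
# The default constants are c1 = (0.01 L)^2 and c2 = (0.03 L)^2 for dynamic
# range L. The index is 1 for identical images and near 0 for unrelated
# ones. The global mode evaluates the formula once over the whole image
# (one value per patch); the windowed mode averages a local index computed
# under a Gaussian window.

#' SSIM parameters
#'
#' @param dynamic_range intensity span `L` (255 for 8-bit images)
#' @param k1,k2 constants defining `c1 = (k1 L)^2`, `c2 = (k2 L)^2`
#' @param window `"global"` for one index over the whole patch, or
#'   `"gaussian"` for a local index averaged over the image
#' @param window_size,window_sigma Gaussian window geometry (used only for
#'   `window = "gaussian"`)
#' @return list of class `ssim_params`
#' @export
ssim_params <- function(dynamic_range = 255, k1 = 0.01, k2 = 0.03,
                        window = c("global", "gaussian"),
                        window_size = 11L, window_sigma = 1.5) {
  window <- match.arg(window)
  if (dynamic_range <= 0) stopf("dynamic_range must be > 0")
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  if (c1 <= 0 || c2 <= 0) stopf("regularization constants must be > 0")
  structure(list(dynamic_range = dynamic_range, c1 = c1, c2 = c2,
                 window = window, window_size = as.integer(window_size),
                 window_sigma = window_sigma), class = "ssim_params")
}

ssim_scalar <- function(i, j, c1, c2) {
  n <- length(i)
  mu_i <- mean(i); mu_j <- mean(j)
  # population moments (divide by n), matching the windowed estimator
  var_i <- sum((i - mu_i)^2) / n
  var_j <- sum((j - mu_j)^2) / n
  cov_ij <- sum((i - mu_i) * (j - mu_j)) / n
  ((2 * mu_i * mu_j + c1) * (2 * cov_ij + c2)) /
    ((mu_i^2 + mu_j^2 + c1) * (var_i + var_j + c2))
}

gaussian_kernel1d <- function(size, sigma) {
  half <- (size - 1) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable "same" convolution with replicated borders.
conv2_sep <- function(img, k) {
  half <- (length(k) - 1) / 2
  H <- nrow(img); W <- ncol(img)
  ridx <- clamp(outer(seq_len(H), seq(-half, half), `+`), 1, H)
  out <- matrix(0, H, W)
  for (s in seq_along(k)) out <- out + k[s] * img[ridx[, s], , drop = FALSE]
  img2 <- out
  cidx <- clamp(outer(seq_len(W), seq(-half, half), `+`), 1, W)
  out <- matrix(0, H, W)
  for (s in seq_along(k)) out <- out + k[s] * img2[, cidx[, s], drop = FALSE]
  out
}

ssim_channel <- function(i, j, params) {
  if (params$window == "global")
    return(ssim_scalar(as.numeric(i), as.numeric(j), params$c1, params$c2))
  k <- gaussian_kernel1d(params$window_size, params$window_sigma)
  mu_i <- conv2_sep(i, k); mu_j <- conv2_sep(j, k)
  var_i <- conv2_sep(i * i, k) - mu_i^2
  var_j <- conv2_sep(j * j, k) - mu_j^2
  cov_ij <- conv2_sep(i * j, k) - mu_i * mu_j
  num <- (2 * mu_i * mu_j + params$c1) * (2 * cov_ij + params$c2)
  den <- (mu_i^2 + mu_j^2 + params$c1) * (var_i + var_j + params$c2)
  mean(num / den)
}

as_image_array <- function(x) {
  if (inherits(x, "stain_image")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stopf("expected an image matrix or H x W x C array")
  x
}

#' Structural similarity index between two images
#'
#' Multi-channel images are scored per channel and averaged.
#'
#' @param i,j images of identical geometry (matrix, H x W x C array, or
#'   [stain_image()])
#' @param params a [ssim_params()]
#' @return SSIM value in `[-1, 1]`
#' @export
ssim <- function(i, j, params = ssim_params()) {
  i <- as_image_array(i); j <- as_image_array(j)
  if (!identical(dim(i), dim(j)))
    stopf("image geometry mismatch: %s vs %s",
          paste(dim(i), collapse = "x"), paste(dim(j), collapse = "x"))
  mean(vapply(seq_len(dim(i)[3]),
              function(ch) ssim_channel(i[, , ch], j[, , ch], params),
              numeric(1)))
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(peak^2 / MSE)`; identical images return `Inf`.
#'
#' @param i,j images of identical geometry
#' @param peak peak intensity (255 for 8-bit)
#' @return PSNR in dB
#' @export
psnr <- function(i, j, peak = 255) {
  i <- as_image_array(i); j <- as_image_array(j)
  if (!identical(dim(i), dim(j)))
    stopf("image geometry mismatch: %s vs %s",
          paste(dim(i), collapse = "x"), paste(dim(j), collapse = "x"))
  if (peak <= 0) stopf("peak must be > 0")
  mse <- mean((i - j)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Evaluate a model's predictions against ground truth
#'
#' Computes one SSIM and one PSNR value per patch and aggregates them as
#' mean and SD for the model group.
#'
#' @param pred_patches,truth_patches lists of matched patches
#' @param params a [ssim_params()]
#' @param model free-text model name
#' @param peak peak intensity for PSNR
#' @return object of class `model_report`: per-patch `ssim` and `psnr`
#'   vectors plus `ssim_mean`, `ssim_sd`, `psnr_mean`, `psnr_sd`
#' @export
evaluate_model <- function(pred_patches, truth_patches,
                           params = ssim_params(), model = "model",
                           peak = 255) {
  if (length(pred_patches) != length(truth_patches))
    stopf("prediction list (%d) and truth list (%d) differ in length",
          length(pred_patches), length(truth_patches))
  if (length(pred_patches) == 0L) stopf("empty patch lists")
  s <- mapply(function(p, t) ssim(p, t, params), pred_patches, truth_patches)
  p <- mapply(function(p, t) psnr(p, t, peak), pred_patches, truth_patches)
  structure(list(model = model, ssim = as.numeric(s), psnr = as.numeric(p),
                 ssim_mean = mean(s), ssim_sd = sd(s),
                 psnr_mean = mean(p), psnr_sd = sd(p),
                 params = params), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model report '%s' (%d patches, %s SSIM window)\n",
              x$model, length(x$ssim), x$params$window))
  cat(sprintf("  SSIM %.4f +/- %.4f\n", x$ssim_mean, x$ssim_sd))
  cat(sprintf("  PSNR %.2f +/- %.2f dB\n", x$psnr_mean, x$psnr_sd))
  invisible(x)
}

#' Write a model report (per-patch and summary CSVs)
#' @param report a `model_report`
#' @param dir output directory
#' @export
write_model_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(patch_id = seq_along(report$ssim),
                       ssim = report$ssim, psnr = report$psnr),
            file.path(dir, paste0(report$model, "_patches.csv")),
            row.names = FALSE)
  write.csv(data.frame(model = report$model,
                       metric = c("ssim", "psnr"),
                       mean = c(report$ssim_mean, report$psnr_mean),
                       sd = c(report$ssim_sd, report$psnr_sd)),
            file.path(dir, paste0(report$model, "_summary.csv")),
            row.names = FALSE)
  invisible(dir)
}
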