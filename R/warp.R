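# Geometric transforms and bilinear resampling.
#
# One coordinate convention is used throughout the package: pixel centers sit
# at integer (row, col) positions starting at 1; a nonreflective similarity
# maps moving -> fixed coordinates by rotating/scaling about the image center
# and then translating,
#   p_fixed = s * R(theta) %*% (p_moving - c) + c + t .
# Warping an image with a transform resamples the moving image on the fixed
# grid via the inverse mapping, with bilinear interpolation.

#' Nonreflective similarity transform
#'
#' @param rotation rotation angle in degrees (counter-clockwise in (col,row)
#'   axes with row pointing down)
#' @param scale isotropic scale factor, must be > 0
#' @param translation numeric length-2 `(dx, dy)` = (column, row) shift in px
#' @return an object of class `similarity_transform`
#' @export
similarity_transform <- function(rotation = 0, scale = 1,
                                 translation = c(0, 0)) {
  assert_scalar_number(rotation, "rotation")
  assert_scalar_number(scale, "scale")
  if (scale <= 0) stopf("degenerate transform: scale must be > 0, got %g", scale)
  stopifnot(length(translation) == 2L, all(is.finite(translation)))
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "similarity transform: rotation %.3f deg, scale %.4f, translation (%.2f, %.2f) px\n",
    x$rotation, x$scale, x$translation[1], x$translation[2]))
  invisible(x)
}

rotmat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Invert a similarity transform
#'
#' The analytic inverse about the same rotation center: rotation negated,
#' scale reciprocal, and translation `-R(-theta) t / s`.
#'
#' @param tf a [similarity_transform()]
#' @return the inverse `similarity_transform`
#' @export
invert_similarity <- function(tf) {
  stopifnot(inherits(tf, "similarity_transform"))
  Rinv <- rotmat(-tf$rotation)
  t_inv <- -(Rinv %*% tf$translation) / tf$scale
  similarity_transform(-tf$rotation, 1 / tf$scale, as.numeric(t_inv))
}

# Map points (n x 2 matrix of (x=col, y=row)) through a similarity transform
# about center `center` (x, y).
apply_similarity_points <- function(points, tf, center) {
  points <- rbind(points)
  R <- rotmat(tf$rotation)
  centered <- sweep(points, 2L, center)
  out <- tf$scale * centered %*% t(R)
  sweep(out, 2L, center + tf$translation, `+`)
}

# Bilinearly sample a single-channel image at fractional (row, col)
# positions; positions outside the frame return `bg`.
sample_bilinear <- function(img, rows, cols, bg = 0) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- numeric(length(rows))
  inside <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
  # exact border rows/cols (no +1 neighbor needed)
  edge <- !inside & rows >= 1 & rows <= H & cols >= 1 & cols <= W &
    fr < 1e-9 & fc < 1e-9
  val[!inside & !edge] <- bg
  if (any(inside)) {
    i <- which(inside)
    i00 <- cbind(r0[i], c0[i]); i01 <- cbind(r0[i], c0[i] + 1L)
    i10 <- cbind(r0[i] + 1L, c0[i]); i11 <- cbind(r0[i] + 1L, c0[i] + 1L)
    val[i] <- img[i00] * (1 - fr[i]) * (1 - fc[i]) +
      img[i01] * (1 - fr[i]) * fc[i] +
      img[i10] * fr[i] * (1 - fc[i]) +
      img[i11] * fr[i] * fc[i]
  }
  if (any(edge)) {
    i <- which(edge)
    val[i] <- img[cbind(r0[i], c0[i])]
  }
  val
}

# Resample an image (matrix or H x W x C array) at per-pixel source
# coordinates given as H x W matrices of rows/cols.
warp_by_mapping <- function(img, src_rows, src_cols, bg = 0) {
  d <- dim(img)
  if (length(d) == 2L) {
    out <- matrix(sample_bilinear(img, as.numeric(src_rows),
                                  as.numeric(src_cols), bg), d[1], d[2])
    return(out)
  }
  out <- array(0, d)
  for (ch in seq_len(d[3]))
    out[, , ch] <- matrix(sample_bilinear(img[, , ch], as.numeric(src_rows),
                                          as.numeric(src_cols), bg),
                          d[1], d[2])
  out
}

# Inverse-map the fixed grid through `tf` (moving -> fixed) and resample.
warp_similarity <- function(img, tf, bg = 0) {
  d <- dim(img); H <- d[1]; W <- d[2]
  center <- c((W + 1) / 2, (H + 1) / 2)
  inv <- invert_similarity(tf)
  grid <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), times = W))
  src <- apply_similarity_points(grid, inv, center)
  warp_by_mapping(img, matrix(src[, 2], H, W), matrix(src[, 1], H, W), bg)
}

# General affine warp used by augmentation: 2x2 matrix `A` (moving -> fixed
# about the image center) plus translation (dx, dy).
warp_affine <- function(img, A, translation = c(0, 0), bg = 0) {
  d <- dim(img); H <- d[1]; W <- d[2]
  center <- c((W + 1) / 2, (H + 1) / 2)
  Ainv <- solve(A)
  grid <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), times = W))
  centered <- sweep(grid, 2L, center + translation)
  src <- sweep(centered %*% t(Ainv), 2L, center, `+`)
  warp_by_mapping(img, matrix(src[, 2], H, W), matrix(src[, 1], H, W), bg)
}
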