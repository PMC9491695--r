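# Co-registration of stain images to the hyperspectral frame.
#
# The moving (immunostained) image is complemented (255 - pixel) so its
# contrast polarity matches the transmission image, then fitted with a
# nonreflective similarity transform (rotation + isotropic scale +
# translation) maximizing normalized cross-correlation over a 3-level
# multi-resolution pyramid. When control points are available, a local
# weighted mean (LWM) of second-degree polynomial transforms fitted around
# each control point refines the mapping for spatially varying deformation.

#' Complement an 8-bit image
#'
#' Maps every pixel value `p` to `255 - p`, flipping stain contrast to
#' match transmission contrast. An involution: applying it twice returns
#' the original image.
#'
#' @param image a [stain_image()], matrix or array of 8-bit values
#' @return same type as the input, complemented
#' @export
complement_8bit <- function(image) {
  if (inherits(image, "stain_image"))
    return(stain_image(255 - image$data, image$kind))
  if (!is_8bit(image))
    stopf("complement_8bit requires 8-bit input (integers in [0, 255])")
  out <- 255 - image
  storage.mode(out) <- storage.mode(image)  # type-stable involution
  out
}

#' Band with the most spatial contrast
#'
#' Operationalized as the band maximizing the spatial intensity SD; used to
#' pick the fixed image for registration.
#'
#' @param cube a [hypercube()]
#' @return integer band index
#' @export
band_max_contrast <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  which.max(band_sds(cube$data))
}

to_gray <- function(image) {
  if (inherits(image, "stain_image")) image <- image$data
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] == 1L) return(image[, , 1])
    return(apply(image, c(1, 2), mean))
  }
  stopf("expected an image matrix or array")
}

ncc <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

downsample2 <- function(img) {
  H <- 2L * (nrow(img) %/% 2L); W <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  (img[seq(1, H, 2), seq(1, W, 2)] + img[seq(2, H, 2), seq(1, W, 2)] +
     img[seq(1, H, 2), seq(2, W, 2)] + img[seq(2, H, 2), seq(2, W, 2)]) / 4
}

similarity_score <- function(par, moving, fixed, bg) {
  tf <- similarity_transform(par[1], exp(par[2]), c(par[3], par[4]))
  warped <- warp_similarity(moving, tf, bg = bg)
  ncc(as.numeric(warped), as.numeric(fixed))
}

#' Fit a nonreflective similarity transform between two images
#'
#' Maximizes normalized cross-correlation between the warped moving image
#' and the fixed image over rotation, isotropic scale and translation, with
#' a 3-level multi-resolution pyramid (coarse grid search over rotation and
#' scale, Nelder-Mead refinement at every level).
#'
#' @param moving the image to warp (a [stain_image()] or matrix); typically
#'   a complemented stain image
#' @param fixed the reference image (e.g. the most-contrast band of the
#'   hypercube); matrix of the same geometry
#' @param init optional [similarity_transform()] starting point
#' @param levels pyramid levels (default 3)
#' @param bg background fill for out-of-frame pixels (255 for brightfield,
#'   0 for fluorescence/complemented images)
#' @return list: `transform` (moving -> fixed [similarity_transform()]),
#'   `warped` (the moving image resampled into the fixed frame), `score`
#'   (final NCC), `degenerate` (TRUE when either image has no contrast)
#' @export
register_similarity <- function(moving, fixed, init = NULL, levels = 3L,
                                bg = 0) {
  mov <- to_gray(moving)
  fix <- to_gray(fixed)
  if (!identical(dim(mov), dim(fix)))
    stopf("moving and fixed images must share geometry")
  degenerate <- sd(mov) == 0 || sd(fix) == 0
  if (degenerate) {
    tf <- init %||% similarity_transform()
    return(list(transform = tf, warped = warp_similarity(mov, tf, bg = bg),
                score = 0, degenerate = TRUE))
  }
  # build pyramids (coarsest first)
  pyr_m <- list(mov); pyr_f <- list(fix)
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyr_m[[1]])) < 24L) break
    pyr_m <- c(list(downsample2(pyr_m[[1]])), pyr_m)
    pyr_f <- c(list(downsample2(pyr_f[[1]])), pyr_f)
  }
  n_lev <- length(pyr_m)
  scale_to_coarse <- 2^(n_lev - 1L)
  if (is.null(init)) {
    par <- c(0, 0, 0, 0)
    # coarse grid over rotation and scale
    best <- -Inf
    for (rot in seq(-14, 14, by = 3.5)) for (sc in c(0.85, 1, 1.18)) {
      cand <- c(rot, log(sc), 0, 0)
      val <- similarity_score(cand, pyr_m[[1]], pyr_f[[1]], bg)
      if (val > best) { best <- val; par <- cand }
    }
  } else {
    par <- c(init$rotation, log(init$scale),
             init$translation / scale_to_coarse)
  }
  score <- -Inf
  for (l in seq_len(n_lev)) {
    opt <- optim(par, similarity_score, moving = pyr_m[[l]],
                 fixed = pyr_f[[l]], bg = bg,
                 method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = 400,
                                reltol = 1e-9))
    par <- opt$par
    score <- opt$value
    if (l < n_lev) par[3:4] <- par[3:4] * 2  # translations double per level
  }
  if (!is.finite(score))
    stopf("similarity registration failed to converge (best score %g)", score)
  tf <- similarity_transform(par[1], exp(par[2]), par[3:4])
  warped_full <- if (inherits(moving, "stain_image")) {
    stain_image(round(clamp(warp_similarity(moving$data, tf, bg = bg),
                            0, 255)), moving$kind)
  } else {
    warp_similarity(mov, tf, bg = bg)
  }
  list(transform = tf, warped = warped_full, score = score,
       degenerate = FALSE)
}

#' Control point set
#'
#' @param fixed_points,moving_points matched n x 2 matrices of `(x, y)`
#'   pixel coordinates (x = column, y = row); at least 6 pairs (a
#'   second-degree 2-D polynomial has 6 coefficients per coordinate)
#' @return object of class `control_point_set`
#' @export
control_point_set <- function(fixed_points, moving_points) {
  fixed_points <- as.matrix(fixed_points)
  moving_points <- as.matrix(moving_points)
  if (nrow(fixed_points) != nrow(moving_points))
    stopf("fixed (%d) and moving (%d) point counts differ",
          nrow(fixed_points), nrow(moving_points))
  if (nrow(fixed_points) < 6L)
    stopf("local weighted mean needs at least 6 control point pairs, got %d",
          nrow(fixed_points))
  structure(list(fixed_points = fixed_points,
                 moving_points = moving_points),
            class = "control_point_set")
}

#' Read / write control points as whitespace-separated text
#'
#' One line per pair: `x_fixed y_fixed x_moving y_moving`.
#' @param path text file path
#' @param cps a [control_point_set()]
#' @export
read_control_points <- function(path) {
  m <- as.matrix(read.table(path))
  control_point_set(m[, 1:2, drop = FALSE], m[, 3:4, drop = FALSE])
}

#' @rdname read_control_points
#' @export
write_control_points <- function(cps, path) {
  write.table(cbind(cps$fixed_points, cps$moving_points), path,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean landmark error of a similarity transform on control points
#'
#' Mean Euclidean distance between `transform(moving_points)` and
#' `fixed_points`; used to decide whether LWM refinement is needed.
#'
#' @param tf a [similarity_transform()] (moving -> fixed)
#' @param cps a [control_point_set()]
#' @param image_dim `(rows, cols)` of the registration frame (sets the
#'   rotation center)
#' @return mean distance in px
#' @export
landmark_error <- function(tf, cps, image_dim) {
  center <- c((image_dim[2] + 1) / 2, (image_dim[1] + 1) / 2)
  mapped <- apply_similarity_points(cps$moving_points, tf, center)
  mean(sqrt(rowSums((mapped - cps$fixed_points)^2)))
}

quad_design <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Local-weighted-mean control point registration
#'
#' For every control point a second-degree polynomial mapping
#' (fixed -> moving coordinates) is least-squares fitted on its `K` nearest
#' control points; at each output pixel the mapping is the weighted mean of
#' the local polynomials, with a quadratic falloff weight vanishing at each
#' point's `K`-th neighbour distance. Pixels outside all neighbourhoods
#' fall back to the nearest control point's polynomial. The moving image is
#' then resampled at the mapped coordinates.
#'
#' @param cps a [control_point_set()] with at least 6 pairs
#' @param moving a [stain_image()] or matrix to warp into the fixed frame
#' @param output_dim `(rows, cols)` of the output; default the moving
#'   image's geometry
#' @param K neighbourhood size (default 12, capped at the number of pairs)
#' @param bg background fill
#' @return list: `warped` image, `map_points(points)` function evaluating
#'   the fixed -> moving mapping at arbitrary `(x, y)` points
#' @export
register_lwm <- function(cps, moving, output_dim = NULL, K = 12L, bg = 0) {
  stopifnot(inherits(cps, "control_point_set"))
  n <- nrow(cps$fixed_points)
  K <- min(as.integer(K), n)
  if (K < 6L) K <- min(6L, n)
  fx <- cps$fixed_points[, 1]; fy <- cps$fixed_points[, 2]
  # per-point local polynomial fits on the K nearest control points
  coefs_u <- matrix(0, n, 6L); coefs_v <- matrix(0, n, 6L)
  radius <- numeric(n)
  dists <- as.matrix(dist(cps$fixed_points))
  for (i in seq_len(n)) {
    nb <- order(dists[i, ])[seq_len(K)]
    radius[i] <- dists[i, nb[K]]
    A <- quad_design(fx[nb], fy[nb])
    qa <- qr(A)
    if (qa$rank < 6L)
      stopf("degenerate (collinear) neighbourhood around control point %d", i)
    coefs_u[i, ] <- qr.coef(qa, cps$moving_points[nb, 1])
    coefs_v[i, ] <- qr.coef(qa, cps$moving_points[nb, 2])
  }
  map_points <- function(points) {
    points <- rbind(points)
    m <- nrow(points)
    D <- quad_design(points[, 1], points[, 2])
    num_u <- numeric(m); num_v <- numeric(m); den <- numeric(m)
    d2 <- outer(points[, 1], fx, `-`)^2 + outer(points[, 2], fy, `-`)^2
    for (i in seq_len(n)) {
      w <- pmax(0, 1 - d2[, i] / radius[i]^2)
      if (all(w == 0)) next
      pu <- D %*% coefs_u[i, ]; pv <- D %*% coefs_v[i, ]
      num_u <- num_u + w * pu; num_v <- num_v + w * pv
      den <- den + w
    }
    out <- cbind(num_u, num_v) / den
    uncovered <- den == 0
    if (any(uncovered)) {
      ni <- apply(d2[uncovered, , drop = FALSE], 1L, which.min)
      for (j in seq_along(ni)) {
        i <- ni[j]; p <- which(uncovered)[j]
        out[p, 1] <- D[p, , drop = FALSE] %*% coefs_u[i, ]
        out[p, 2] <- D[p, , drop = FALSE] %*% coefs_v[i, ]
      }
    }
    colnames(out) <- c("x", "y")
    out
  }
  img <- if (inherits(moving, "stain_image")) moving$data else moving
  dims <- output_dim %||% dim(img)[1:2]
  H <- dims[1]; W <- dims[2]
  grid <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), times = W))
  src <- map_points(grid)
  warped <- warp_by_mapping(img, matrix(src[, 2], H, W),
                            matrix(src[, 1], H, W), bg)
  if (inherits(moving, "stain_image"))
    warped <- stain_image(round(clamp(warped, 0, 255)), moving$kind)
  list(warped = warped, map_points = map_points)
}
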