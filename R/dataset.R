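# Paired training/validation/test patch construction.
#
# Patches are cut from a registered (compressed HSI, stain) image pair. The
# analyzed region is held out and tiled with overlapping test patches (1/3
# to 1/2 overlap, so stitched predictions have no intensity jumps); train
# and validation patches come from the rest of the strip and never touch
# the held-out region; validation is drawn randomly from the training
# patches under a fixed seed. Fluorescence ground truth can be cleaned by
# negative-labeling vessel-lumen artifacts, and every pair is expanded
# twelve-fold by geometric augmentation that mimics residual registration
# error.

patch_origins <- function(extent, patch, stride) {
  if (extent < patch) return(integer(0))
  o <- seq(1L, extent - patch + 1L, by = stride)
  if (o[length(o)] != extent - patch + 1L) o <- c(o, extent - patch + 1L)
  unique(o)
}

rect_intersects <- function(r1, c1, r2, c2, patch, rect) {
  # patch [r1, r1+patch-1] x [c1, ...] vs rect list(rows=, cols=)
  !(r1 + patch - 1L < rect$rows[1] || r1 > rect$rows[2] ||
      c1 + patch - 1L < rect$cols[1] || c1 > rect$cols[2])
}

#' Cut paired train/val/test patches from a registered image pair
#'
#' @param x_image compressed 3-channel image (a `compressed_image` or
#'   H x W x 3 array in `[0, 255]`)
#' @param y_image registered ground-truth stain image (a [stain_image()])
#' @param patch patch side in px (256 at full scale; 64 in tiny mode)
#' @param holdout analyzed region to reserve for testing:
#'   `list(rows = c(r0, r1), cols = c(c0, c1))`, or `NULL` for no test set
#' @param overlap_test test-patch overlap fraction, in `[1/3, 1/2]`
#' @param val_fraction fraction of training patches assigned to validation
#' @param seed seed for the random validation split
#' @return list of pairs, each `list(x, y, role, origin, y_kind,
#'   provenance)`; test patches tile the held-out region with the stated
#'   overlap, train/val patches never intersect it
#' @export
make_patches <- function(x_image, y_image, patch = 256L, holdout = NULL,
                         overlap_test = 0.5, val_fraction = 0.1,
                         seed = 1L) {
  if (inherits(x_image, "compressed_image")) x_image <- x_image$data
  x_image <- as_image_array(x_image)
  y_kind <- if (inherits(y_image, "stain_image")) y_image$kind else "dab"
  y_arr <- as_image_array(y_image)
  d <- dim(x_image)
  if (!identical(d[1:2], dim(y_arr)[1:2]))
    stopf("x and y images must share geometry")
  patch <- as.integer(patch)
  if (overlap_test < 1 / 3 - 1e-9 || overlap_test > 1 / 2 + 1e-9)
    stopf("overlap_test must lie in [1/3, 1/2], got %g", overlap_test)
  pairs <- list()
  cut_pair <- function(r, cc, role) {
    list(x = x_image[r:(r + patch - 1L), cc:(cc + patch - 1L), ,
                     drop = FALSE],
         y = y_arr[r:(r + patch - 1L), cc:(cc + patch - 1L), ,
                   drop = FALSE],
         role = role, origin = c(row = r, col = cc), y_kind = y_kind,
         provenance = "strip")
  }
  if (!is.null(holdout)) {
    hr <- as.integer(holdout$rows); hc <- as.integer(holdout$cols)
    if (hr[1] < 1L || hc[1] < 1L || hr[2] > d[1] || hc[2] > d[2])
      stopf("held-out region (%d:%d, %d:%d) exceeds the %d x %d image",
            hr[1], hr[2], hc[1], hc[2], d[1], d[2])
    if (hr[2] - hr[1] + 1L < patch || hc[2] - hc[1] + 1L < patch)
      stopf("held-out region is smaller than one %d px patch", patch)
    stride <- max(1L, as.integer(round(patch * (1 - overlap_test))))
    for (r in patch_origins(hr[2] - hr[1] + 1L, patch, stride) + hr[1] - 1L)
      for (cc in patch_origins(hc[2] - hc[1] + 1L, patch, stride) +
           hc[1] - 1L)
        pairs[[length(pairs) + 1L]] <- cut_pair(r, cc, "test")
  }
  train_idx <- integer(0)
  for (r in patch_origins(d[1], patch, patch))
    for (cc in patch_origins(d[2], patch, patch)) {
      if (!is.null(holdout) &&
          rect_intersects(r, cc, NULL, NULL, patch,
                          list(rows = as.integer(holdout$rows),
                               cols = as.integer(holdout$cols))))
        next
      pairs[[length(pairs) + 1L]] <- cut_pair(r, cc, "train")
      train_idx <- c(train_idx, length(pairs))
    }
  if (val_fraction > 0 && length(train_idx) > 1L) {
    n_val <- floor(val_fraction * length(train_idx))
    if (n_val > 0L) {
      val_pick <- with_seed(seed, sample(train_idx, n_val))
      for (i in val_pick) pairs[[i]]$role <- "val"
    }
  }
  pairs
}

#' Negative-label vessel-lumen artifacts in a fluorescence patch
#'
#' Spurious autofluorescence inside vessel lumina would mislead training;
#' pixels under the lumen mask are set to 0 (negative class) and the
#' remaining true signal is contrast-stretched between its 1st and 99th
#' positive-value percentiles onto `[1, 255]`, so zero pixels stay zero and
#' true signal stays positive.
#'
#' @param y fluorescence patch (matrix or H x W x C array in `[0, 255]`)
#' @param lumen_mask logical matrix of lumen pixels, same geometry
#' @param stretch percentile pair for the contrast stretch
#' @return cleaned patch, same shape as `y`
#' @export
mask_lumen_negative <- function(y, lumen_mask, stretch = c(0.01, 0.99)) {
  y_img <- if (inherits(y, "stain_image")) y$data else y
  was_matrix <- is.matrix(y_img)
  y_arr <- as_image_array(y_img)
  if (!identical(dim(y_arr)[1:2], dim(lumen_mask)))
    stopf("lumen mask geometry %s does not match patch %s",
          paste(dim(lumen_mask), collapse = "x"),
          paste(dim(y_arr)[1:2], collapse = "x"))
  out <- y_arr
  for (ch in seq_len(dim(y_arr)[3])) {
    v <- y_arr[, , ch]
    v[lumen_mask] <- 0
    pos <- v[v > 0]
    if (length(pos) > 0L) {
      q <- quantile(pos, stretch, names = FALSE)
      if (q[2] > q[1]) {
        w <- v > 0
        v[w] <- 1 + clamp((v[w] - q[1]) / (q[2] - q[1]), 0, 1) * 254
      }
    }
    out[, , ch] <- v
  }
  out <- round(out)
  if (was_matrix) out <- out[, , 1]
  if (inherits(y, "stain_image")) stain_image(out, y$kind) else out
}

#' The twelve-variant augmentation policy
#'
#' Fixed roster: the original; translations of +-8 px along the strip;
#' rotations of +-5 and +-10 degrees; horizontal and vertical flips;
#' isotropic scales 0.9 and 1.1; and one anisotropic stretch (1.0 x 1.1) --
#' twelve geometry-preserving outputs per input.
#'
#' @return object of class `augmentation_policy`: a named list of 12
#'   transform descriptors
#' @export
augmentation_policy <- function() {
  ops <- list(
    identity = list(kind = "identity"),
    translate_p8 = list(kind = "similarity", rotation = 0, scale = 1,
                        translation = c(8, 0)),
    translate_m8 = list(kind = "similarity", rotation = 0, scale = 1,
                        translation = c(-8, 0)),
    rotate_p5 = list(kind = "similarity", rotation = 5, scale = 1,
                     translation = c(0, 0)),
    rotate_m5 = list(kind = "similarity", rotation = -5, scale = 1,
                     translation = c(0, 0)),
    rotate_p10 = list(kind = "similarity", rotation = 10, scale = 1,
                      translation = c(0, 0)),
    rotate_m10 = list(kind = "similarity", rotation = -10, scale = 1,
                      translation = c(0, 0)),
    flip_h = list(kind = "flip", axis = "h"),
    flip_v = list(kind = "flip", axis = "v"),
    scale_090 = list(kind = "similarity", rotation = 0, scale = 0.9,
                     translation = c(0, 0)),
    scale_110 = list(kind = "similarity", rotation = 0, scale = 1.1,
                     translation = c(0, 0)),
    stretch_110 = list(kind = "stretch", sx = 1.0, sy = 1.1)
  )
  structure(list(ops = ops, target_factor = 12L),
            class = "augmentation_policy")
}

apply_aug_op <- function(img, op, bg, extra_translation = c(0, 0)) {
  jittered <- any(extra_translation != 0)
  switch(op$kind,
    identity = if (jittered) {
      warp_similarity(img, similarity_transform(0, 1, extra_translation),
                      bg = bg)
    } else img,
    flip = {
      out <- if (op$axis == "h") {
        if (is.matrix(img)) img[, rev(seq_len(ncol(img)))]
        else img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      } else {
        if (is.matrix(img)) img[rev(seq_len(nrow(img))), ]
        else img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
      }
      if (jittered)
        out <- warp_similarity(out, similarity_transform(0, 1,
                                                         extra_translation),
                               bg = bg)
      out
    },
    similarity = warp_similarity(
      img, similarity_transform(op$rotation, op$scale,
                                op$translation + extra_translation),
      bg = bg),
    stretch = warp_affine(img, diag(c(op$sx, op$sy)), extra_translation,
                          bg = bg),
    stopf("unknown augmentation op '%s'", op$kind))
}

#' Twelve-fold augmentation of a training pair
#'
#' Applies each policy transform identically to `x` and `y`, then adds a
#' small uniform translation jitter (default +-2 px) to `x` only on the
#' eleven non-identity variants, emulating the registration offset between
#' the hyperspectral and ground-truth frames. Deterministic under `seed`.
#'
#' @param pair a [make_patches()] element
#' @param policy an [augmentation_policy()]
#' @param seed integer seed for the jitter draws
#' @param jitter_px maximum registration-offset jitter applied to `x`
#' @return list of `policy$target_factor` pairs (the original first)
#' @export
augment <- function(pair, policy = augmentation_policy(), seed = 1L,
                    jitter_px = 2) {
  stopifnot(inherits(policy, "augmentation_policy"))
  y_bg <- if ((pair$y_kind %||% "dab") == "dab") 255 else 0
  with_seed(seed, {
    out <- vector("list", length(policy$ops))
    for (k in seq_along(policy$ops)) {
      op <- policy$ops[[k]]
      jit <- if (op$kind == "identity") c(0, 0) else
        runif(2, -jitter_px, jitter_px)
      x_aug <- apply_aug_op(pair$x, op, bg = 0, extra_translation = jit)
      y_aug <- apply_aug_op(pair$y, op, bg = y_bg)
      p <- pair
      p$x <- clamp(x_aug, 0, 255)
      p$y <- round(clamp(y_aug, 0, 255))
      p$transform_id <- names(policy$ops)[k]
      out[[k]] <- p
    }
    out
  })
}

#' Augment a list of pairs
#' @param pairs list of pairs
#' @inheritParams augment
#' @return list of `12 * length(pairs)` pairs
#' @export
augment_dataset <- function(pairs, policy = augmentation_policy(),
                            seed = 1L, jitter_px = 2) {
  out <- lapply(seq_along(pairs), function(i)
    augment(pairs[[i]], policy, seed = seed + i, jitter_px = jitter_px))
  do.call(c, out)
}

#' Discard damaged or uninformative patches
#'
#' Two rules: a blank-fraction rule (fraction of `x` pixels equal to the
#' patch's modal value; nearly uniform patches carry no tissue spectra) and
#' a landmark-error rule (pairs carrying a `landmark_error` field above the
#' threshold were unreliably registered).
#'
#' @param pairs list of pairs
#' @param rules `list(max_blank_fraction =, max_landmark_error =)`
#' @return list: `kept` pairs and `report` (counts per rule)
#' @export
discard_damaged <- function(pairs,
                            rules = list(max_blank_fraction = 0.98,
                                         max_landmark_error = 2)) {
  n_blank <- 0L; n_landmark <- 0L
  keep <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    x <- round(as_image_array(p$x))
    modal <- as.numeric(names(which.max(table(x))))
    blank_fraction <- mean(x == modal)
    if (blank_fraction >= rules$max_blank_fraction) {
      n_blank <- n_blank + 1L
      next
    }
    if (!is.null(p$landmark_error) &&
        p$landmark_error > rules$max_landmark_error) {
      n_landmark <- n_landmark + 1L
      next
    }
    keep[i] <- TRUE
  }
  list(kept = pairs[keep],
       report = data.frame(rule = c("blank_fraction", "landmark_error"),
                           discarded = c(n_blank, n_landmark)))
}

#' Write a patch dataset as paired PNG directories with a manifest
#'
#' @param pairs list of pairs
#' @param dir output directory (subdirs `x/`, `y/`, file `manifest.csv`)
#' @export
write_dataset <- function(pairs, dir) {
  dir.create(file.path(dir, "x"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "y"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    id <- sprintf("patch_%05d", i)
    png::writePNG(as_image_array(p$x) / 255,
                  file.path(dir, "x", paste0(id, ".png")))
    y <- as_image_array(p$y)
    if (dim(y)[3] == 1L) y <- y[, , 1]
    png::writePNG(y / 255, file.path(dir, "y", paste0(id, ".png")))
    rows[[i]] <- data.frame(patch_id = id, role = p$role %||% "train",
                            origin_row = p$origin[1], origin_col = p$origin[2],
                            transform_id = p$transform_id %||% "identity")
  }
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}
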