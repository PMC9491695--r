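# Field-of-view and output-patch mosaic stitching.
#
# Adjacent tiles overlap nominally (1/3 for FOV scans). The seam search
# scans candidate overlap widths (and a small vertical jitter) within a
# margin around the nominal overlap and keeps the offset maximizing
# normalized cross-correlation over the shared strip; stitching then
# assembles tiles at the resolved seams, optionally averaging the two
# columns adjacent to a seam when a visible intensity jump remains.

tile_gray <- function(tile) {
  if (inherits(tile, "stain_image")) tile <- tile$data
  if (length(dim(tile)) == 3L) {
    if (dim(tile)[3] == 1L) tile[, , 1] else apply(tile, c(1, 2), mean)
  } else tile
}

shift_rows <- function(img, v, bg = 0) {
  if (v == 0) return(img)
  H <- nrow(img)
  out <- matrix(bg, H, ncol(img))
  if (v > 0) out[(1 + v):H, ] <- img[seq_len(H - v), ]
  else out[seq_len(H + v), ] <- img[(1 - v):H, ]
  out
}

#' Find the best connective coordinate between two adjacent tiles
#'
#' Exhaustively scans overlap widths `nominal_overlap +- margin` (and row
#' shifts `+- vmargin`) and scores each candidate by normalized
#' cross-correlation between the right edge of the left tile and the left
#' edge of the right tile. Ties and contrast-free overlaps are flagged
#' degenerate and resolved to the nominal offset.
#'
#' @param left_tile,right_tile adjacent tiles (matrix, array or
#'   [stain_image()])
#' @param nominal_overlap expected overlap width in px (>= 8)
#' @param margin search margin around the nominal overlap in px
#' @param vmargin vertical jitter search range in px
#' @return list: `offset` (resolved overlap width), `vshift`, `score`,
#'   `degenerate`
#' @export
find_connective_coordinate <- function(left_tile, right_tile,
                                       nominal_overlap, margin = 10L,
                                       vmargin = 3L) {
  left <- tile_gray(left_tile); right <- tile_gray(right_tile)
  if (nrow(left) != nrow(right))
    stopf("tiles must share height (%d vs %d)", nrow(left), nrow(right))
  nominal_overlap <- as.integer(round(nominal_overlap))
  if (nominal_overlap < 8L)
    stopf("overlap too small for seam search: %d px (need >= 8)",
          nominal_overlap)
  cand <- seq(max(8L, nominal_overlap - margin),
              min(ncol(left), ncol(right), nominal_overlap + margin))
  best <- list(offset = nominal_overlap, vshift = 0L, score = -Inf)
  all_scores <- c()
  for (o in cand) {
    ls <- left[, (ncol(left) - o + 1L):ncol(left), drop = FALSE]
    for (v in seq(-vmargin, vmargin)) {
      rs <- shift_rows(right, v)[, seq_len(o), drop = FALSE]
      sc <- ncc(as.numeric(ls), as.numeric(rs))
      all_scores <- c(all_scores, sc)
      if (sc > best$score ||
          (sc == best$score && o == nominal_overlap && v == 0L)) {
        best <- list(offset = o, vshift = v, score = sc)
      }
    }
  }
  degenerate <- length(unique(round(all_scores, 12))) == 1L
  if (degenerate) best <- list(offset = nominal_overlap, vshift = 0L,
                               score = all_scores[1])
  c(best, list(degenerate = degenerate))
}

#' Build a mosaic plan for a row of tiles
#'
#' Resolves every adjacent seam with [find_connective_coordinate()].
#'
#' @param tiles list of tiles, left to right
#' @param overlap_fraction nominal overlap as a fraction of tile width
#'   (1/3 for FOV scans)
#' @param seam_blend `"none"` or `"neighbor_column_average"`
#' @param margin,vmargin passed to the seam search
#' @return object of class `mosaic_plan`
#' @export
mosaic_plan <- function(tiles, overlap_fraction = 1 / 3,
                        seam_blend = c("neighbor_column_average", "none"),
                        margin = 10L, vmargin = 3L) {
  seam_blend <- match.arg(seam_blend)
  if (length(tiles) < 2L) stopf("a mosaic needs at least two tiles")
  widths <- vapply(tiles, function(t) ncol(tile_gray(t)), integer(1))
  seams <- vector("list", length(tiles) - 1L)
  for (i in seq_len(length(tiles) - 1L)) {
    nominal <- as.integer(round(overlap_fraction * widths[i + 1L]))
    seams[[i]] <- find_connective_coordinate(tiles[[i]], tiles[[i + 1L]],
                                             nominal, margin, vmargin)
  }
  structure(list(widths = widths, seams = seams, seam_blend = seam_blend),
            class = "mosaic_plan")
}

#' Stitch tiles into a mosaic
#'
#' Assembles the tiles at the plan's resolved seams (the right tile's
#' pixels fill each overlap). When a seam still shows an intensity jump
#' (mean absolute neighbour-column difference above `artifact_threshold`)
#' and blending is enabled, the two columns adjacent to the seam are
#' replaced by their average.
#'
#' @param plan a [mosaic_plan()]
#' @param tiles the tiles the plan was built for
#' @param artifact_threshold 8-bit intensity jump triggering column
#'   averaging (default 5)
#' @return the stitched mosaic (matrix or H x W x C array matching the
#'   tiles)
#' @export
stitch <- function(plan, tiles, artifact_threshold = 5) {
  stopifnot(inherits(plan, "mosaic_plan"))
  arrs <- lapply(tiles, function(t) {
    if (inherits(t, "stain_image")) t <- t$data
    if (length(dim(t)) == 2L) array(t, c(dim(t), 1L)) else t
  })
  C <- dim(arrs[[1]])[3]; H <- dim(arrs[[1]])[1]
  offsets <- vapply(plan$seams, function(s) s$offset, numeric(1))
  total_w <- sum(plan$widths) - sum(offsets)
  if (total_w < 1) stopf("inconsistent offsets: mosaic width %d", total_w)
  out <- array(0, c(H, total_w, C))
  pos <- 1L  # column where the current tile starts
  seam_cols <- integer(0)
  for (i in seq_along(arrs)) {
    w <- plan$widths[i]
    if (i > 1L) {
      o <- plan$seams[[i - 1L]]$offset
      v <- plan$seams[[i - 1L]]$vshift
      pos <- pos - o
      seam_cols <- c(seam_cols, pos - 1L)
      tile <- arrs[[i]]
      if (v != 0)
        for (ch in seq_len(C)) tile[, , ch] <- shift_rows(tile[, , ch], v)
      arrs[[i]] <- tile
    }
    out[, pos:(pos + w - 1L), ] <- arrs[[i]][, , , drop = FALSE]
    pos <- pos + w
  }
  if (plan$seam_blend == "neighbor_column_average") {
    for (sc in seam_cols) {
      if (sc < 1L || sc + 1L > total_w) next
      jump <- mean(abs(out[, sc, , drop = FALSE] -
                         out[, sc + 1L, , drop = FALSE]))
      if (jump > artifact_threshold) {
        avg <- (out[, sc, , drop = FALSE] + out[, sc + 1L, , drop = FALSE]) / 2
        out[, sc, ] <- avg
        out[, sc + 1L, ] <- avg
      }
    }
  }
  if (C == 1L) out[, , 1] else out
}
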