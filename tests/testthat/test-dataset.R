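blank_pair_images <- function(h, w, seed = 1) {
  set.seed(seed)
  x <- array(runif(h * w * 3, 0, 255), c(h, w, 3))
  y <- stain_image(array(round(runif(h * w * 3, 0, 255)), c(h, w, 3)),
                   "dab")
  list(x = x, y = y)
}

test_that("test patches tile the held-out region at the stated overlap", {
  im <- blank_pair_images(192, 192)
  pairs <- make_patches(im$x, im$y, patch = 64,
                        holdout = list(rows = c(1, 192), cols = c(1, 192)),
                        overlap_test = 0.5, val_fraction = 0)
  test <- Filter(function(p) p$role == "test", pairs)
  origins <- sort(unique(vapply(test, function(p) p$origin[["row"]],
                                numeric(1))))
  expect_equal(origins, c(1, 33, 65, 97, 129))  # 32-px stride grid
  expect_length(Filter(function(p) p$role != "test", pairs), 0)
})

test_that("train patch count matches brute-force origin enumeration", {
  im <- blank_pair_images(256, 768)
  pairs <- make_patches(im$x, im$y, patch = 256, holdout = NULL,
                        val_fraction = 0)
  # brute force: non-overlapping 256-px origins incl. the flush-right one
  count <- 0
  for (r in unique(c(seq(1, 256 - 256 + 1, 256))))
    for (cc in unique(c(seq(1, 768 - 256 + 1, 256))))
      count <- count + 1
  expect_length(pairs, count)
  expect_true(all(vapply(pairs, function(p) p$role == "train", logical(1))))
})

test_that("train and validation patches never touch the held-out region", {
  im <- blank_pair_images(192, 320)
  holdout <- list(rows = c(1, 192), cols = c(193, 320))
  pairs <- make_patches(im$x, im$y, patch = 64, holdout = holdout,
                        overlap_test = 1 / 3, val_fraction = 0.2, seed = 2)
  roles <- vapply(pairs, `[[`, character(1), "role")
  expect_setequal(unique(roles), c("test", "train", "val"))
  for (p in pairs[roles != "test"]) {
    r <- p$origin[["row"]]; cc <- p$origin[["col"]]
    expect_true(r + 63 < holdout$rows[1] || r > holdout$rows[2] ||
                  cc + 63 < holdout$cols[1] || cc > holdout$cols[2])
  }
})

test_that("oversized held-out regions and bad overlaps are rejected", {
  im <- blank_pair_images(64, 64)
  expect_error(make_patches(im$x, im$y, patch = 32,
                            holdout = list(rows = c(1, 80),
                                           cols = c(1, 64))), "exceeds")
  expect_error(make_patches(im$x, im$y, patch = 32, overlap_test = 0.25),
               "overlap_test")
})

test_that("augmentation emits exactly 12 variants with a faithful original", {
  pair <- fx_pairs()[[1]]
  out <- augment(pair, seed = 5)
  expect_length(out, 12L)
  expect_identical(out[[1]]$x, pair$x)
  expect_identical(out[[1]]$y, pair$y)
  expect_false(identical(out[[4]]$y, pair$y))
  # same seed twice is bit-identical; different seed jitters x differently
  out2 <- augment(pair, seed = 5)
  for (k in seq_along(out))
    expect_identical(out[[k]]$x, out2[[k]]$x)
  out3 <- augment(pair, seed = 6)
  expect_false(identical(out[[2]]$x, out3[[2]]$x))
  # jitter applies to x only: y of matching variants is unchanged
  expect_identical(out[[2]]$y, out3[[2]]$y)
})

test_that("dataset-level augmentation scales counts by 12", {
  pairs <- fx_pairs()[1:5]
  out <- augment_dataset(pairs, seed = 3)
  expect_length(out, 60L)
})

test_that("flip variants transform y's geometry exactly", {
  pair <- fx_pairs()[[1]]
  out <- augment(pair, seed = 9)
  ids <- vapply(out, `[[`, character(1), "transform_id")
  h <- out[[which(ids == "flip_h")]]
  expect_identical(h$y, pair$y[, rev(seq_len(dim(pair$y)[2])), ,
                               drop = FALSE])
  v <- out[[which(ids == "flip_v")]]
  expect_identical(v$y, pair$y[rev(seq_len(dim(pair$y)[1])), , ,
                               drop = FALSE])
})

test_that("lumen artifacts are negative-labeled out of fluorescence", {
  # artifact-only patch collapses to zero
  y <- array(0, c(32, 32, 3))
  lumen <- matrix(FALSE, 32, 32); lumen[10:20, 10:20] <- TRUE
  y[, , 2][lumen] <- 180
  out <- mask_lumen_negative(y, lumen)
  expect_true(all(out == 0))
  # without lumen pixels only the stretch applies and zeros stay zero
  y2 <- array(0, c(32, 32, 3))
  y2[5:8, 5:8, 1] <- 100
  out2 <- mask_lumen_negative(y2, matrix(FALSE, 32, 32))
  expect_true(all(out2[y2 == 0] == 0))
  expect_true(any(out2 > 0))
  expect_error(mask_lumen_negative(y2, matrix(FALSE, 16, 16)), "geometry")
})

test_that("cleaning the phantom's fluorescence recovers the clean render", {
  gt <- fx_phantom()
  lumen <- gt$label_mask == 4L
  cleaned <- mask_lumen_negative(gt$fluor_image, lumen)
  clean_ref <- gt$fluor_clean$data
  # identical support, and per-channel signal ordering preserved (the
  # stretch is monotone within each channel)
  expect_identical(cleaned$data > 0, clean_ref > 0)
  for (ch in 1:2) {
    sel <- clean_ref[, , ch] > 0
    if (any(sel))
      expect_gt(cor(cleaned$data[, , ch][sel], clean_ref[, , ch][sel]),
                0.999)
  }
})

test_that("discard rules remove blank and misregistered patches", {
  pairs <- fx_pairs()[1:4]
  blank <- pairs[[1]]
  blank$x <- array(7, dim(blank$x))
  bad_reg <- lapply(pairs[2:3], function(p) { p$landmark_error <- 5; p })
  ok <- pairs[[4]]
  res <- discard_damaged(c(list(blank), bad_reg, list(ok)))
  expect_length(res$kept, 1L)
  expect_equal(res$report$discarded[res$report$rule == "blank_fraction"], 1L)
  expect_equal(res$report$discarded[res$report$rule == "landmark_error"], 2L)
  # pristine tissue-bearing patches are all retained
  res2 <- discard_damaged(fx_pairs())
  expect_length(res2$kept, length(fx_pairs()))
})

test_that("datasets round trip through PNG directories", {
  pairs <- fx_pairs()[1:3]
  dir <- withr::local_tempdir()
  write_dataset(pairs, dir)
  back <- read_dataset(dir, kind = "dab")
  expect_length(back, 3L)
  expect_equal(back[[1]]$x, round(pairs[[1]]$x))
  expect_equal(back[[1]]$y, pairs[[1]]$y)
})
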