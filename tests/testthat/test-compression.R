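test_that("a near rank-1 cube concentrates variance in PC1", {
  set.seed(31)
  wl <- seq(500, 590, 10)
  spec <- runif(10, 0.5, 1)
  map <- matrix(runif(20 * 20, 0.2, 1), 20, 20)
  data <- array(0, c(20, 20, 10))
  for (b in 1:10) data[, , b] <- map * spec[b]
  data <- data + array(rnorm(length(data), sd = 1e-5), dim(data))
  data <- pmax(data, 0)
  basis <- fit_pca(hypercube(data, wl))
  expect_gt(basis$explained_variance[1], 0.999)
})

test_that("phantom hypercubes compress to 3 components above 85% variance", {
  basis <- fit_pca(fx_calibrated_cube())
  expect_gte(sum(basis$explained_variance), 0.85)
})

test_that("components match a brute-force eigen-decomposition on 4x4x5", {
  set.seed(33)
  wl <- seq(500, 540, 10)
  cube <- hypercube(array(runif(4 * 4 * 5), c(4, 4, 5)), wl)
  basis <- fit_pca(cube)
  X <- matrix(cube$data, ncol = 5)
  Xc <- sweep(X, 2, colMeans(X))
  C <- t(Xc) %*% Xc / (nrow(X) - 1)
  eig <- eigen(C, symmetric = TRUE)
  for (k in 1:3) {
    v <- eig$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(basis$loadings[, k], v, tolerance = 1e-10)
  }
  expect_equal(basis$explained_variance,
               eig$values[1:3] / sum(eig$values), tolerance = 1e-10)
})

test_that("a constant cube has no usable components", {
  wl <- seq(500, 540, 10)
  expect_error(fit_pca(hypercube(array(1, c(6, 6, 5)), wl)), "degenerate")
})

test_that("explained variance is non-increasing and sums below 1", {
  basis <- fit_pca(fx_calibrated_cube())
  expect_true(all(diff(basis$explained_variance) <= 1e-12))
  expect_lte(sum(basis$explained_variance), 1 + 1e-12)
  expect_true(all(basis$explained_variance >= 0))
})

test_that("projection maps PCs to RGB with recorded scaling", {
  cube <- fx_calibrated_cube()
  basis <- fit_pca(cube)
  rgb <- project_to_rgb(cube, basis)
  expect_equal(dim(rgb$data), c(dim(cube$data)[1:2], 3L))
  expect_true(all(rgb$data >= 0 & rgb$data <= 255))
  # reusing the recorded scaling reproduces the mapping exactly
  rgb2 <- project_to_rgb(cube, basis, fit_stats = rgb$fit_stats)
  expect_identical(rgb2$data, rgb$data)
  # axis mismatch is rejected
  other <- hypercube(cube$data[, , 1:150], cube$wavelengths[1:150])
  expect_error(project_to_rgb(other, basis), "mismatch")
})

test_that("deposit classes separate in RGB space", {
  gt <- fx_phantom02()
  cube <- fx_calibrated_cube()
  rgb <- project_to_rgb(cube, fit_pca(cube))
  px <- function(code) {
    sel <- gt$label_mask == code
    t(apply(rgb$data, 3, function(ch) ch[sel]))
  }
  mean_rgb <- function(code) rowMeans(px(code))
  d_ab <- sqrt(sum((mean_rgb(2L) - mean_rgb(3L))^2))
  intra_sd <- mean(c(apply(px(2L), 1, sd), apply(px(3L), 1, sd)))
  expect_gt(d_ab, intra_sd)
})

test_that("3-component reconstruction error matches explained variance", {
  cube <- fx_calibrated_cube()
  basis <- fit_pca(cube)
  X <- matrix(cube$data, ncol = dim(cube$data)[3])
  Xc <- sweep(X, 2, basis$center)
  scores <- Xc %*% basis$loadings
  resid <- Xc - scores %*% t(basis$loadings)
  rel_err <- sum(resid^2) / sum(Xc^2)
  expect_lte(rel_err, 1 - sum(basis$explained_variance) + 1e-6)
})

test_that("projection is linear up to the stored channel scaling", {
  cube <- fx_calibrated_cube()
  basis <- fit_pca(cube)
  a <- 2.5
  scaled <- hypercube(cube$data * a, cube$wavelengths)
  X <- matrix(cube$data, ncol = dim(cube$data)[3])
  s1 <- sweep(X, 2, basis$center) %*% basis$loadings
  X2 <- matrix(scaled$data, ncol = dim(cube$data)[3])
  # recenter the scaled cube on its own means: scores scale by a
  s2 <- sweep(X2, 2, colMeans(X2)) %*% basis$loadings
  expect_equal(s2, a * sweep(X, 2, colMeans(X)) %*% basis$loadings,
               tolerance = 1e-9)
})

test_that("a PCA basis survives the JSON sidecar round trip", {
  cube <- fx_calibrated_cube()
  basis <- fit_pca(cube)
  rgb <- project_to_rgb(cube, basis)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_basis(basis, path, fit_stats = rgb$fit_stats)
  back <- read_pca_basis(path)
  expect_equal(back$basis$loadings, basis$loadings, tolerance = 1e-12)
  expect_equal(back$basis$explained_variance, basis$explained_variance,
               tolerance = 1e-12)
  rgb3 <- project_to_rgb(cube, back$basis, fit_stats = back$fit_stats)
  expect_equal(rgb3$data, rgb$data, tolerance = 1e-9)
})
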