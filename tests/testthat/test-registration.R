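test_that("complement maps 0 to 255 and back", {
  img <- rand_img8(10, 10, 1)
  img[1, 1] <- 0; img[1, 2] <- 255
  comp <- complement_8bit(img)
  expect_equal(comp[1, 1], 255)
  expect_equal(comp[1, 2], 0)
  expect_identical(complement_8bit(comp), img)
  expect_error(complement_8bit(img + 0.5), "8-bit")
  expect_error(complement_8bit(img - 300), "8-bit")
})

test_that("registration score is invariant to complementing both images", {
  gt <- fx_phantom()
  a <- hsistain:::to_gray(gt$dab_image)
  b <- hsistain:::to_gray(apply_known_warp(
    gt$dab_image, similarity_transform(2, 1, c(1, 1)))$warped$data)
  expect_equal(hsistain:::ncc(255 - a, 255 - round(b)),
               hsistain:::ncc(a, round(b)), tolerance = 1e-12)
})

test_that("the most-contrast band maximizes spatial SD", {
  cube <- fx_phantom02()$hypercube
  b <- band_max_contrast(cube)
  sds <- apply(cube$data, 3, sd)
  expect_equal(b, which.max(sds))
})

test_that("registering an image to itself returns the identity", {
  img <- hsistain:::to_gray(fx_phantom()$dab_image)
  fit <- register_similarity(img, img, bg = 255)
  expect_lt(abs(fit$transform$rotation), 0.1)
  expect_lt(abs(fit$transform$scale - 1), 0.01)
  expect_lt(max(abs(fit$transform$translation)), 0.5)
  expect_false(fit$degenerate)
})

test_that("known similarity warps are recovered within tolerance", {
  gt <- fx_phantom()
  cases <- list(c(7, 1.1, 4, -3), c(-5, 0.9, -6, 2), c(12, 1.0, 0, 5))
  for (cs in cases) {
    tf <- similarity_transform(cs[1], cs[2], cs[3:4])
    w <- apply_known_warp(gt$dab_image, tf)
    fit <- register_similarity(w$warped, hsistain:::to_gray(gt$dab_image),
                               bg = 255)
    expect_lt(abs(fit$transform$rotation - w$inverse$rotation), 0.5)
    expect_lt(abs(fit$transform$scale / w$inverse$scale - 1), 0.01)
    expect_lt(max(abs(fit$transform$translation - w$inverse$translation)),
              1)
  }
})

test_that("blank-on-blank registration is flagged degenerate", {
  blank <- matrix(128, 64, 64)
  fit <- register_similarity(blank, blank)
  expect_true(fit$degenerate)
  expect_equal(fit$transform$rotation, 0)
  expect_equal(fit$score, 0)
})

test_that("control point sets enforce the 6-pair minimum", {
  expect_error(control_point_set(cbind(1:5, 1:5), cbind(1:5, 1:5)),
               "at least 6")
  expect_error(control_point_set(cbind(1:6, 1:6), cbind(1:5, 1:5)),
               "differ")
})

test_that("LWM agrees with a global similarity on its control points", {
  gt <- fx_phantom()
  tf <- similarity_transform(6, 1.05, c(3, -2))
  inv <- invert_similarity(tf)
  ctr <- c((128 + 1) / 2, (96 + 1) / 2)
  set.seed(8)
  fp <- cbind(runif(12, 15, 110), runif(12, 15, 85))
  mp <- hsistain:::apply_similarity_points(fp, inv, ctr)
  cps <- control_point_set(fp, mp)
  lw <- register_lwm(cps, hsistain:::to_gray(gt$dab_image),
                     output_dim = c(96, 128), bg = 255)
  mapped <- lw$map_points(fp)
  expect_lt(max(sqrt(rowSums((mapped - mp)^2))), 0.5)
  # also exact away from control points for a polynomial-representable map
  grid <- cbind(runif(20, 20, 100), runif(20, 20, 80))
  expect_lt(max(sqrt(rowSums((lw$map_points(grid) -
    hsistain:::apply_similarity_points(grid, inv, ctr))^2))), 0.5)
})

test_that("six exact pairs interpolate exactly at control points", {
  fp <- cbind(c(10, 50, 90, 10, 50, 90), c(10, 15, 10, 80, 85, 80))
  mp <- fp + cbind(rep(3, 6), rep(-2, 6))
  cps <- control_point_set(fp, mp)
  lw <- register_lwm(cps, matrix(0, 96, 128), output_dim = c(96, 128))
  mapped <- lw$map_points(fp)
  expect_lt(max(sqrt(rowSums((mapped - mp)^2))), 0.5)
})

test_that("LWM refines a quadratic warp better than similarity alone", {
  # true mapping fixed -> moving is second-degree; similarity cannot track it
  quad_map <- function(p)
    cbind(p[, 1] + 0.0012 * (p[, 2] - 48)^2,
          p[, 2] - 0.0010 * (p[, 1] - 64)^2)
  set.seed(13)
  fp <- cbind(runif(16, 10, 118), runif(16, 10, 86))
  mp <- quad_map(fp)
  cps <- control_point_set(fp, mp)
  lw <- register_lwm(cps, matrix(0, 96, 128), output_dim = c(96, 128))
  probe <- cbind(runif(30, 15, 110), runif(30, 15, 80))
  err_lwm <- mean(sqrt(rowSums((lw$map_points(probe) - quad_map(probe))^2)))
  # best similarity fitted to the same pairs (least squares, no reflection)
  ls_sim <- function() {
    fc <- scale(fp, scale = FALSE); mc <- scale(mp, scale = FALSE)
    num <- sum(fc[, 1] * mc[, 1] + fc[, 2] * mc[, 2])
    cross <- sum(fc[, 1] * mc[, 2] - fc[, 2] * mc[, 1])
    theta <- atan2(cross, num)
    s <- sqrt(num^2 + cross^2) / sum(fc^2)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    t_vec <- colMeans(mp) - s * colMeans(fp) %*% t(R)
    function(p) s * p %*% t(R) + matrix(t_vec, nrow(p), 2, byrow = TRUE)
  }
  f <- ls_sim()
  err_sim <- mean(sqrt(rowSums((f(probe) - quad_map(probe))^2)))
  expect_lt(err_lwm, err_sim)
})

test_that("degenerate collinear neighbourhoods are identified", {
  fp <- cbind(seq(10, 60, 10), seq(10, 60, 10))  # all on a line
  cps <- control_point_set(fp, fp)
  expect_error(register_lwm(cps, matrix(0, 64, 64)), "degenerate")
})

test_that("control points survive the text round trip", {
  fp <- cbind(runif(8, 1, 100), runif(8, 1, 100))
  mp <- fp + 2
  path <- withr::local_tempfile()
  write_control_points(control_point_set(fp, mp), path)
  back <- read_control_points(path)
  expect_equal(back$fixed_points, unname(fp), ignore_attr = TRUE)
  expect_equal(back$moving_points, unname(mp), ignore_attr = TRUE)
})

test_that("landmark error measures similarity fit quality", {
  fp <- cbind(c(10, 50, 90, 10, 50, 90), c(10, 15, 10, 80, 85, 80))
  cps <- control_point_set(fp, fp)
  expect_equal(landmark_error(similarity_transform(), cps, c(96, 128)), 0)
  shifted <- control_point_set(fp + cbind(rep(3, 6), rep(4, 6)), fp)
  expect_equal(landmark_error(similarity_transform(), shifted,
                              c(96, 128)), 5)
})
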