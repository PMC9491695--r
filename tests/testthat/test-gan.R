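test_that("generator loss vanishes at the perfect-generator fixed point", {
  y <- array(rand_img8(16, 16, 1), c(16, 16, 1))
  l <- generator_loss(y, y, D_score = 1 - 1e-12)
  expect_equal(l$total, 0, tolerance = 1e-9)
  expect_equal(l$l1, 0)
  expect_equal(l$ssim_term, 0, tolerance = 1e-9)
})

test_that("generator loss matches closed-form arithmetic", {
  y <- array(rand_img8(16, 16, 2), c(16, 16, 1))
  l <- generator_loss(y, y, D_score = 0.5)
  expect_equal(l$total, -log(0.5), tolerance = 1e-9)
  # constant images 10 gray levels apart, cross-checked against the
  # metrics module's SSIM
  a <- array(100, c(16, 16, 1)); b <- array(110, c(16, 16, 1))
  s <- ssim(a / 255 * 255, b / 255 * 255, ssim_params())
  expected <- -log(0.5) + 100 * (10 / 255) - 100 * log((1 + s) / 2)
  l2 <- generator_loss(a, b, D_score = 0.5,
                       weights = loss_weights(100, 100))
  expect_equal(l2$total, expected, tolerance = 1e-9)
})

test_that("zero weights reduce the generator loss to the adversarial term", {
  a <- array(rand_img8(8, 8, 3), c(8, 8, 1))
  b <- array(rand_img8(8, 8, 4), c(8, 8, 1))
  l <- generator_loss(a, b, D_score = 0.3, weights = loss_weights(0, 0))
  expect_equal(l$total, -log(0.3), tolerance = 1e-12)
})

test_that("boundary discriminator scores are rejected", {
  a <- array(0, c(4, 4, 1))
  expect_error(generator_loss(a, a, D_score = 0), "0, 1")
  expect_error(generator_loss(a, a, D_score = 1), "0, 1")
  expect_error(discriminator_loss(1, 0.5), "strictly inside")
})

test_that("discriminator loss follows its closed forms", {
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-12)
  expect_equal(discriminator_loss(0.9, 0.1), -2 * log(0.9),
               tolerance = 1e-12)
  # perfect-discriminator limit
  eps <- c(1e-3, 1e-5, 1e-7)
  losses <- vapply(eps, function(e) discriminator_loss(1 - e, e),
                   numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[3], 1e-6)
})

test_that("network gradients agree with finite differences", {
  ns <- asNamespace("hsistain")
  set.seed(42)
  # SSIM gradient
  x <- runif(64); y <- runif(64)
  sg <- ns$ssim_grad_channel(x, y, 1e-4, 9e-4)
  for (i in c(1, 17, 40)) {
    e <- 1e-6; xp <- x; xm <- x
    xp[i] <- xp[i] + e; xm[i] <- xm[i] - e
    fd <- (ns$ssim_grad_channel(xp, y, 1e-4, 9e-4)$value -
             ns$ssim_grad_channel(xm, y, 1e-4, 9e-4)$value) / (2 * e)
    expect_equal(sg$grad[i], fd, tolerance = 1e-5)
  }
  # generator parameter gradients through conv and instance norm
  G <- ns$build_generator(3L, 1L, depth = 2L, base_width = 4L)
  xin <- array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  tgt <- array(runif(16 * 16, -1, 1), c(16, 16, 1))
  loss_of <- function() {
    g <- ns$generator_forward(G, xin); 0.5 * sum((g - tgt)^2)
  }
  g0 <- ns$generator_forward(G, xin)
  ns$generator_backward(G, g0 - tgt)
  conv1 <- ns$trainable_layers(G)[[1]]
  inorm <- Filter(function(e) e$type == "instnorm", G$layers)[[1]]
  e <- 1e-5
  a_grad <- conv1$dW[3, 2]
  conv1$W[3, 2] <- conv1$W[3, 2] + e; up <- loss_of()
  conv1$W[3, 2] <- conv1$W[3, 2] - 2 * e; dn <- loss_of()
  conv1$W[3, 2] <- conv1$W[3, 2] + e
  expect_equal(a_grad, (up - dn) / (2 * e), tolerance = 1e-4)
  g_grad <- inorm$dW[1]
  inorm$gamma[1] <- inorm$gamma[1] + e; up <- loss_of()
  inorm$gamma[1] <- inorm$gamma[1] - 2 * e; dn <- loss_of()
  inorm$gamma[1] <- inorm$gamma[1] + e
  expect_equal(g_grad, (up - dn) / (2 * e), tolerance = 1e-4)
  # discriminator gradient with respect to its input
  D <- ns$build_discriminator(4L, base_width = 4L)
  xy <- array(runif(16 * 16 * 4, -1, 1), c(16, 16, 4))
  dmap <- ns$discriminator_forward(D, xy)
  gin <- ns$discriminator_backward(D, array(1, dim(dmap)))
  xy2 <- xy; xy2[5, 5, 4] <- xy2[5, 5, 4] + e
  up <- sum(ns$discriminator_forward(D, xy2))
  xy2[5, 5, 4] <- xy2[5, 5, 4] - 2 * e
  dn <- sum(ns$discriminator_forward(D, xy2))
  expect_equal(gin[5, 5, 4], (up - dn) / (2 * e), tolerance = 1e-4)
})

test_that("configs encode the published schedule and reject bad values", {
  full <- gan_config("dab_ptau", "full")
  expect_equal(full$learning_rate, 1e-5)
  expect_equal(full$epochs, 135L)
  expect_equal(full$decay_epochs, 50L)
  expect_equal(full$batch_size, 1L)
  expect_equal(full$normalization, "instance")
  expect_equal(gan_config("fluo_abeta", "full")$learning_rate, 5e-6)
  expect_error(gan_config("dab_ptau", epochs = 5, decay_epochs = 10),
               "decay")
  expect_error(gan_config("h&e"), "unknown target")
  expect_error(loss_weights(-1), ">= 0")
})

test_that("a zero-epoch run returns an untrained bundle with empty log", {
  pairs <- fx_pairs()[1:2]
  cfg <- gan_config("dab_ptau", "tiny", epochs = 0, decay_epochs = 0)
  b <- train_model(pairs, "dab_ptau", cfg)
  expect_null(b$train_log)
  expect_s3_class(b, "model_bundle")
  p <- predict_patches(b, list(pairs[[1]]$x))
  expect_equal(dim(p[[1]]), c(64, 64, 3))
})

test_that("short training reduces the L1 term deterministically", {
  pairs <- fx_pairs()
  cfg <- gan_config("dab_ptau", "tiny", epochs = 4, decay_epochs = 0,
                    seed = 2)
  b1 <- train_model(pairs, "dab_ptau", cfg)
  expect_lt(b1$train_log$G_L1[4], b1$train_log$G_L1[1])
  b2 <- train_model(pairs, "dab_ptau", cfg)
  expect_identical(b1$train_log, b2$train_log)
  # inference determinism
  p1 <- predict_patches(b1, list(pairs[[1]]$x))
  p2 <- predict_patches(b1, list(pairs[[1]]$x))
  expect_identical(p1, p2)
  # geometry mismatch is caught
  expect_error(predict_patches(b1, list(array(0, c(32, 32, 3)))),
               "geometry")
  # model bundles survive serialization
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(b1, path)
  b3 <- load_model(path)
  expect_identical(predict_patches(b3, list(pairs[[1]]$x)), p1)
})

test_that("empty datasets are rejected", {
  expect_error(train_model(list(), "dab_ptau",
                           gan_config("dab_ptau", "tiny")), "empty")
})

test_that("fluorescence targets train on their own channel", {
  pairs <- phantom_pairs(4L, patch = 64L, seed = 19L,
                         target = "fluo_ptau")
  cfg <- gan_config("fluo_ptau", "tiny", epochs = 1, decay_epochs = 0)
  b <- train_model(pairs, "fluo_ptau", cfg)
  p <- predict_patches(b, list(pairs[[1]]$x))
  expect_equal(dim(p[[1]]), c(64, 64, 1))
})
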