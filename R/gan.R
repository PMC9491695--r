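# Conditional GAN for virtual staining.
#
# A U-Net generator G maps a PCA-compressed 3-channel patch x to a
# histopathology-like patch; a 3-block patch discriminator D judges (x, y)
# pairs. The generator objective combines an adversarial term, an L1
# fidelity term and an SSIM term,
#
#   L(G; D) = -log D(G(x)) + lambda * L1(G(x), y)
#             - nu * log[(1 + SSIM(G(x), y)) / 2]
#
# and the discriminator minimizes
#
#   L(D; G) = -log D(y) - log(1 - D(G(x))) .
#
# Both default weights are 100. Training uses Adam at batch size one under
# instance normalization, with the learning rate held constant and then
# linearly decayed over the final epochs. Four model targets exist:
# DAB/fluorescence renderings of abeta and ptau, trained separately.

GAN_TARGETS <- c("dab_abeta", "dab_ptau", "fluo_abeta", "fluo_ptau")
SCORE_EPS <- 1e-7  # probability clamp keeping logs finite

#' Loss weights for the generator objective
#' @param lambda_l1 weight of the L1 term (default 100)
#' @param nu_ssim weight of the SSIM term (default 100)
#' @return list of class `loss_weights`
#' @export
loss_weights <- function(lambda_l1 = 100, nu_ssim = 100) {
  if (lambda_l1 < 0) stopf("lambda_l1 must be >= 0")
  if (nu_ssim < 0) stopf("nu_ssim must be >= 0")
  structure(list(lambda_l1 = lambda_l1, nu_ssim = nu_ssim),
            class = "loss_weights")
}

#' Training configuration
#'
#' Full-size mode mirrors the published schedule: learning rate 1e-5 for
#' DAB targets and 5e-6 for fluorescence targets, 135 epochs (midpoint of
#' the 120-150 range) with the final 50 at a linearly decayed rate, batch
#' size one under instance normalization, Adam with default moments, U-Net
#' depth 6 / base width 64. Tiny mode is the desk-scale surrogate used for
#' testing on 64 x 64 phantom patches: depth 3 / width 16, 20 epochs with
#' the final 7 decayed, and a learning rate of 2e-4 (the conventional value
#' for this conditional-GAN family, compensating the far shorter schedule).
#'
#' @param target one of `dab_abeta`, `dab_ptau`, `fluo_abeta`, `fluo_ptau`
#' @param mode `"tiny"` or `"full"`
#' @param learning_rate,epochs,decay_epochs,depth,base_width overrides
#' @param seed integer seed controlling weight init and data order
#' @param checkpoint_every write a checkpoint every N epochs when a
#'   `checkpoint_dir` is passed to [train_model()] (0 = never)
#' @return list of class `train_config` (always `batch_size = 1`,
#'   `normalization = "instance"`)
#' @export
gan_config <- function(target = "dab_ptau", mode = c("tiny", "full"),
                       learning_rate = NULL, epochs = NULL,
                       decay_epochs = NULL, depth = NULL, base_width = NULL,
                       seed = 1L, checkpoint_every = 0L) {
  mode <- match.arg(mode)
  if (!target %in% GAN_TARGETS)
    stopf("unknown target '%s' (expected one of %s)", target,
          paste(GAN_TARGETS, collapse = ", "))
  is_dab <- startsWith(target, "dab")
  if (mode == "full") {
    learning_rate <- learning_rate %||% if (is_dab) 1e-5 else 5e-6
    epochs <- epochs %||% 135L
    decay_epochs <- decay_epochs %||% min(50L, epochs)
    depth <- depth %||% 6L
    base_width <- base_width %||% 64L
  } else {
    learning_rate <- learning_rate %||% 2e-4
    epochs <- epochs %||% 20L
    decay_epochs <- decay_epochs %||% min(7L, epochs)
    depth <- depth %||% 3L
    base_width <- base_width %||% 16L
  }
  if (decay_epochs > epochs)
    stopf("decay_epochs (%d) must not exceed epochs (%d)", decay_epochs,
          epochs)
  structure(list(target = target, mode = mode,
                 learning_rate = learning_rate, batch_size = 1L,
                 normalization = "instance",
                 epochs = as.integer(epochs),
                 decay_epochs = as.integer(decay_epochs),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

target_channels <- function(target) {
  if (startsWith(target, "dab")) 3L else 1L
}

#' Generator loss
#'
#' Evaluates the three-term generator objective on 8-bit images (internally
#' rescaled to `[0, 1]`): `-log D_score + lambda * L1 - nu *
#' log((1 + SSIM)/2)`. SSIM uses the metrics module's global index with the
#' standard constants on unit dynamic range.
#'
#' @param G_out,y generated and ground-truth images in `[0, 255]`, same
#'   geometry
#' @param D_score discriminator probability for the generated pair,
#'   strictly inside (0, 1)
#' @param weights a [loss_weights()]
#' @param scale intensity scale of the inputs (255 for 8-bit)
#' @return list: `total`, `adversarial`, `l1`, `ssim_term`, `ssim`
#' @export
generator_loss <- function(G_out, y, D_score, weights = loss_weights(),
                           scale = 255) {
  G_out <- as_image_array(G_out); y <- as_image_array(y)
  if (!identical(dim(G_out), dim(y)))
    stopf("G_out and y geometry mismatch")
  assert_scalar_number(D_score, "D_score")
  if (D_score <= 0 || D_score >= 1)
    stopf("D_score must lie strictly inside (0, 1), got %g", D_score)
  g01 <- G_out / scale; y01 <- y / scale
  l1 <- mean(abs(g01 - y01))
  s <- ssim(g01 * 255, y01 * 255, ssim_params(dynamic_range = 255))
  adv <- -log(D_score)
  ssim_term <- -weights$nu_ssim * log((1 + s) / 2)
  list(total = adv + weights$lambda_l1 * l1 + ssim_term,
       adversarial = adv, l1 = weights$lambda_l1 * l1, ssim_term = ssim_term,
       ssim = s)
}

#' Discriminator loss
#'
#' `-log D_real - log(1 - D_fake)`; zero in the perfect-discriminator
#' limit.
#'
#' @param D_real,D_fake discriminator probabilities in (0, 1)
#' @return scalar loss
#' @export
discriminator_loss <- function(D_real, D_fake) {
  assert_scalar_number(D_real, "D_real")
  assert_scalar_number(D_fake, "D_fake")
  if (D_real <= 0 || D_real >= 1 || D_fake <= 0 || D_fake >= 1)
    stopf("discriminator scores must lie strictly inside (0, 1)")
  -log(D_real) - log(1 - D_fake)
}

# scale 8-bit [0,255] to network range [-1,1] and back
to_net <- function(x) x / 127.5 - 1
from_net <- function(x) clamp((x + 1) * 127.5, 0, 255)

# Select the y channels a target trains on. Fluorescence models train on a
# single channel (red = ptau / Cy3, green = abeta / Cy5); DAB models use
# all three RGB channels.
target_y <- function(y_img, target) {
  cy <- target_channels(target)
  if (dim(y_img)[3] == cy) return(y_img)
  if (cy == 1L && dim(y_img)[3] >= 2L) {
    ch <- if (target == "fluo_ptau") 1L else 2L
    return(y_img[, , ch, drop = FALSE])
  }
  stopf("pair's y has %d channel(s) but target '%s' needs %d",
        dim(y_img)[3], target, cy)
}

pair_tensors <- function(pair, target) {
  x <- to_net(as_image_array(pair$x))
  y_img <- target_y(as_image_array(pair$y), target)
  list(x = x, y = to_net(y_img))
}

#' Train a conditional-GAN virtual-staining model
#'
#' Alternates single-sample discriminator and generator Adam updates over
#' the training pairs; the learning rate is constant, then linearly decayed
#' over the final `decay_epochs`. Data order and weight initialization are
#' deterministic under `config$seed`. A zero-epoch run returns the
#' initialized bundle with an empty log.
#'
#' @param pairs list of training pairs, each `list(x = HxWx3 array in
#'   [0,255], y = stain patch in [0,255])`; elements with `role` not equal
#'   to `"train"` are ignored
#' @param target one of `dab_abeta`, `dab_ptau`, `fluo_abeta`, `fluo_ptau`
#' @param config a [gan_config()]
#' @param weights a [loss_weights()]
#' @param checkpoint_dir optional directory for periodic weight snapshots
#' @param verbose print one line per epoch
#' @return object of class `model_bundle`: the generator/discriminator,
#'   `train_log` (per-epoch mean losses), `config`, `weights`, `manifest`
#' @export
train_model <- function(pairs, target, config = gan_config(target),
                        weights = loss_weights(), checkpoint_dir = NULL,
                        verbose = FALSE) {
  if (!target %in% GAN_TARGETS) stopf("unknown target '%s'", target)
  roles <- vapply(pairs, function(p) p$role %||% "train", character(1))
  pairs <- pairs[roles == "train"]
  if (length(pairs) == 0L) stopf("empty training dataset for '%s'", target)
  cy <- target_channels(target)
  d0 <- dim(as_image_array(pairs[[1]]$x))
  bundle <- with_seed(config$seed, {
    G <- build_generator(3L, cy, depth = config$depth,
                         base_width = config$base_width)
    D <- build_discriminator(3L + cy, base_width = config$base_width)
    log_rows <- list()
    t_G <- 0L; t_D <- 0L
    n <- length(pairs)
    for (epoch in seq_len(config$epochs)) {
      # linear decay over the final decay_epochs
      plain <- config$epochs - config$decay_epochs
      lr <- if (epoch <= plain) config$learning_rate else {
        config$learning_rate *
          (1 - (epoch - plain) / (config$decay_epochs + 1L))
      }
      order_idx <- sample.int(n)
      acc <- c(G_total = 0, G_adv = 0, G_L1 = 0, G_SSIM = 0, D_loss = 0)
      for (step in seq_len(n)) {
        p <- pair_tensors(pairs[[order_idx[step]]], target)
        g <- generator_forward(G, p$x)
        npix <- length(g)

        # ---- discriminator update ----
        xy_real <- array(c(p$x, p$y), c(d0[1], d0[2], 3L + cy))
        d_real_map <- discriminator_forward(D, xy_real)
        d_real_map <- clamp(d_real_map, SCORE_EPS, 1 - SCORE_EPS)
        dmap_n <- length(d_real_map)
        grad_real <- array(-1 / (dmap_n * d_real_map), dim(d_real_map))
        discriminator_backward(D, grad_real)
        gW_real <- lapply(trainable_layers(D), function(e)
          list(dW = e$dW, db = e$db))
        xy_fake <- array(c(p$x, g), c(d0[1], d0[2], 3L + cy))
        d_fake_map <- discriminator_forward(D, xy_fake)
        d_fake_map <- clamp(d_fake_map, SCORE_EPS, 1 - SCORE_EPS)
        grad_fake <- array(1 / (dmap_n * (1 - d_fake_map)),
                           dim(d_fake_map))
        discriminator_backward(D, grad_fake)
        tl <- trainable_layers(D)
        for (i in seq_along(tl)) {  # accumulate both passes
          tl[[i]]$dW <- tl[[i]]$dW + gW_real[[i]]$dW
          tl[[i]]$db <- tl[[i]]$db + gW_real[[i]]$db
        }
        d_loss <- -mean(log(d_real_map)) - mean(log(1 - d_fake_map))
        t_D <- t_D + 1L
        adam_step(tl, lr, t = t_D)

        # ---- generator update ----
        xy_fake <- array(c(p$x, g), c(d0[1], d0[2], 3L + cy))
        d_fake_map <- discriminator_forward(D, xy_fake)
        d_fake_map <- clamp(d_fake_map, SCORE_EPS, 1 - SCORE_EPS)
        adv <- -mean(log(d_fake_map))
        grad_adv_map <- array(-1 / (dmap_n * d_fake_map), dim(d_fake_map))
        dxy <- discriminator_backward(D, grad_adv_map)
        dg_adv <- dxy[, , 3L + seq_len(cy), drop = FALSE]
        # fidelity terms on the [0, 1] scale; d(v01)/d(v_net) = 1/2
        g01 <- (g + 1) / 2; y01 <- (p$y + 1) / 2
        l1 <- mean(abs(g01 - y01))
        dg_l1 <- weights$lambda_l1 * sign(g01 - y01) / npix / 2
        ssim_vals <- numeric(cy); dg_ssim <- array(0, dim(g))
        for (ch in seq_len(cy)) {
          sg <- ssim_grad_channel(as.numeric(g01[, , ch]),
                                  as.numeric(y01[, , ch]),
                                  c1 = 0.01^2, c2 = 0.03^2)
          ssim_vals[ch] <- sg$value
          dg_ssim[, , ch] <- matrix(sg$grad, d0[1], d0[2])
        }
        s_mean <- mean(ssim_vals)
        ssim_term <- -weights$nu_ssim * log((1 + s_mean) / 2)
        # d(term)/dS = -nu / (1 + S); channel mean and [0,1] chain rule
        dg_ssim <- dg_ssim * (-weights$nu_ssim / (1 + s_mean)) / cy / 2
        dg <- dg_adv + dg_l1 + dg_ssim
        generator_backward(G, dg)
        t_G <- t_G + 1L
        adam_step(trainable_layers(G), lr, t = t_G)

        g_total <- adv + weights$lambda_l1 * l1 + ssim_term
        if (!is.finite(g_total) || !is.finite(d_loss))
          stopf("non-finite loss at epoch %d, step %d", epoch, step)
        acc <- acc + c(g_total, adv, weights$lambda_l1 * l1, ssim_term,
                       d_loss)
      }
      acc <- acc / n
      log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                      G_total = acc[["G_total"]],
                                      G_adv = acc[["G_adv"]],
                                      G_L1 = acc[["G_L1"]],
                                      G_SSIM = acc[["G_SSIM"]],
                                      D_loss = acc[["D_loss"]])
      if (verbose)
        message(sprintf(
          "epoch %3d  lr %.2g  G %.3f (adv %.3f, L1 %.3f, SSIM %.3f)  D %.3f",
          epoch, lr, acc[["G_total"]], acc[["G_adv"]], acc[["G_L1"]],
          acc[["G_SSIM"]], acc[["D_loss"]]))
      if (!is.null(checkpoint_dir) && config$checkpoint_every > 0L &&
          epoch %% config$checkpoint_every == 0L) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(list(G = net_state(G), D = net_state(D), epoch = epoch),
                file.path(checkpoint_dir, sprintf("epoch_%03d.rds", epoch)))
      }
    }
    list(G = G, D = D, log = do.call(rbind, log_rows %||% list()))
  })
  manifest <- list(target = target,
                   config_hash = fnv1a32(unclass(config)),
                   n_train = length(pairs),
                   patch_dim = d0)
  structure(list(generator = bundle$G, discriminator = bundle$D,
                 target = target, config = config, weights = weights,
                 train_log = bundle$log, manifest = manifest),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model bundle '%s' (%s mode): depth %d, width %d, %d epoch(s) trained\n",
              x$target, x$config$mode, x$config$depth, x$config$base_width,
              if (is.null(x$train_log)) 0L else nrow(x$train_log)))
  invisible(x)
}

#' Predict stain patches with a trained model
#'
#' Deterministic inference: one output patch per input, de-normalized to
#' 8-bit range.
#'
#' @param bundle a [train_model()] result
#' @param x_patches list of H x W x 3 compressed patches in `[0, 255]`
#'   (geometry must match training)
#' @return list of predicted patches in `[0, 255]`
#' @export
predict_patches <- function(bundle, x_patches) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (!is.list(x_patches) || inherits(x_patches, "compressed_image"))
    x_patches <- list(x_patches)
  lapply(x_patches, function(x) {
    if (inherits(x, "compressed_image")) x <- x$data
    x <- as_image_array(x)
    if (!identical(dim(x)[1:2], bundle$manifest$patch_dim[1:2]))
      stopf("patch geometry %s does not match training geometry %s",
            paste(dim(x)[1:2], collapse = "x"),
            paste(bundle$manifest$patch_dim[1:2], collapse = "x"))
    round(from_net(generator_forward(bundle$generator, to_net(x))))
  })
}

#' Save / load a trained model bundle
#' @param bundle a `model_bundle`
#' @param path RDS path
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(list(G_state = net_state(bundle$generator),
               D_state = net_state(bundle$discriminator),
               target = bundle$target, config = bundle$config,
               weights = bundle$weights, train_log = bundle$train_log,
               manifest = bundle$manifest), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  s <- readRDS(path)
  cy <- target_channels(s$target)
  G <- build_generator(3L, cy, depth = s$config$depth,
                       base_width = s$config$base_width)
  D <- build_discriminator(3L + cy, base_width = s$config$base_width)
  net_restore(G, s$G_state); net_restore(D, s$D_state)
  structure(list(generator = G, discriminator = D, target = s$target,
                 config = s$config, weights = s$weights,
                 train_log = s$train_log, manifest = s$manifest),
            class = "model_bundle")
}
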