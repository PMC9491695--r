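# End-to-end workflow orchestration.
#
# Every stage reads and writes documented on-disk artifacts inside one
# workspace directory, so any stage can be rerun from its persisted
# upstream outputs: simulate -> calibrate -> compress -> register ->
# dataset -> train -> predict -> stitch -> evaluate. A run manifest
# records, per executed stage, its inputs, outputs, config hash, derived
# seed and duration.

PIPELINE_STAGES <- c("simulate", "calibrate", "compress", "register",
                     "dataset", "train", "predict", "stitch", "evaluate")

#' Pipeline configuration
#'
#' @param out_dir workspace directory for all stage artifacts
#' @param phantom a [phantom_spec()] describing the simulated acquisition
#' @param target GAN model target (e.g. `"dab_ptau"`)
#' @param patch patch side in px
#' @param overlap_test test-patch overlap fraction in `[1/3, 1/2]`
#' @param gan a [gan_config()] for the training stage
#' @param weights a [loss_weights()]
#' @param metric_params a [ssim_params()] for evaluation
#' @param augment_data apply the twelve-fold augmentation to training pairs
#' @param seed global seed, fanned out per stage by stable hashing
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir,
                            phantom = phantom_spec(),
                            target = "dab_ptau",
                            patch = 64L,
                            overlap_test = 0.5,
                            gan = gan_config(target, mode = "tiny"),
                            weights = loss_weights(),
                            metric_params = ssim_params(),
                            augment_data = FALSE,
                            seed = 1L) {
  structure(list(out_dir = out_dir, phantom = phantom, target = target,
                 patch = as.integer(patch), overlap_test = overlap_test,
                 gan = gan, weights = weights,
                 metric_params = metric_params,
                 augment_data = isTRUE(augment_data),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every contract from the module types and returns all violations,
#' not just the first.
#'
#' @param config a [pipeline_config()]
#' @return the validated config (invisibly); with `collect = TRUE` a
#'   character vector of error messages (empty when valid)
#' @param collect return the error list instead of stopping
#' @export
validate_config <- function(config, collect = FALSE) {
  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)
  if (!inherits(config, "pipeline_config"))
    add("config must be a pipeline_config")
  else {
    if (!is.character(config$out_dir) || nchar(config$out_dir) == 0)
      add("out_dir must be a non-empty path")
    else if (!dir.exists(dirname(config$out_dir)))
      add(sprintf("parent of out_dir does not resolve: %s",
                  dirname(config$out_dir)))
    if (!inherits(config$phantom, "phantom_spec"))
      add("phantom must be a phantom_spec")
    if (!config$target %in% GAN_TARGETS)
      add(sprintf("unknown target '%s'", config$target))
    if (config$overlap_test < 1 / 3 - 1e-9 ||
        config$overlap_test > 1 / 2 + 1e-9)
      add(sprintf("overlap_test must be in [1/3, 1/2], got %g",
                  config$overlap_test))
    if (!inherits(config$gan, "train_config"))
      add("gan must be a train_config")
    else {
      if (config$gan$batch_size != 1L)
        add(sprintf("batch_size must be 1 under instance normalization, got %d",
                    config$gan$batch_size))
      if (config$gan$normalization != "instance")
        add("normalization must be 'instance'")
      if (config$gan$decay_epochs > config$gan$epochs)
        add("decay_epochs must not exceed epochs")
      if (config$gan$target != config$target)
        add(sprintf("gan config target '%s' differs from pipeline target '%s'",
                    config$gan$target, config$target))
    }
    if (!inherits(config$weights, "loss_weights"))
      add("weights must be a loss_weights")
    else {
      if (config$weights$lambda_l1 < 0) add("lambda_l1 must be >= 0")
      if (config$weights$nu_ssim < 0) add("nu_ssim must be >= 0")
    }
    if (config$patch < 16L) add("patch must be >= 16 px")
  }
  if (collect) return(errors)
  if (length(errors) > 0L)
    stopf("invalid pipeline config:\n  - %s",
          paste(errors, collapse = "\n  - "))
  invisible(config)
}

stage_paths <- function(out_dir) {
  list(cube_tif = file.path(out_dir, "hypercube.tif"),
       cube_wl = file.path(out_dir, "wavelengths.txt"),
       blank_tif = file.path(out_dir, "blank.tif"),
       spectrometer = file.path(out_dir, "spectrometer.csv"),
       stain_png = file.path(out_dir, "stain.png"),
       mask_png = file.path(out_dir, "mask.png"),
       coeff = file.path(out_dir, "coefficients.csv"),
       basis = file.path(out_dir, "pca_basis.json"),
       rgb = file.path(out_dir, "rgb.png"),
       transform = file.path(out_dir, "transform.json"),
       warped = file.path(out_dir, "stain_registered.png"),
       dataset = file.path(out_dir, "dataset"),
       model = file.path(out_dir, "model.rds"),
       train_log = file.path(out_dir, "train_log.csv"),
       pred_dir = file.path(out_dir, "predictions"),
       mosaic = file.path(out_dir, "mosaic.png"),
       report_dir = file.path(out_dir, "report"),
       manifest = file.path(out_dir, "run_manifest.csv"))
}

read_png_8bit <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  round(x * 255)
}

#' Run the virtual-staining pipeline on a simulated workspace
#'
#' Executes the requested stages in order. Each stage persists its outputs
#' under `config$out_dir` and later stages reload them from disk, so a
#' stage can be rerun in a fresh session as long as its upstream artifacts
#' exist.
#'
#' @param config a validated [pipeline_config()]
#' @param stages subset of
#'   `simulate, calibrate, compress, register, dataset, train, predict,
#'   stitch, evaluate` (default: all, in order)
#' @return data.frame run manifest (stage, inputs, outputs, config hash,
#'   seed, duration)
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  validate_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  paths <- stage_paths(config$out_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- fnv1a32(unclass(config))
  manifest <- list()
  note <- function(stage, inputs, outputs, seed, elapsed) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, inputs = paste(inputs, collapse = ";"),
      outputs = paste(outputs, collapse = ";"),
      config_hash = cfg_hash, seed = seed, duration_s = round(elapsed, 3))
  }
  need <- function(stage, files) {
    missing <- files[!file.exists(files)]
    if (length(missing) > 0L)
      stopf("stage '%s' needs artifacts from an earlier stage; run it first (missing: %s)",
            stage, paste(basename(missing), collapse = ", "))
  }
  is_dab <- startsWith(config$target, "dab")

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    seed <- derive_seed(config$seed, stage)
    switch(stage,
      simulate = {
        spec <- config$phantom
        spec$seed <- derive_seed(config$seed, "phantom")
        gt <- render_phantom(spec)
        # normalized intensities are stored as 16-bit counts on disk
        write_hypercube(hypercube(gt$hypercube$data * 65535,
                                  gt$hypercube$wavelengths),
                        paths$cube_tif, paths$cube_wl)
        blank <- render_blank(spec)
        write_hypercube(hypercube(blank$data * 65535, blank$wavelengths),
                        paths$blank_tif, paths$cube_wl)
        write.csv(phantom_spectrometer(spec), paths$spectrometer,
                  row.names = FALSE)
        stain <- if (is_dab) gt$dab_image else gt$fluor_image
        png::writePNG(stain$data / 255, paths$stain_png)
        png::writePNG(gt$label_mask / 255, paths$mask_png)
        note(stage, character(0),
             c(paths$cube_tif, paths$blank_tif, paths$stain_png,
               paths$mask_png, paths$spectrometer),
             seed, proc.time()[["elapsed"]] - t0)
      },
      calibrate = {
        need(stage, c(paths$blank_tif, paths$spectrometer))
        blank <- load_hypercube(paths$blank_tif, paths$cube_wl)
        blank$data <- blank$data / 65535  # stored as scaled counts
        tab <- estimate_coefficients(blank, read.csv(paths$spectrometer))
        write_calibration(tab, paths$coeff)
        note(stage, c(paths$blank_tif, paths$spectrometer), paths$coeff,
             seed, proc.time()[["elapsed"]] - t0)
      },
      compress = {
        need(stage, c(paths$cube_tif, paths$coeff))
        cube <- load_hypercube(paths$cube_tif, paths$cube_wl)
        cube$data <- cube$data / 65535
        cube <- apply_calibration(cube, read_calibration(paths$coeff))
        basis <- fit_pca(cube)
        rgb <- project_to_rgb(cube, basis)
        write_pca_basis(basis, paths$basis, fit_stats = rgb$fit_stats)
        png::writePNG(rgb$data / 255, paths$rgb)
        note(stage, paths$cube_tif, c(paths$basis, paths$rgb), seed,
             proc.time()[["elapsed"]] - t0)
      },
      register = {
        need(stage, c(paths$cube_tif, paths$stain_png))
        cube <- load_hypercube(paths$cube_tif, paths$cube_wl)
        stain <- read_png_8bit(paths$stain_png)
        fixed <- cube$data[, , band_max_contrast(cube)]
        fixed <- fixed / max(fixed) * 255
        moving <- if (is_dab) {
          stain_image(stain, "dab")
        } else stain_image(stain, "fluorescence")
        # complement so stain contrast matches transmission contrast
        mov_for_fit <- if (is_dab) moving else complement_8bit(moving)
        fit <- register_similarity(mov_for_fit, fixed,
                                   bg = if (is_dab) 255 else 0)
        jsonlite::write_json(
          list(rotation = fit$transform$rotation,
               scale = fit$transform$scale,
               translation = fit$transform$translation,
               score = fit$score, degenerate = fit$degenerate),
          paths$transform, auto_unbox = TRUE, digits = NA)
        warped <- warp_similarity(moving$data, fit$transform,
                                  bg = if (is_dab) 255 else 0)
        png::writePNG(clamp(warped, 0, 255) / 255, paths$warped)
        note(stage, c(paths$cube_tif, paths$stain_png),
             c(paths$transform, paths$warped), seed,
             proc.time()[["elapsed"]] - t0)
      },
      dataset = {
        need(stage, c(paths$rgb, paths$warped, paths$mask_png))
        rgb <- read_png_8bit(paths$rgb)
        stain <- read_png_8bit(paths$warped)
        H <- dim(rgb)[1]; W <- dim(rgb)[2]
        ps <- config$patch
        holdout <- if (H >= ps && W >= 2L * ps)
          list(rows = c(1L, H), cols = c(W - ps + 1L, W))
        y_img <- stain_image(stain, if (is_dab) "dab" else "fluorescence")
        if (!is_dab) {
          mask <- read_png_8bit(paths$mask_png)[, , 1]
          lumen <- mask == PHANTOM_CLASSES[["lumen"]]
          y_img <- mask_lumen_negative(y_img, lumen)
        }
        pairs <- make_patches(rgb, y_img, patch = ps, holdout = holdout,
                              overlap_test = config$overlap_test,
                              seed = seed)
        pairs <- discard_damaged(pairs)$kept
        if (config$augment_data) {
          is_train <- vapply(pairs, function(p) p$role == "train",
                             logical(1))
          pairs <- c(augment_dataset(pairs[is_train], seed = seed),
                     pairs[!is_train])
        }
        write_dataset(pairs, paths$dataset)
        note(stage, c(paths$rgb, paths$warped),
             file.path(paths$dataset, "manifest.csv"), seed,
             proc.time()[["elapsed"]] - t0)
      },
      train = {
        need(stage, file.path(paths$dataset, "manifest.csv"))
        pairs <- read_dataset(paths$dataset,
                              if (is_dab) "dab" else "fluorescence")
        gcfg <- config$gan
        gcfg$seed <- seed
        bundle <- train_model(pairs, config$target, gcfg, config$weights)
        save_model(bundle, paths$model)
        if (!is.null(bundle$train_log))
          write.csv(bundle$train_log, paths$train_log, row.names = FALSE)
        note(stage, file.path(paths$dataset, "manifest.csv"),
             paths$model, seed, proc.time()[["elapsed"]] - t0)
      },
      predict = {
        need(stage, c(paths$model,
                      file.path(paths$dataset, "manifest.csv")))
        bundle <- load_model(paths$model)
        pairs <- read_dataset(paths$dataset,
                              if (is_dab) "dab" else "fluorescence")
        test <- Filter(function(p) p$role == "test", pairs)
        if (length(test) == 0L) test <- utils::head(pairs, 4L)
        preds <- predict_patches(bundle, lapply(test, `[[`, "x"))
        dir.create(paths$pred_dir, showWarnings = FALSE)
        for (i in seq_along(preds)) {
          y <- preds[[i]]
          if (dim(y)[3] == 1L) y <- y[, , 1]
          png::writePNG(y / 255,
                        file.path(paths$pred_dir,
                                  sprintf("pred_%04d.png", i)))
        }
        note(stage, paths$model, paths$pred_dir, seed,
             proc.time()[["elapsed"]] - t0)
      },
      stitch = {
        need(stage, paths$pred_dir)
        files <- sort(list.files(paths$pred_dir, full.names = TRUE))
        tiles <- lapply(files, read_png_8bit)
        if (length(tiles) >= 2L) {
          overlap <- config$overlap_test
          plan <- mosaic_plan(utils::head(tiles, 3L),
                              overlap_fraction = overlap)
          mosaic <- stitch(plan, utils::head(tiles, 3L))
        } else {
          mosaic <- tiles[[1]]
        }
        if (length(dim(mosaic)) == 3L && dim(mosaic)[3] == 1L)
          mosaic <- mosaic[, , 1]
        png::writePNG(clamp(mosaic, 0, 255) / 255, paths$mosaic)
        note(stage, paths$pred_dir, paths$mosaic, seed,
             proc.time()[["elapsed"]] - t0)
      },
      evaluate = {
        need(stage, c(paths$pred_dir,
                      file.path(paths$dataset, "manifest.csv")))
        pairs <- read_dataset(paths$dataset,
                              if (is_dab) "dab" else "fluorescence")
        test <- Filter(function(p) p$role == "test", pairs)
        if (length(test) == 0L) test <- utils::head(pairs, 4L)
        files <- sort(list.files(paths$pred_dir, full.names = TRUE))
        preds <- lapply(files, read_png_8bit)
        n <- min(length(preds), length(test))
        truths <- lapply(test[seq_len(n)], function(p)
          target_y(as_image_array(p$y), config$target))
        report <- evaluate_model(preds[seq_len(n)], truths,
                                 params = config$metric_params,
                                 model = config$target)
        write_model_report(report, paths$report_dir)
        note(stage, paths$pred_dir, paths$report_dir, seed,
             proc.time()[["elapsed"]] - t0)
      }
    )
  }
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, paths$manifest, row.names = FALSE)
  manifest
}

#' Read a patch dataset written by [write_dataset()]
#' @param dir dataset directory
#' @param kind stain kind of the y patches
#' @return list of pairs
#' @export
read_dataset <- function(dir, kind = "dab") {
  man <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(man)), function(i) {
    id <- man$patch_id[i]
    list(x = read_png_8bit(file.path(dir, "x", paste0(id, ".png"))),
         y = read_png_8bit(file.path(dir, "y", paste0(id, ".png"))),
         role = man$role[i],
         origin = c(row = man$origin_row[i], col = man$origin_col[i]),
         y_kind = kind)
  })
}
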