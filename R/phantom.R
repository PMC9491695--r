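# Synthetic retinal-phantom generator.
#
# Stands in for donor tissue throughout the test suite: layered retinal
# cross-sections (NFL..ONL bands) carrying planted amyloid-beta (abeta) and
# phosphorylated-tau (ptau) deposits with the two characteristic transmission
# signatures -- ptau with an elevated, flat ("flat hat") transmittance over
# 550-650 nm, abeta with a Rayleigh-like (lambda^-4) transmission deficit
# over 450-600 nm -- plus blood vessels whose lumen can carry a spurious
# fluorescence artifact. Each rendering returns the hypercube together with
# paired DAB and immunofluorescence ground-truth images and a per-pixel
# class mask.

PHANTOM_CLASSES <- c(background = 0L, tissue = 1L, abeta = 2L, ptau = 3L,
                     lumen = 4L)

# Smooth baseline tissue transmittance: low-order polynomial in lambda
# peaking near 600 nm. Kept below 1 so the ptau plateau (1.3x the 550-650 nm
# baseline mean) remains a valid transmittance.
tissue_baseline <- function(wavelengths) {
  0.70 - 0.62 * ((wavelengths - 600) / 300)^2
}

# Raised-cosine window equal to 1 on [550, 650] nm with `shoulder`-nm
# smooth transitions on both sides.
flat_hat_window <- function(wavelengths, shoulder = 40) {
  w <- numeric(length(wavelengths))
  w[wavelengths >= 550 & wavelengths <= 650] <- 1
  lo <- wavelengths >= (550 - shoulder) & wavelengths < 550
  hi <- wavelengths > 650 & wavelengths <= (650 + shoulder)
  w[lo] <- 0.5 * (1 + cos(pi * (550 - wavelengths[lo]) / shoulder))
  w[hi] <- 0.5 * (1 + cos(pi * (wavelengths[hi] - 650) / shoulder))
  w
}

#' Model transmittance spectrum of a tissue class
#'
#' Generates the per-class transmittance curves that the phantom plants:
#' * `tissue` -- a smooth baseline peaking near 600 nm;
#' * `ptau` -- the baseline blended toward a plateau that is elevated and
#'   flat over 550-650 nm (the "flat hat"); the plateau level is 1.3x the
#'   baseline mean over that window at `amplitude` 1;
#' * `abeta` -- the baseline attenuated by a Rayleigh-like `lambda^-4`
#'   factor scaled so `amplitude` 1 gives a 30% transmission deficit at
#'   500 nm.
#'
#' @param wavelengths numeric wavelengths in nm, within `[420, 720]`
#' @param class one of `"tissue"`, `"abeta"`, `"ptau"`
#' @param amplitude deposit strength in `[0, 1]`; 0 returns the tissue
#'   baseline for every class
#' @return transmittance spectrum in `(0, 1]`, one value per wavelength
#' @export
make_tissue_spectrum <- function(wavelengths, class, amplitude = 1) {
  wavelengths <- as.numeric(wavelengths)
  if (any(wavelengths < 420 - 1e-9) || any(wavelengths > 720 + 1e-9))
    stopf("wavelengths must lie within [420, 720] nm")
  assert_scalar_number(amplitude, "amplitude")
  if (amplitude < 0 || amplitude > 1)
    stopf("amplitude must be in [0, 1], got %g", amplitude)
  base <- tissue_baseline(wavelengths)
  switch(as.character(class),
    tissue = base,
    ptau = {
      w <- flat_hat_window(wavelengths) * amplitude
      plateau <- 1.3 * mean(tissue_baseline(seq(550, 650, by = 1)))
      (1 - w) * base + w * plateau
    },
    abeta = base * (1 - 0.3 * amplitude * (500 / wavelengths)^4),
    stopf("unknown tissue class: '%s' (expected tissue, abeta or ptau)",
          class)
  )
}

#' Specify a retinal phantom
#'
#' The defaults describe the study conditions used across the package: a
#' layered cross-section strip, a handful of abeta/ptau deposits in the
#' layers where the respective deposits are reported (abeta in NFL/GCL and
#' ONL, ptau in the OPL and inner plexiform layers), one blood vessel with a
#' fluorescence lumen artifact, and mild sensor noise.
#'
#' @param image_shape `(rows, cols)` in pixels
#' @param wavelengths acquisition axis in nm (default [band_axis()] =
#'   420-720 nm step 2)
#' @param layer_boundaries ordered row fractions in (0,1) delimiting the
#'   NFL, GCL, IPL, INL, OPL, ONL bands (7 values); tissue spans the first
#'   to the last fraction, with background above and below
#' @param deposit_list list of deposits, each
#'   `list(class = "abeta"|"ptau", center = c(row, col), radius = px,
#'   amplitude in (0,1])`; `NULL` gives the default roster scaled to
#'   `image_shape`
#' @param vessel_list list of vessels, each `list(center = c(row, col),
#'   lumen_radius, wall_thickness, lumen_artifact = TRUE/FALSE)`
#' @param noise_sd additive Gaussian noise SD in normalized intensity
#' @param dab_class which deposit class the DAB rendering stains
#'   (one DAB slide stains a single protein)
#' @param seed integer RNG seed for the noise field
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(image_shape = c(96, 128),
                         wavelengths = band_axis(),
                         layer_boundaries = c(0.10, 0.20, 0.32, 0.46,
                                              0.58, 0.70, 0.90),
                         deposit_list = NULL,
                         vessel_list = NULL,
                         noise_sd = 0.01,
                         dab_class = "ptau",
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16L))
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (any(diff(layer_boundaries) <= 0) || any(layer_boundaries <= 0) ||
      any(layer_boundaries >= 1))
    stopf("layer_boundaries must be strictly increasing fractions in (0,1)")
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!dab_class %in% c("abeta", "ptau"))
    stopf("dab_class must be 'abeta' or 'ptau'")
  H <- image_shape[1]; W <- image_shape[2]
  if (is.null(deposit_list)) {
    deposit_list <- list(
      list(class = "ptau", center = c(round(0.63 * H), round(0.30 * W)),
           radius = max(4, round(0.055 * min(H, W))), amplitude = 0.9),
      list(class = "ptau", center = c(round(0.38 * H), round(0.72 * W)),
           radius = max(3, round(0.04 * min(H, W))), amplitude = 0.8),
      list(class = "abeta", center = c(round(0.15 * H), round(0.55 * W)),
           radius = max(4, round(0.05 * min(H, W))), amplitude = 0.9),
      list(class = "abeta", center = c(round(0.78 * H), round(0.82 * W)),
           radius = max(3, round(0.045 * min(H, W))), amplitude = 0.85)
    )
  }
  if (is.null(vessel_list)) {
    vessel_list <- list(
      list(center = c(round(0.26 * H), round(0.14 * W)),
           lumen_radius = max(3, round(0.04 * min(H, W))),
           wall_thickness = 2, lumen_artifact = TRUE)
    )
  }
  for (d in deposit_list) {
    if (!d$class %in% c("abeta", "ptau"))
      stopf("unknown deposit class: '%s'", d$class)
    if (d$radius <= 0) stopf("deposit radius must be > 0")
    if (d$amplitude <= 0 || d$amplitude > 1)
      stopf("deposit amplitude must be in (0, 1]")
    if (d$center[1] - d$radius < 1 || d$center[1] + d$radius > H ||
        d$center[2] - d$radius < 1 || d$center[2] + d$radius > W)
      stopf("deposit at (%d, %d) with radius %g lies outside the %d x %d image",
            d$center[1], d$center[2], d$radius, H, W)
  }
  for (v in vessel_list) {
    r <- v$lumen_radius + v$wall_thickness
    if (v$lumen_radius <= 0 || v$wall_thickness < 0)
      stopf("vessel radii must be positive")
    if (v$center[1] - r < 1 || v$center[1] + r > H ||
        v$center[2] - r < 1 || v$center[2] + r > W)
      stopf("vessel at (%d, %d) lies outside the image", v$center[1],
            v$center[2])
  }
  structure(list(image_shape = image_shape, wavelengths = wavelengths,
                 layer_boundaries = layer_boundaries,
                 deposit_list = deposit_list, vessel_list = vessel_list,
                 noise_sd = noise_sd, dab_class = dab_class,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# System spectral response (camera quantum efficiency x tunable-filter
# transmission), rising toward the red; this is the envelope calibration
# must remove. The lamp itself is modeled as spectrally flat at the sample
# stage, which is what the phantom's reference spectrometer reports.
phantom_response <- function(wavelengths) {
  0.35 + 0.65 * (wavelengths - 420) / 300
}

PHANTOM_LAMP_LEVEL <- 100  # flat lamp intensity seen by the spectrometer

#' Reference spectrometer table of the phantom's lamp
#'
#' The phantom's lamp is spectrally flat at the sample stage; all spectral
#' shaping of the recorded counts comes from the system response that
#' calibration removes.
#'
#' @param spec a [phantom_spec()]
#' @return data.frame `(wavelength_nm, intensity)` covering the axis
#' @export
phantom_spectrometer <- function(spec) {
  wl <- range(spec$wavelengths)
  grid <- seq(wl[1] - 2, wl[2] + 2, by = 1)
  data.frame(wavelength_nm = grid,
             intensity = rep(PHANTOM_LAMP_LEVEL, length(grid)))
}

# Smooth separable vignetting profile, max 1 at the image center.
phantom_illumination <- function(H, W) {
  vr <- 1 - 0.3 * ((seq_len(H) - (H + 1) / 2) / H)^2
  vc <- 1 - 0.3 * ((seq_len(W) - (W + 1) / 2) / W)^2
  outer(vr, vc)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

disk_mask <- function(H, W, center, radius) {
  outer((seq_len(H) - center[1])^2, (seq_len(W) - center[2])^2, `+`) <=
    radius^2
}

# relative transmittance multipliers per retinal layer (spatial texture)
LAYER_FACTORS <- c(NFL = 1.00, GCL = 0.92, IPL = 1.00, INL = 0.87,
                   OPL = 0.95, ONL = 0.90)
BG_TRANSMITTANCE <- 0.95
LUMEN_TRANSMITTANCE <- 0.93
DAB_BROWN <- c(90, 60, 30)
DAB_TISSUE <- c(228, 221, 214)
DAB_BACKGROUND <- c(245, 243, 240)

#' Render a retinal phantom
#'
#' Builds the hypercube (per-pixel class transmittance times a separable
#' illumination profile times the system spectral response, plus clipped additive
#' Gaussian noise), the paired DAB and immunofluorescence ground-truth
#' images, and the per-pixel label mask. Rendering is deterministic under
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()]
#' @return an object of class `ground_truth_pair` with elements
#'   `hypercube`, `dab_image` (H x W x 3, 8-bit), `fluor_image`
#'   (H x W x 3, 8-bit; green = abeta, red = ptau), `label_mask` (integer
#'   matrix, codes in `PHANTOM_CLASSES`: 0 background, 1 tissue, 2 abeta,
#'   3 ptau, 4 lumen), `illumination`, `response`, `fluor_clean` (the
#'   artifact-free fluorescence rendering) and `spec`
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  wl <- spec$wavelengths; B <- length(wl)

  # --- label mask -----------------------------------------------------
  mask <- matrix(PHANTOM_CLASSES[["background"]], H, W)
  top <- round(spec$layer_boundaries[1] * H)
  bot <- round(spec$layer_boundaries[length(spec$layer_boundaries)] * H)
  mask[seq(max(1, top), min(H, bot)), ] <- PHANTOM_CLASSES[["tissue"]]
  layer_of_row <- rep(NA_integer_, H)
  bounds <- round(spec$layer_boundaries * H)
  for (k in seq_len(length(bounds) - 1L)) {
    rows <- seq(max(1, bounds[k]), min(H, bounds[k + 1]))
    layer_of_row[rows] <- k
  }
  wall <- matrix(FALSE, H, W); lumen <- matrix(FALSE, H, W)
  artifact_lumen <- matrix(FALSE, H, W)
  for (v in spec$vessel_list) {
    outer_d <- disk_mask(H, W, v$center, v$lumen_radius + v$wall_thickness)
    inner_d <- disk_mask(H, W, v$center, v$lumen_radius)
    wall <- wall | (outer_d & !inner_d)
    lumen <- lumen | inner_d
    if (isTRUE(v$lumen_artifact)) artifact_lumen <- artifact_lumen | inner_d
  }
  mask[lumen] <- PHANTOM_CLASSES[["lumen"]]
  amp <- matrix(0, H, W)  # deposit amplitude map
  for (d in spec$deposit_list) {
    dm <- disk_mask(H, W, d$center, d$radius)
    mask[dm] <- PHANTOM_CLASSES[[d$class]]
    amp[dm] <- d$amplitude
  }

  # --- hypercube ------------------------------------------------------
  illum <- phantom_illumination(H, W)
  resp <- phantom_response(wl)
  base <- tissue_baseline(wl)
  layer_fac <- unname(LAYER_FACTORS)
  cube <- array(0, c(H, W, B))
  # transmittance per pixel, assembled band by band
  tissue_px <- mask == PHANTOM_CLASSES[["tissue"]] & !wall
  wall_px <- mask == PHANTOM_CLASSES[["tissue"]] & wall
  lumen_px <- mask == PHANTOM_CLASSES[["lumen"]]
  bg_px <- mask == PHANTOM_CLASSES[["background"]]
  fac_map <- matrix(1, H, W)
  for (r in seq_len(H)) {
    if (!is.na(layer_of_row[r])) fac_map[r, ] <- layer_fac[layer_of_row[r]]
  }
  # per-class deposit spectra are looked up per unique amplitude
  dep_classes <- c("abeta", "ptau")
  for (b in seq_len(B)) {
    tr <- matrix(BG_TRANSMITTANCE, H, W)
    tr[tissue_px] <- base[b] * fac_map[tissue_px]
    tr[wall_px] <- base[b] * fac_map[wall_px] * 0.80
    tr[lumen_px] <- LUMEN_TRANSMITTANCE
    cube[, , b] <- tr
  }
  for (cl in dep_classes) {
    code <- PHANTOM_CLASSES[[cl]]
    sel <- mask == code
    if (!any(sel)) next
    for (a in unique(amp[sel])) {
      spec_a <- make_tissue_spectrum(wl, cl, a)
      px <- sel & amp == a
      idx <- which(px)
      for (b in seq_len(B)) cube[idx + (b - 1L) * H * W] <- spec_a[b]
    }
  }
  for (b in seq_len(B)) cube[, , b] <- cube[, , b] * illum * resp[b]
  if (spec$noise_sd > 0) {
    cube <- with_seed(spec$seed, {
      cube + array(rnorm(length(cube), sd = spec$noise_sd), dim(cube))
    })
    cube <- clamp(cube, 0, 1)
  }

  # --- DAB rendering --------------------------------------------------
  dab <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    m <- matrix(DAB_BACKGROUND[ch], H, W)
    m[tissue_px | wall_px] <- DAB_TISSUE[ch]
    m[wall_px] <- DAB_TISSUE[ch] * 0.9
    m[lumen_px] <- DAB_BACKGROUND[ch]
    dab[, , ch] <- m
  }
  stained <- mask == PHANTOM_CLASSES[[spec$dab_class]]
  other <- mask == PHANTOM_CLASSES[[setdiff(dep_classes, spec$dab_class)]]
  for (ch in 1:3) {
    m <- dab[, , ch]
    # stained deposits: optical-density blend toward DAB brown
    m[stained] <- (1 - amp[stained]) * DAB_TISSUE[ch] +
      amp[stained] * DAB_BROWN[ch]
    m[other] <- DAB_TISSUE[ch]  # unstained protein: plain tissue
    dab[, , ch] <- m
  }
  dab <- round(clamp(dab, 0, 255))

  # --- fluorescence rendering ----------------------------------------
  fluor_clean <- array(0, c(H, W, 3))
  g <- matrix(0, H, W); r <- matrix(0, H, W)
  sel_a <- mask == PHANTOM_CLASSES[["abeta"]]
  sel_p <- mask == PHANTOM_CLASSES[["ptau"]]
  g[sel_a] <- amp[sel_a] * 255
  r[sel_p] <- amp[sel_p] * 255
  fluor_clean[, , 1] <- r   # red channel = ptau (Cy3 pseudocolor)
  fluor_clean[, , 2] <- g   # green channel = abeta (Cy5 pseudocolor)
  fluor_clean <- round(clamp(fluor_clean, 0, 255))
  fluor <- fluor_clean
  if (any(artifact_lumen)) {
    for (ch in 1:2) {
      m <- fluor[, , ch]
      m[artifact_lumen] <- 180  # spurious autofluorescence in the lumen
      fluor[, , ch] <- m
    }
  }

  structure(list(
    hypercube = hypercube(cube, wl, meta = list(source = "phantom",
                                                seed = spec$seed)),
    dab_image = stain_image(dab, kind = "dab"),
    fluor_image = stain_image(fluor, kind = "fluorescence"),
    fluor_clean = stain_image(fluor_clean, kind = "fluorescence"),
    label_mask = mask,
    illumination = illum,
    response = resp,
    spec = spec), class = "ground_truth_pair")
}

#' Render a blank (tissue-free) acquisition
#'
#' Used as the blank-slide acquisition for calibration-coefficient
#' estimation: uniform background transmittance times illumination times
#' system spectral response, with the spec's noise.
#'
#' @param spec a [phantom_spec()]
#' @return a [hypercube()]
#' @export
render_blank <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  wl <- spec$wavelengths
  illum <- phantom_illumination(H, W)
  resp <- phantom_response(wl)
  cube <- array(0, c(H, W, length(wl)))
  for (b in seq_along(wl))
    cube[, , b] <- BG_TRANSMITTANCE * illum * resp[b]
  if (spec$noise_sd > 0) {
    cube <- with_seed(spec$seed + 7L, {
      cube + array(rnorm(length(cube), sd = spec$noise_sd), dim(cube))
    })
    cube <- clamp(cube, 0, 1)
  }
  hypercube(cube, wl, meta = list(source = "phantom_blank"))
}

#' Construct a stain image
#'
#' 8-bit ground-truth stain image. DAB images are RGB brightfield
#' (brown-on-light); fluorescence images use red = ptau (Cy3), green =
#' abeta (Cy5) on a black background.
#'
#' @param data numeric H x W x C array (or H x W matrix) of integer values
#'   in `[0, 255]`
#' @param kind `"dab"` or `"fluorescence"`
#' @return an object of class `stain_image`
#' @export
stain_image <- function(data, kind = c("dab", "fluorescence")) {
  kind <- match.arg(kind)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is_8bit(data))
    stopf("stain image must hold integers in [0, 255]")
  structure(list(data = data, kind = kind), class = "stain_image")
}

#' @export
print.stain_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("stain image (%s): %d x %d px, %d channel(s)\n",
              x$kind, d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.stain_image <- function(x) dim(x$data)

#' Warp a stain image by a known similarity transform
#'
#' Registration fixture: applies a known similarity warp and returns both
#' the warped image and the exact analytic inverse transform, so recovery
#' can be scored against ground truth.
#'
#' @param image a [stain_image()]
#' @param transform a [similarity_transform()] with `|rotation| <= 15` deg
#'   and scale in `[0.8, 1.25]`
#' @return list with elements `warped` (a `stain_image`) and `inverse`
#'   (a `similarity_transform`)
#' @export
apply_known_warp <- function(image, transform) {
  stopifnot(inherits(image, "stain_image"),
            inherits(transform, "similarity_transform"))
  if (abs(transform$rotation) > 15)
    stopf("|rotation| must be <= 15 degrees for warp fixtures")
  if (transform$scale < 0.8 || transform$scale > 1.25)
    stopf("scale must be in [0.8, 1.25] for warp fixtures")
  bg <- if (image$kind == "dab") 255 else 0
  warped <- warp_similarity(image$data, transform, bg = bg)
  list(warped = stain_image(round(clamp(warped, 0, 255)), image$kind),
       inverse = invert_similarity(transform))
}

#' Write / read a phantom spec as a YAML config
#' @param spec a [phantom_spec()]
#' @param path YAML file path
#' @return `read_phantom_spec` returns a `phantom_spec`
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  phantom_spec(image_shape = unlist(x$image_shape),
               wavelengths = unlist(x$wavelengths),
               layer_boundaries = unlist(x$layer_boundaries),
               deposit_list = lapply(x$deposit_list, function(d) {
                 d$center <- unlist(d$center); d
               }),
               vessel_list = lapply(x$vessel_list, function(v) {
                 v$center <- unlist(v$center); v
               }),
               noise_sd = x$noise_sd, dab_class = x$dab_class,
               seed = x$seed)
}

#' Randomized phantom specification
#'
#' Draws a phantom with randomly placed deposits and vessels (deterministic
#' under `seed`): 5-9 deposits of mixed class with amplitudes 0.6-1,
#' radii 3-7 px, placed inside the tissue band, and 1-2 vessels with
#' fluorescence lumen artifacts in about half the draws. Used to produce
#' varied strips for dataset generation.
#'
#' @param seed integer seed
#' @param image_shape `(rows, cols)` in px
#' @param noise_sd additive noise SD
#' @param dab_class class stained in the DAB rendering
#' @return a [phantom_spec()]
#' @export
random_phantom_spec <- function(seed, image_shape = c(64, 320),
                                noise_sd = 0.02, dab_class = "ptau") {
  H <- image_shape[1]; W <- image_shape[2]
  boundaries <- c(0.10, 0.20, 0.32, 0.46, 0.58, 0.70, 0.90)
  with_seed(seed, {
    n_dep <- sample(5:9, 1)
    deposits <- lapply(seq_len(n_dep), function(i) {
      radius <- sample(3:7, 1)
      r_lo <- ceiling(boundaries[1] * H) + radius + 1
      r_hi <- floor(boundaries[7] * H) - radius - 1
      list(class = sample(c("abeta", "ptau"), 1),
           center = c(sample(r_lo:r_hi, 1),
                      sample((radius + 1):(W - radius - 1), 1)),
           radius = radius,
           amplitude = runif(1, 0.6, 1))
    })
    n_ves <- sample(1:2, 1)
    vessels <- lapply(seq_len(n_ves), function(i) {
      lr <- sample(3:5, 1); wt <- 2
      r <- lr + wt
      list(center = c(sample((ceiling(0.2 * H) + r):(floor(0.8 * H) - r), 1),
                      sample((r + 1):(W - r - 1), 1)),
           lumen_radius = lr, wall_thickness = wt,
           lumen_artifact = runif(1) < 0.5)
    })
    phantom_spec(image_shape = image_shape,
                 layer_boundaries = boundaries,
                 deposit_list = deposits, vessel_list = vessels,
                 noise_sd = noise_sd, dab_class = dab_class,
                 seed = seed)
  })
}

#' Generate paired virtual-staining patches from random phantoms
#'
#' End-to-end fixture generator: renders randomized phantom strips,
#' estimates and applies lamp calibration from a blank acquisition, fits a
#' per-strip 3-component PCA, projects to an 8-bit RGB image, and cuts
#' paired patches against the requested ground-truth rendering
#' (fluorescence ground truth is first cleaned by lumen negative
#' labeling).
#'
#' @param n_pairs number of pairs to generate
#' @param patch patch side in px
#' @param seed integer seed (phantom `i` uses `seed * 1000 + i`)
#' @param target one of `dab_abeta`, `dab_ptau`, `fluo_abeta`, `fluo_ptau`
#' @param noise_sd phantom noise SD
#' @param strip_cols width of each phantom strip in px
#' @return list of pairs as produced by [make_patches()]
#' @export
phantom_pairs <- function(n_pairs, patch = 64L, seed = 1L,
                          target = "dab_ptau", noise_sd = 0.02,
                          strip_cols = 320L) {
  is_dab <- startsWith(target, "dab")
  dab_class <- if (target == "dab_abeta") "abeta" else "ptau"
  pairs <- list()
  i <- 0L
  while (length(pairs) < n_pairs) {
    i <- i + 1L
    spec <- random_phantom_spec(seed * 1000L + i,
                                image_shape = c(patch, strip_cols),
                                noise_sd = noise_sd, dab_class = dab_class)
    gt <- render_phantom(spec)
    tab <- estimate_coefficients(render_blank(spec),
                                 phantom_spectrometer(spec))
    cal <- apply_calibration(gt$hypercube, tab)
    rgb <- project_to_rgb(cal, fit_pca(cal))
    y <- if (is_dab) gt$dab_image else {
      mask_lumen_negative(gt$fluor_image,
                          gt$label_mask == PHANTOM_CLASSES[["lumen"]])
    }
    pairs <- c(pairs, make_patches(rgb$data, y, patch = patch,
                                   holdout = NULL, val_fraction = 0))
  }
  pairs[seq_len(n_pairs)]
}
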