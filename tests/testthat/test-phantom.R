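wl <- band_axis()

test_that("ptau spectrum is a flat elevated hat over 550-650 nm", {
  base <- make_tissue_spectrum(wl, "tissue")
  ptau <- make_tissue_spectrum(wl, "ptau", amplitude = 1)
  hat <- wl >= 550 & wl <= 650
  cv <- function(v) sd(v) / mean(v)
  expect_lt(cv(ptau[hat]), cv(base[hat]))
  expect_gt(mean(ptau[hat]), mean(base[hat]))
  # flatness sharpens monotonically with amplitude
  cvs <- vapply(c(0.25, 0.5, 0.75, 1),
                function(a) cv(make_tissue_spectrum(wl, "ptau", a)[hat]),
                numeric(1))
  expect_true(all(diff(cvs) < 0))
  expect_true(all(ptau > 0 & ptau <= 1))
})

test_that("zero-amplitude deposits reduce to the tissue baseline", {
  base <- make_tissue_spectrum(wl, "tissue")
  expect_identical(make_tissue_spectrum(wl, "abeta", 0), base)
  expect_identical(make_tissue_spectrum(wl, "ptau", 0), base)
})

test_that("abeta spectrum shows the lambda^-4 transmission dip", {
  base <- make_tissue_spectrum(wl, "tissue")
  abeta <- make_tissue_spectrum(wl, "abeta", amplitude = 1)
  dip_win <- wl >= 450 & wl <= 600
  expect_lt(mean(abeta[dip_win]), mean(base[dip_win]))
  # brute-force oracle: per-band attenuation factor 1 - 0.3 (500/lambda)^4,
  # evaluated independently at every band
  oracle <- vapply(seq_along(wl),
                   function(b) base[b] * (1 - 0.3 * (500 / wl[b])^4),
                   numeric(1))
  expect_equal(abeta, oracle, tolerance = 1e-12)
  # relative deficit is proportional to lambda^-4
  deficit <- 1 - abeta / base
  expect_equal(deficit * wl^4, rep(0.3 * 500^4, length(wl)),
               tolerance = 1e-9)
})

test_that("unknown class is rejected by name", {
  expect_error(make_tissue_spectrum(wl, "gfap"), "gfap")
})

test_that("noiseless deposit pixels carry the exact planted spectrum", {
  spec <- phantom_spec(noise_sd = 0)
  gt <- render_phantom(spec)
  dep <- spec$deposit_list[[1]]  # a ptau deposit
  sel <- which(gt$label_mask == 3L, arr.ind = TRUE)
  # restrict to the first deposit's disk
  inside <- (sel[, 1] - dep$center[1])^2 + (sel[, 2] - dep$center[2])^2 <=
    dep$radius^2
  sel <- sel[inside, , drop = FALSE]
  planted <- make_tissue_spectrum(spec$wavelengths, "ptau", dep$amplitude)
  for (b in c(1L, 66L, 151L)) {
    vals <- gt$hypercube$data[, , b][sel]
    expected <- planted[b] * gt$illumination[sel] * gt$response[b]
    expect_equal(vals, expected, tolerance = 1e-12)
  }
})

test_that("deposit-free phantom has zero fluorescence signal", {
  spec <- phantom_spec(deposit_list = list(),
                       vessel_list = list(), noise_sd = 0)
  gt <- render_phantom(spec)
  expect_true(all(gt$fluor_image$data[, , 1:2] == 0))
})

test_that("rendering is bit-identical under a fixed seed", {
  spec <- phantom_spec(seed = 11L)
  a <- render_phantom(spec)
  b <- render_phantom(spec)
  expect_identical(a$hypercube$data, b$hypercube$data)
  expect_identical(a$dab_image$data, b$dab_image$data)
  expect_identical(a$fluor_image$data, b$fluor_image$data)
  expect_identical(a$label_mask, b$label_mask)
  spec2 <- phantom_spec(seed = 12L)
  expect_false(identical(render_phantom(spec2)$hypercube$data,
                         a$hypercube$data))
})

test_that("out-of-bounds deposits and vessels are rejected", {
  expect_error(phantom_spec(deposit_list = list(
    list(class = "ptau", center = c(2, 50), radius = 6, amplitude = 0.9))),
    "outside")
  expect_error(phantom_spec(vessel_list = list(
    list(center = c(1, 1), lumen_radius = 4, wall_thickness = 2,
         lumen_artifact = FALSE))), "outside")
})

test_that("class spectra stay separable above the noise floor", {
  gt <- fx_phantom02()
  spec <- gt$spec
  combos <- combn(c("tissue", "abeta", "ptau"), 2)
  for (k in seq_len(ncol(combos))) {
    s1 <- make_tissue_spectrum(spec$wavelengths, combos[1, k], 0.9)
    s2 <- make_tissue_spectrum(spec$wavelengths, combos[2, k], 0.9)
    expect_gt(max(abs(s1 - s2)), 5 * spec$noise_sd)
  }
})

test_that("mask and fluorescence channels are mutually consistent", {
  gt <- fx_phantom()
  red <- gt$fluor_image$data[, , 1]; green <- gt$fluor_image$data[, , 2]
  expect_true(all(red[gt$label_mask == 2L] == 0))    # abeta has no red
  expect_true(all(green[gt$label_mask == 3L] == 0))  # ptau has no green
  # lumen artifact appears in the fluorescence image only
  lum <- gt$label_mask == 4L
  expect_true(any(gt$fluor_image$data[, , 2][lum] > 0))
  expect_true(all(gt$fluor_clean$data[, , 1:2][rep(lum, 2)] == 0))
})

test_that("known-warp fixtures return exact analytic inverses", {
  gt <- fx_phantom()
  img <- gt$dab_image
  # identity
  w <- apply_known_warp(img, similarity_transform())
  expect_identical(w$warped$data, img$data)
  # pure translation inverts by sign
  w <- apply_known_warp(img, similarity_transform(0, 1, c(5, -3)))
  expect_equal(w$inverse$translation, c(-5, 3))
  # warp then inverse-warp round trip within interpolation tolerance
  tf <- similarity_transform(7, 1.1, c(0, 0))
  w <- apply_known_warp(img, tf)
  back <- apply_known_warp(w$warped, w$inverse)$warped
  interior <- 15:80  # avoid background fill near the frame
  expect_lt(mean(abs(back$data[interior, interior, ] -
                       img$data[interior, interior, ])), 2)
})

test_that("degenerate warp parameters are rejected", {
  expect_error(similarity_transform(scale = 0), "scale")
  gt <- fx_phantom()
  expect_error(apply_known_warp(gt$dab_image, similarity_transform(30)),
               "rotation")
  expect_error(apply_known_warp(gt$dab_image,
                                similarity_transform(0, 0.5)), "scale")
})

test_that("phantom specs survive a YAML round trip", {
  spec <- phantom_spec(seed = 5L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  spec2 <- read_phantom_spec(path)
  expect_equal(spec2$image_shape, spec$image_shape)
  expect_equal(spec2$deposit_list, spec$deposit_list)
  expect_identical(render_phantom(spec2)$hypercube$data,
                   render_phantom(spec)$hypercube$data)
})
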