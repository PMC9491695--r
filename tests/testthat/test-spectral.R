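test_that("a constant cube yields a flat unit spectrum", {
  wl <- seq(450, 700, by = 10)
  cube <- hypercube(array(7, c(6, 6, length(wl))), wl)
  s <- extract_region_spectrum(cube, cbind(1:3, 1:3),
                               unity_calibration(wl))
  expect_equal(s$calibrated_normalized, rep(1, length(wl)))
  expect_equal(s$pixel_count, 3L)
})

test_that("regions below 3 pixels or out of bounds are rejected", {
  wl <- seq(450, 700, by = 10)
  cube <- hypercube(array(1, c(6, 6, length(wl))), wl)
  expect_error(extract_region_spectrum(cube, cbind(1:2, 1:2)),
               "minimum of 3")
  expect_error(extract_region_spectrum(cube, cbind(c(1, 2, 9), c(1, 2, 3))),
               "out-of-bounds")
})

test_that("region spectra match a brute-force per-band double loop", {
  set.seed(5)
  wl <- seq(450, 700, by = 25)
  cube <- hypercube(array(runif(12 * 12 * length(wl), 0.2, 2),
                          c(12, 12, length(wl))), wl)
  region <- cbind(sample(1:12, 10, TRUE), sample(1:12, 10, TRUE))
  coefs <- runif(length(wl), 0.5, 2)
  tab <- calibration_table(wl, coefs)
  s <- extract_region_spectrum(cube, region, tab)
  oracle <- numeric(length(wl))
  for (b in seq_along(wl)) {
    tot <- 0
    for (i in seq_len(nrow(region)))
      tot <- tot + cube$data[region[i, 1], region[i, 2], b]
    oracle[b] <- (tot / nrow(region)) / coefs[b]
  }
  oracle <- oracle / max(oracle)
  expect_equal(s$calibrated_normalized, oracle, tolerance = 1e-12)
})

test_that("peak normalization is idempotent and scale invariant", {
  gt <- fx_phantom02()
  cube <- gt$hypercube
  region <- cbind(30:34, 50:54)
  s1 <- extract_region_spectrum(cube, region)
  scaled <- hypercube(cube$data * 3.7, cube$wavelengths)
  s2 <- extract_region_spectrum(scaled, region)
  expect_equal(s1$calibrated_normalized, s2$calibrated_normalized,
               tolerance = 1e-12)
  expect_equal(max(s1$calibrated_normalized), 1)
  renorm <- s1$calibrated_normalized / max(s1$calibrated_normalized)
  expect_identical(renorm, s1$calibrated_normalized)
})

test_that("pure class spectra are categorized correctly", {
  wl <- band_axis()
  for (amp in c(0.7, 0.9, 1)) {
    ptau <- make_tissue_spectrum(wl, "ptau", amp)
    res <- categorize_spectrum(ptau / max(ptau), wavelengths = wl)
    expect_equal(res$category, "ptau")
  }
  for (amp in c(0.7, 0.9, 1)) {
    abeta <- make_tissue_spectrum(wl, "abeta", amp)
    res <- categorize_spectrum(abeta / max(abeta), wavelengths = wl)
    expect_equal(res$category, "abeta")
  }
  tissue <- make_tissue_spectrum(wl, "tissue")
  expect_equal(categorize_spectrum(tissue / max(tissue),
                                   wavelengths = wl)$category, "control")
})

test_that("a perfectly flat spectrum has flatness exactly 1", {
  wl <- band_axis()
  res <- categorize_spectrum(rep(1, length(wl)), wavelengths = wl)
  expect_identical(res$scores[["flatness"]], 1)
})

test_that("categorization requires 450-700 nm coverage", {
  wl <- seq(500, 650, 10)
  expect_error(categorize_spectrum(rep(1, length(wl)), wavelengths = wl),
               "450-700")
})

test_that("strip scanning localizes planted deposits", {
  gt <- fx_phantom02()
  cal <- fx_calibrated_cube()
  res <- scan_strip(cal, stride = 5, window = 5)
  # at least one window on the large ptau deposit is categorized ptau
  dep <- gt$spec$deposit_list[[1]]
  on_dep <- res$row >= dep$center[1] - 4 & res$row <= dep$center[1] &
    res$col >= dep$center[2] - 4 & res$col <= dep$center[2]
  expect_true(any(res$category[on_dep] == "ptau"))
  # windows far from any deposit or vessel are control
  far <- res$row > 60 & res$row < 70 & res$col > 40 & res$col < 60
  expect_true(all(res$category[far] == "control"))
})

test_that("strip scanning over an empty phantom finds only control", {
  spec <- phantom_spec(image_shape = c(48, 48), deposit_list = list(),
                       vessel_list = list(), noise_sd = 0.01)
  gt <- render_phantom(spec)
  tab <- estimate_coefficients(render_blank(spec),
                               phantom_spectrometer(spec))
  cal <- apply_calibration(gt$hypercube, tab)
  res <- scan_strip(cal, stride = 8, window = 5)
  expect_true(all(res$category == "control"))
})

test_that("a stride larger than the image yields a single window", {
  wl <- band_axis(450, 700, 10)
  cube <- hypercube(array(runif(8 * 8 * length(wl), 0.5, 1),
                          c(8, 8, length(wl))), wl)
  res <- scan_strip(cube, stride = 100, window = 5)
  expect_equal(nrow(res), 1L)
})

test_that("windowed categorization recovers phantom classes", {
  # >= 95% agreement with the label-mask majority class at noise_sd 0.02
  gt <- fx_phantom02()
  cal <- fx_calibrated_cube()
  res <- scan_strip(cal, stride = 5, window = 5)
  class_map <- c("0" = "control", "1" = "control", "2" = "abeta",
                 "3" = "ptau", "4" = "control")
  truth <- mapply(function(r, cc) {
    m <- gt$label_mask[r:(r + 4), cc:(cc + 4)]
    class_map[[names(which.max(table(m)))]]
  }, res$row, res$col)
  expect_gte(mean(res$category == truth), 0.95)
})

test_that("spectra export to labelled CSV", {
  cube <- fx_phantom02()$hypercube
  s <- extract_region_spectrum(cube, cbind(30:34, 50:54), label = "control")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(list(s), path)
  df <- read.csv(path)
  expect_equal(nrow(df), length(cube$wavelengths))
  expect_true(all(df$label == "control"))
})
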