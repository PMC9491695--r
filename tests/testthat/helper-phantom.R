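# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# default-condition phantom (96 x 128, 151 bands, noise 0.01)
fx_phantom <- function() cached("phantom", render_phantom(phantom_spec()))

# low-noise phantom for recovery tests (noise_sd 0.02 study condition)
fx_phantom02 <- function() {
  cached("phantom02", render_phantom(phantom_spec(noise_sd = 0.02,
                                                  seed = 3L)))
}

fx_calibration <- function() {
  cached("calibration", {
    spec <- phantom_spec(noise_sd = 0.02, seed = 3L)
    estimate_coefficients(render_blank(spec), phantom_spectrometer(spec))
  })
}

fx_calibrated_cube <- function() {
  cached("calibrated_cube",
         apply_calibration(fx_phantom02()$hypercube, fx_calibration()))
}

# a handful of 64 x 64 DAB-pTau pairs for dataset/GAN plumbing tests
fx_pairs <- function() {
  cached("pairs", phantom_pairs(10L, patch = 64L, seed = 7L,
                                target = "dab_ptau"))
}

# small random 8-bit image
rand_img8 <- function(h, w, seed = 1L) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
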