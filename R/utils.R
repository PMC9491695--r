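# Shared validation helpers and small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  invisible(x)
}

#' Clamp values to an interval
#' @param x numeric vector or array
#' @param lo,hi interval bounds
#' @return `x` with values outside `[lo, hi]` replaced by the bounds
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic 32-bit FNV-1a hash of an R object's serialization; used for
# config/artifact fingerprints in run manifests. Not cryptographic.
fnv1a32 <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2L))
  # drop the serialization header (R version stamp) so equal objects hash
  # equally across R patch versions
  bytes <- bytes[-seq_len(14L)]
  h <- 2166136261
  for (b in bytes) {
    # xor with the low byte only (b < 256); h is tracked as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by 16777619, split to stay inside 2^53
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

# Derive a per-stage seed from a global seed by hashing the stage name.
# Result is kept in the 31-bit positive integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- strtoi(substr(fnv1a32(stage), 1, 7), base = 16L)
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647) + 1L
}

is_8bit <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 255) &&
    all(x == round(x))
}

# Per-band spatial standard deviation of a hypercube.
band_sds <- function(data) apply(data, 3L, sd)
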