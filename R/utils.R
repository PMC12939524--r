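# Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which does
# not reproduce fixed-composition cohort tallies (e.g. 42 of 274 at 15.3%).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_fraction <- function(x, name, allow_na = FALSE) {
  if (allow_na && all(is.na(x))) return(invisible(x))
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must be a fraction in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != trunc(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Derive independent sub-seeds from one user-facing seed so that each
# consumer (labels, biomarkers, missingness, raters, ...) has its own
# stream: adding raters must not perturb the cohort. Kept below 2^31.
derive_seed <- function(seed, stream) {
  seed <- as.integer(seed)
  h <- (as.double(seed) * 48271 + stream * 100003) %% 2147483629
  as.integer(h)
}

# Tiny FNV-1a string hash for provenance blocks (hex, not cryptographic).
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
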