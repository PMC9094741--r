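# Internal helpers: condition classes, seeded evaluation, truncated normals.

pwv_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("pwvagree_", class), "pwvagree_error"), ...)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# stream; seed = NULL means "use the ambient stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive a child seed from a parent seed and an integer offset. Kept strictly
# below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) + 97003 * as.numeric(offset)) %% 2147483647)
}

# Inverse-CDF truncated normal sampler; `mean` may be a vector. A zero sd
# collapses to the (clamped) mean, which lets degenerate presets run.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (all(sd <= 0)) {
    return(pmin(pmax(rep_len(mean, n), lower), upper))
  }
  p <- stats::runif(n,
    stats::pnorm(lower, mean, sd),
    stats::pnorm(upper, mean, sd)
  )
  stats::qnorm(p, mean, sd)
}

# Centered moving average; edges fall back to the raw signal so the output
# has no NA values and linear segments are preserved exactly.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < width) {
    return(x)
  }
  sm <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  edge <- is.na(sm)
  sm[edge] <- x[edge]
  sm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
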