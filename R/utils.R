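# Internal helpers: argument checks, seeded evaluation, small numerics.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("resim_input_error", "error")))
}

check_scalar <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(name, " must be a finite numeric scalar")
  if (integer && x != round(x))
    stop_input(name, " must be an integer")
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max)
    stop_input(name, " out of range [", min, ", ", max, "]: ", x)
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing generators funnel randomness through this so
# every result is a pure function of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) check_scalar(seed, "seed", integer = TRUE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  if (!is.null(seed)) set.seed(seed)
  expr
}

# Polynomial string hash over the 31-bit prime field (Horner scheme; all
# intermediates stay below 2^53 so double arithmetic is exact).
str_hash31 <- function(x) {
  h <- 17
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  h
}

# Derive a child seed from a parent seed and a stage label, keeping the
# result inside the 32-bit signed integer range.
derive_seed <- function(seed, label) {
  as.integer(str_hash31(paste0(label, ":", seed)) %% 2147483646 + 1)
}

# Hash of a character scalar, reported as hex; used to stamp artifacts
# with a configuration fingerprint (no external digest dep).
fnv1a_hex <- function(x) {
  sprintf("%08x", str_hash31(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unit conversions (SI internally, clinical units at interfaces)
ML_MIN_TO_M3_S <- 1e-6 / 60
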