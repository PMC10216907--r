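# Internal helpers: seeded RNG scoping and deterministic seed derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

# Fold integers into one sub-seed < 2^31 - 1 (Lehmer-style hash; all
# intermediates stay below 2^53 so double arithmetic is exact).
derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (v in c(...)) {
    h <- (h * 48271 + as.double(v) + 1) %% 2147483647
  }
  as.integer(h)
}

# Round half away from zero to `digits` decimals (not banker's rounding).
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
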