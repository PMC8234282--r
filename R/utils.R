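# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package
# route through this so no call mutates global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round to nearest integer, then coerce; used wherever a vital is reported.
round_int <- function(x) as.integer(round(x))

# Nearest multiple of `m`, ties away from zero (72 -> 70, 73 -> 75, 67.5 -> 70).
round_to_multiple <- function(x, m = 5L) {
  s <- sign(x)
  as.integer(s * floor(abs(x) / m + 0.5) * m)
}

# Derive a distinct sub-seed from a base seed, kept inside 32-bit range.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435.0 + k * 97.0) %% 2147483647)
}

# Deterministic 31-bit polynomial hash of a character scalar; used to stamp
# artifacts with a config fingerprint without external dependencies.
str_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

config_hash <- function(config) {
  str_hash(paste(deparse(config[order(names(config))]), collapse = ""))
}

msg <- function(...) {
  if (isTRUE(getOption("activital.verbose", TRUE))) message(...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
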