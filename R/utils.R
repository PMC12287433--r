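# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never clobber the global stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit integer seed derived from a base seed and a set of
# string/numeric keys (well id, day, position, stage name ...). Simple
# multiplicative string hash; stays well below 2^31.
derive_seed <- function(base_seed, ...) {
  keys <- paste(c(base_seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(keys)) {
    h <- (h * 31 + ch) %% 2147483587
  }
  as.integer((h + as.numeric(base_seed)) %% 2147483587 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

check_count <- function(x, name) {
  if (!is_count(x)) stopf("`%s` must be a single positive integer, got %s",
                          name, paste(format(x), collapse = ", "))
  invisible(as.integer(x))
}
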