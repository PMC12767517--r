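#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps seeded helpers free of RNG side effects.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Deterministic 31-bit polynomial string hash (exact in double arithmetic).
hash_string <- function(s) {
  x <- utf8ToInt(s)
  h <- 0
  for (ch in x) h <- (h * 131 + ch) %% 2147483629
  h
}

# Derive a stream of child seeds from a master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
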