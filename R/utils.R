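# Internal helpers shared across modules.

# Deterministic lexicographic sort (C locale, radix method) so node
# orderings never depend on the session locale.
lex_sort <- function(x) sort(x, method = "radix")

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All stochastic entry points funnel through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed, staying inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000003 + k) %% 2147483647L)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) warn(sprintf(fmt, ...))

`%||%` <- function(x, y) if (is.null(x)) y else x
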