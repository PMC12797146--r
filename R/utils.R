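# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All stochastic entry points funnel through this so
# a call is reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_matrix <- function(x, name, ncol = NULL, nrow = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("`%s` must be a numeric matrix", name)
  }
  if (!is.null(ncol) && ncol(x) != ncol) {
    stopf("`%s` must have %d columns, got %d", name, ncol, ncol(x))
  }
  if (!is.null(nrow) && nrow(x) != nrow) {
    stopf("`%s` must have %d rows, got %d", name, nrow, nrow(x))
  }
  invisible(x)
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) stopf("`%s` contains non-finite values", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
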