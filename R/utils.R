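# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded package functions never disturb user-level randomness.
with_seed <- function(seed, code) {
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
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stopf("'%s' must be a numeric matrix", name)
  }
  if (any(!is.finite(x))) stopf("'%s' contains non-finite entries", name)
  x
}

frob2 <- function(m) sum(m * m)

# Smoothed change of an objective trace at iteration r: absolute difference
# between the moving averages ending at r and at r-1 (window 10). Raw
# consecutive differences are dominated by single-sample noise in
# stochastic training and would halt optimization prematurely.
smoothed_delta <- function(trace, r, window = 10L) {
  abs(mean(trace[max(1L, r - window + 1L):r]) -
        mean(trace[max(1L, r - window):(r - 1L)]))
}
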