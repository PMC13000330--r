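#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats dnorm pnorm rnorm runif cor optim setNames
NULL

# clamp to [lo, hi]; predictions and simulated ratings live on the bounded slider
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# one child seed per named stage, derived from a single top-level seed so every
# stochastic stage has its own reproducible stream (kept < 2^31)
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1299709) %% 2147483647)
}

assert_scalar_in <- function(x, lo, hi, name, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    abort(sprintf(
      "`%s` = %g is outside %s%g, %g%s.", name, x,
      if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]"
    ))
  }
  invisible(x)
}
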