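# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the base Mersenne-Twister generator to `seed`, evaluates `expr`, and
#' restores the caller's RNG state on exit, so library code never perturbs
#' the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(abs(seed) %% 2147483647), kind = "Mersenne-Twister")
  }
  force(expr)
}

# Derive k reproducible child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stop_poresift <- function(fmt, ..., class = "poresift_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_poresift("'%s' must be a single number in [%s, %s]", name, lo, hi)
  }
  invisible(x)
}

# Percentage formatted consistently in reports (2 decimals).
round_pct <- function(x) round(x, 2)
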