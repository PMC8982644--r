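`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generator functions are reproducible without clobbering
#' the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# raw (unscaled) median absolute deviation; the burst recursion uses
# constant = 1, not R's default 1.4826
raw_mad <- function(x) stats::median(abs(x - stats::median(x)))

# closed-form simple-regression slope (and intercept); much faster than lm()
# in per-event loops
fast_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(c(slope = NA_real_, intercept = NA_real_))
  b <- sum((x - mx) * (y - my)) / sxx
  c(slope = b, intercept = my - b * mx)
}

stop_if_not_prob <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  invisible(p)
}
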