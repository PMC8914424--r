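# Internal helpers shared across modules.

#' Round a monetary amount half-up to cents
#'
#' All internal arithmetic keeps full double precision; rounding to two
#' decimals happens only when a figure is presented or written to a report.
#' Half-up (not banker's) rounding so that printed cents match conventional
#' fee-schedule arithmetic.
#'
#' @param x Numeric vector of monetary amounts.
#' @return `x` rounded half-up to 2 decimal places.
#' @export
#' @examples
#' round_money(9497.025)
round_money <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) * 100 + 0.5) / 100
}

# Validate a single probability (or error with the argument's name).
check_prob <- function(p, what = "p") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", what))
  }
  invisible(p)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state;
# seed = NULL uses the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}
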