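# Base-case cost-minimization: expected 30-day cost per strategy, savings,
# preferred strategy.

# Monetary resolution below which two strategies are considered tied.
TIE_TOLERANCE <- 0.01

#' Build a two-strategy cost-minimization decision model
#'
#' The model compares exactly two salvage drainage strategies over a single
#' 30-day decision episode: each strategy always incurs its bundled initial
#' cost and, with its re-intervention probability, one bundled
#' re-intervention cost. Technical failures and minor adverse events are
#' folded into the re-intervention rate (no separate branches), and no
#' deaths or serious adverse events are modelled over the horizon.
#'
#' @param strategies A list of two strategy inputs as returned by
#'   [build_strategy_inputs()]: each element a list with `profile`
#'   ([strategy_profile()]) and `evidence` ([reintervention_evidence()]).
#' @param horizon_days Time horizon in days (default 30).
#' @param discount_rate Must be 0: with a single decision episode inside a
#'   30-day horizon there is nothing to discount.
#' @return A `decision_model` object.
#' @export
#' @examples
#' model <- us_medicare_model()
#' run_base_case(model)
decision_model <- function(strategies, horizon_days = 30, discount_rate = 0) {
  if (!is.list(strategies) || length(strategies) != 2L) {
    abort("`strategies` must be a list of exactly two strategy inputs.")
  }
  for (s in strategies) {
    if (!is.list(s) || !inherits(s$profile, "strategy_profile") ||
        !inherits(s$evidence, "reintervention_evidence")) {
      abort("each strategy input needs a `profile` and an `evidence` element.")
    }
  }
  names_ <- purrr::map_chr(strategies, ~ .x$profile$strategy)
  if (anyDuplicated(names_)) {
    abort("the two strategies must have distinct names.")
  }
  if (!is.numeric(horizon_days) || length(horizon_days) != 1L || horizon_days < 1) {
    abort("`horizon_days` must be a positive number of days.")
  }
  if (!identical(as.numeric(discount_rate), 0)) {
    abort("`discount_rate` must be 0: the model is a single decision episode.")
  }
  structure(
    list(strategies = setNames(strategies, names_),
         horizon_days = horizon_days, discount_rate = 0),
    class = "decision_model"
  )
}

#' The default US Medicare decision model
#'
#' Packaged Medicare fee schedule with re-intervention counts 8/34 (EUS-BD)
#' and 17/32 (PTBD). The full-precision point estimates (23.53% and 53.13%),
#' not the rounded display percentages, drive the base case.
#'
#' @inheritParams build_strategy_inputs
#' @return A [decision_model()].
#' @export
us_medicare_model <- function(eus_evidence = reintervention_evidence(8, 34),
                              ptbd_evidence = reintervention_evidence(17, 32)) {
  decision_model(build_strategy_inputs(us_medicare_schedule(),
                                       eus_evidence, ptbd_evidence))
}

#' @export
print.decision_model <- function(x, ...) {
  cat(sprintf("Cost-minimization decision model (%d-day horizon)\n",
              x$horizon_days))
  for (s in x$strategies) {
    cat(sprintf("  %-8s initial $%10.2f  re-intervention $%9.2f  p = %d/%d\n",
                s$profile$strategy, s$profile$initial_cost,
                s$profile$reintervention_cost,
                s$evidence$events, s$evidence$trials))
  }
  invisible(x)
}

#' Expected strategy cost at a re-intervention probability
#'
#' The per-strategy expected cost is affine in the re-intervention
#' probability: `E[C] = C_init + p * C_reint`.
#'
#' @param profile A [strategy_profile()].
#' @param p Re-intervention probability in \[0, 1\] (may be a vector).
#' @return Expected cost(s), full precision (no rounding).
#' @export
#' @examples
#' eus <- strategy_profile("EUS-BD", 8002.48, 6351.83)
#' round_money(expected_cost(eus, 8 / 34)) # 9497.03
expected_cost <- function(profile, p) {
  stopifnot(inherits(profile, "strategy_profile"))
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be probabilities in [0, 1].")
  }
  profile$initial_cost + p * profile$reintervention_cost
}

#' Evaluate the base case
#'
#' Computes each strategy's expected cost at its full-precision point
#' estimate, the savings of the first strategy relative to the second, and
#' the preferred (strictly cheaper) strategy. Costs within one cent of each
#' other are reported as a tie.
#'
#' @param model A [decision_model()].
#' @return A `base_case_result` with elements `costs` (tibble: strategy, p,
#'   expected_cost), `savings` (second minus first strategy cost), `preferred`
#'   (strategy name, or `NA` on a tie) and `tie`.
#' @export
run_base_case <- function(model) {
  stopifnot(inherits(model, "decision_model"))
  costs <- purrr::map_dfr(model$strategies, function(s) {
    tibble::tibble(
      strategy = s$profile$strategy,
      p = s$evidence$point_estimate,
      expected_cost = expected_cost(s$profile, s$evidence$point_estimate)
    )
  })
  savings <- costs$expected_cost[2] - costs$expected_cost[1]
  tie <- abs(savings) < TIE_TOLERANCE
  preferred <- if (tie) NA_character_ else costs$strategy[which.min(costs$expected_cost)]
  structure(
    list(costs = costs, savings = savings, preferred = preferred, tie = tie,
         model = model),
    class = "base_case_result"
  )
}

#' @export
print.base_case_result <- function(x, ...) {
  cat(sprintf("Base-case expected %d-day costs:\n", x$model$horizon_days))
  for (i in seq_len(nrow(x$costs))) {
    cat(sprintf("  %-8s $%s (p = %.4f)\n", x$costs$strategy[i],
                format(round_money(x$costs$expected_cost[i]), big.mark = ",", nsmall = 2),
                x$costs$p[i]))
  }
  if (x$tie) {
    cat("  Strategies tie to within one cent.\n")
  } else {
    # presented as the difference of the rounded costs, the way a fee
    # schedule is read
    shown <- abs(diff(round_money(x$costs$expected_cost)))
    cat(sprintf("  Preferred: %s (savings $%s)\n", x$preferred,
                format(round_money(shown), big.mark = ",", nsmall = 2)))
  }
  invisible(x)
}

#' @method tidy base_case_result
#' @export
tidy.base_case_result <- function(x, ...) {
  x$costs
}

#' @method glance base_case_result
#' @export
glance.base_case_result <- function(x, ...) {
  tibble::tibble(
    savings = x$savings,
    preferred = x$preferred,
    tie = x$tie,
    horizon_days = x$model$horizon_days
  )
}

#' Cost savings relative to a reference strategy
#'
#' Antisymmetric by construction: savings with respect to one strategy are
#' minus the savings with respect to the other.
#'
#' @param result A [run_base_case()] result.
#' @param reference Name of the strategy whose savings to report (positive
#'   when this strategy is cheaper).
#' @return A single number, full precision.
#' @export
#' @examples
#' res <- run_base_case(us_medicare_model())
#' round_money(cost_savings(res, "EUS-BD")) # 4381.41
cost_savings <- function(result, reference) {
  stopifnot(inherits(result, "base_case_result"))
  idx <- match(reference, result$costs$strategy)
  if (is.na(idx)) {
    abort(sprintf("unknown strategy '%s'; model has: %s", reference,
                  paste(result$costs$strategy, collapse = ", ")))
  }
  other <- setdiff(seq_len(2), idx)
  result$costs$expected_cost[other] - result$costs$expected_cost[idx]
}
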