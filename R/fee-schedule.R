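# Monetary model inputs: fee schedules, currency conversion, strategy profiles
# and the binomial re-intervention evidence behind each strategy.

FEE_CATEGORIES <- c(
  "primary-intervention", "secondary-intervention", "hospital-day",
  "bundled-strategy-initial", "bundled-strategy-reintervention"
)

#' Construct a validated fee schedule
#'
#' A fee schedule is a tibble of cost items (one per procedure or bundled
#' strategy episode) together with a currency tag and a multiplicative
#' conversion factor into US dollars. Amounts are stored at full precision;
#' rounding to cents happens only at presentation.
#'
#' @param items A data frame with columns `label`, `category`, `amount` and
#'   `country`. Labels must be non-empty and unique; amounts non-negative;
#'   categories one of `r paste(FEE_CATEGORIES, collapse = ", ")`.
#' @param currency ISO currency code of the amounts as entered.
#' @param conversion_factor Positive multiplier taking `currency` into USD
#'   (1 when amounts are already in USD).
#' @return A `fee_schedule` object: the validated items tibble with currency
#'   metadata attached.
#' @seealso [read_fee_schedule()], [fee_amount()], [convert_currency()]
#' @export
fee_schedule <- function(items, currency = "USD", conversion_factor = 1) {
  items <- tibble::as_tibble(items)
  required <- c("label", "category", "amount", "country")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    abort(sprintf("fee schedule is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(conversion_factor) || length(conversion_factor) != 1L ||
      is.na(conversion_factor) || conversion_factor <= 0) {
    abort("`conversion_factor` must be a single positive number.")
  }
  if (nrow(items) > 0) {
    bad <- which(is.na(items$label) | !nzchar(trimws(items$label)))
    if (length(bad) > 0) {
      abort(sprintf("fee schedule row %d has an empty label.", bad[1]))
    }
    dup <- items$label[duplicated(items$label)]
    if (length(dup) > 0) {
      abort(sprintf("duplicate fee schedule label: '%s'", dup[1]))
    }
    bad <- which(!items$category %in% FEE_CATEGORIES)
    if (length(bad) > 0) {
      abort(sprintf("row %d ('%s'): unknown category '%s'",
                    bad[1], items$label[bad[1]], items$category[bad[1]]))
    }
    bad <- which(!is.finite(items$amount) | items$amount < 0)
    if (length(bad) > 0) {
      abort(sprintf("row %d ('%s'): amount must be a non-negative number, got %s",
                    bad[1], items$label[bad[1]], format(items$amount[bad[1]])))
    }
  }
  structure(
    items[required],
    currency = currency,
    conversion_factor = conversion_factor,
    class = c("fee_schedule", class(items))
  )
}

#' Read a fee schedule from CSV
#'
#' Expects columns `label,category,amount,country` (UTF-8, decimal point, no
#' thousands separators). Two schedules ship with the package, carrying the
#' bundled Medicare strategy costs and the Korean per-procedure fees:
#' `system.file("extdata", "fee_schedule_us.csv", package = "biledrain")` and
#' `.../fee_schedule_korea.csv`.
#'
#' @param path Path to the CSV file.
#' @inheritParams fee_schedule
#' @return A [fee_schedule()].
#' @export
#' @examples
#' us <- read_fee_schedule(
#'   system.file("extdata", "fee_schedule_us.csv", package = "biledrain")
#' )
#' fee_amount(us, "EUS-BD")
read_fee_schedule <- function(path, currency = "USD", conversion_factor = 1) {
  if (!file.exists(path)) {
    abort(sprintf("fee schedule file not found: %s", path))
  }
  items <- readr::read_csv(
    path,
    col_types = readr::cols(
      label = readr::col_character(),
      category = readr::col_character(),
      amount = readr::col_double(),
      country = readr::col_character()
    )
  )
  fee_schedule(items, currency = currency, conversion_factor = conversion_factor)
}

#' Look up an amount in a fee schedule
#'
#' Lookup is total over the declared items: an unknown label is an error,
#' never a silent zero.
#'
#' @param schedule A [fee_schedule()].
#' @param label Item label, matched exactly.
#' @param usd If `TRUE` (default) apply the schedule's conversion factor.
#' @return The amount as a single number, at full precision.
#' @export
fee_amount <- function(schedule, label, usd = TRUE) {
  stopifnot(inherits(schedule, "fee_schedule"))
  idx <- match(label, schedule$label)
  if (is.na(idx)) {
    abort(sprintf("label '%s' not found in fee schedule.", label))
  }
  amount <- schedule$amount[idx]
  if (usd) amount <- convert_currency(amount, attr(schedule, "conversion_factor"))
  amount
}

#' Convert an amount between currencies by a fixed factor
#'
#' @param amount Numeric amount(s) in the source currency.
#' @param factor Positive conversion factor (source currency to target).
#' @return `amount * factor`, unrounded; round with [round_money()] at
#'   presentation.
#' @export
#' @examples
#' convert_currency(1e6, 0.00091) # KRW to USD
convert_currency <- function(amount, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) || factor <= 0) {
    abort("`factor` must be a single positive number.")
  }
  stopifnot(is.numeric(amount))
  amount * factor
}

#' Re-intervention evidence as binomial counts
#'
#' The model stores re-intervention rates as the underlying trial counts
#' (events `k` out of `n`), never as rounded percentages: the full-precision
#' point estimate `k/n` is what reproduces the published base case, and the
#' counts are what parameterize the beta distribution in probabilistic
#' sensitivity analysis.
#'
#' @param events Number of patients needing unscheduled re-intervention (`k`).
#' @param trials Number of evaluable patients (`n`).
#' @return A `reintervention_evidence` object with fields `events`, `trials`
#'   and `point_estimate = events/trials`.
#' @export
#' @examples
#' reintervention_evidence(8, 34)$point_estimate # 0.2353, not the rounded 23.6%
reintervention_evidence <- function(events, trials) {
  if (!is.numeric(trials) || length(trials) != 1L || is.na(trials) ||
      trials < 1 || trials != round(trials)) {
    abort("`trials` must be a single positive integer.")
  }
  if (!is.numeric(events) || length(events) != 1L || is.na(events) ||
      events < 0 || events > trials || events != round(events)) {
    abort("`events` must be a single integer in [0, trials].")
  }
  structure(
    list(events = as.integer(events), trials = as.integer(trials),
         point_estimate = events / trials),
    class = "reintervention_evidence"
  )
}

#' @export
print.reintervention_evidence <- function(x, ...) {
  cat(sprintf("Re-intervention evidence: %d/%d events (%.1f%%)\n",
              x$events, x$trials, 100 * x$point_estimate))
  invisible(x)
}

#' A strategy's cost profile
#'
#' Each drainage strategy is costed as a bundled initial episode (always
#' incurred) plus a bundled re-intervention episode (incurred with the
#' strategy's re-intervention probability).
#'
#' @param strategy Strategy name, e.g. `"EUS-BD"` or `"PTBD"`.
#' @param initial_cost Cost of the initial episode (USD, >= 0).
#' @param reintervention_cost Cost of the re-intervention bundle (USD, >= 0).
#' @return A `strategy_profile` object.
#' @export
strategy_profile <- function(strategy, initial_cost, reintervention_cost) {
  if (!is.character(strategy) || length(strategy) != 1L || !nzchar(strategy)) {
    abort("`strategy` must be a non-empty name.")
  }
  for (arg in c("initial_cost", "reintervention_cost")) {
    v <- get(arg)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("`%s` must be a single non-negative number.", arg))
    }
  }
  structure(
    list(strategy = strategy, initial_cost = as.numeric(initial_cost),
         reintervention_cost = as.numeric(reintervention_cost)),
    class = "strategy_profile"
  )
}

#' @export
print.strategy_profile <- function(x, ...) {
  cat(sprintf("%s: initial $%s, re-intervention $%s\n", x$strategy,
              format(round_money(x$initial_cost), big.mark = ","),
              format(round_money(x$reintervention_cost), big.mark = ",")))
  invisible(x)
}

#' Assemble the two strategy inputs from a fee schedule
#'
#' Pulls each strategy's bundled initial and re-intervention amounts out of a
#' schedule and pairs them with the binomial re-intervention evidence. The
#' default labels match the packaged US Medicare schedule.
#'
#' @param schedule A [fee_schedule()] containing the four bundled-strategy
#'   labels.
#' @param eus_evidence,ptbd_evidence [reintervention_evidence()] for each
#'   strategy.
#' @param labels Named character vector mapping
#'   `eus_initial`, `eus_reintervention`, `ptbd_initial`,
#'   `ptbd_reintervention` to schedule labels.
#' @return A list of two strategy inputs, each a list with elements `profile`
#'   ([strategy_profile()]) and `evidence`.
#' @export
build_strategy_inputs <- function(schedule,
                                  eus_evidence = reintervention_evidence(8, 34),
                                  ptbd_evidence = reintervention_evidence(17, 32),
                                  labels = c(
                                    eus_initial = "EUS-BD",
                                    eus_reintervention = "Re-intervention with PTBD after failed EUS-BD",
                                    ptbd_initial = "PTBD",
                                    ptbd_reintervention = "Re-intervention after failed PTBD"
                                  )) {
  stopifnot(inherits(eus_evidence, "reintervention_evidence"),
            inherits(ptbd_evidence, "reintervention_evidence"))
  needed <- c("eus_initial", "eus_reintervention", "ptbd_initial",
              "ptbd_reintervention")
  if (!all(needed %in% names(labels))) {
    abort("`labels` must name eus_initial, eus_reintervention, ptbd_initial, ptbd_reintervention.")
  }
  list(
    eus = list(
      profile = strategy_profile("EUS-BD",
                                 fee_amount(schedule, labels[["eus_initial"]]),
                                 fee_amount(schedule, labels[["eus_reintervention"]])),
      evidence = eus_evidence
    ),
    ptbd = list(
      profile = strategy_profile("PTBD",
                                 fee_amount(schedule, labels[["ptbd_initial"]]),
                                 fee_amount(schedule, labels[["ptbd_reintervention"]])),
      evidence = ptbd_evidence
    )
  )
}

#' The packaged US Medicare fee schedule
#'
#' Convenience loader for the bundled strategy costs shipped with the package
#' (EUS-BD $8,002.48 initial / $6,351.83 re-intervention; PTBD $13,369.98 /
#' $957.11, 2021 Medicare reimbursement).
#'
#' @return A [fee_schedule()].
#' @export
us_medicare_schedule <- function() {
  read_fee_schedule(
    system.file("extdata", "fee_schedule_us.csv", package = "biledrain")
  )
}

#' The packaged Korean fee schedule
#'
#' Per-procedure Korean National Health Insurance fees (2014, converted to
#' USD). Note the schedule carries both the EUS-BD charge (1028.27) and the
#' per-patient single-session EUS-BD cost (1029.15) as published; the two are
#' not reconciled here.
#'
#' @return A [fee_schedule()].
#' @export
korea_fee_schedule <- function() {
  read_fee_schedule(
    system.file("extdata", "fee_schedule_korea.csv", package = "biledrain")
  )
}
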