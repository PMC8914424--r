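---
title: "Methods: cost-minimization of biliary drainage strategies after failed ERCP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-minimization of biliary drainage strategies after failed ERCP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biledrain)
```

## The clinical and economic problem

When ERCP fails to drain a malignant distal biliary obstruction, two salvage
strategies compete: endoscopic ultrasound-guided biliary drainage (EUS-BD),
performed in the same session, and percutaneous transhepatic biliary drainage
(PTBD), performed radiologically and typically requiring two or three
sessions (catheter placement, stent internalization, catheter removal).
Trial evidence shows similar technical and clinical success for the two
approaches, which is precisely the setting where a *cost-minimization*
analysis — rather than a cost-effectiveness analysis — is the appropriate
economic comparison: with equal effectiveness, the cheaper strategy wins.

`biledrain` implements that comparison twice over, reflecting two very
different payment systems:

* a **decision-analytic model of a US Medicare payer**, built from bundled
  2021 reimbursement amounts, with probabilistic and deterministic
  sensitivity analysis; and
* a **per-patient trial-level cost comparison** in the style of the Korean
  fee-for-service analysis (median/range summaries, Mann-Whitney tests,
  bias-corrected bootstrap confidence intervals), driven by a synthetic
  patient-level data generator because the underlying trial records are not
  publicly deposited.

## The decision model

Each strategy is costed over a 30-day horizon as a single decision episode:

$$E[C_s] = C_{\mathrm{init},s} + p_s \, C_{\mathrm{reint},s},$$

where $C_{\mathrm{init},s}$ is the bundled cost of the initial episode
(always incurred), $C_{\mathrm{reint},s}$ the bundled cost of one
unscheduled re-intervention, and $p_s$ the strategy's re-intervention
probability. Technical failures and minor adverse events are folded into
$p_s$ (no separate branches), and deaths or serious adverse events are not
modelled within the horizon. Although the source analysis was built in
Markov-model software, a 30-day horizon with one uncertain event and no
discounting collapses exactly to this closed form, and the closed form
reproduces every published figure; the package therefore implements the
collapsed model, and the constructor rejects nonzero discount rates as
inapplicable to a single episode.

The default inputs are the packaged Medicare fee schedule
(EUS-BD \$8,002.48 initial / \$6,351.83 re-intervention; PTBD \$13,369.98 /
\$957.11) and re-intervention evidence stored as binomial counts, not
percentages: $8/34$ for EUS-BD and $17/32$ for PTBD. The distinction
matters. The published table displays 23.6% and 53.1%, and the trial text
reports 25% (8/32); only the full-precision $8/34 = 23.53\%$ reproduces the
published EUS-BD expected cost of \$9,497.03, and $17/32 = 53.125\%$ rounds
to the displayed 53.1%. The package treats the printed percentages as
display values, keeps counts as the canonical input, and leaves both counts
user-configurable. Similarly, the Korean schedule carries both the EUS-BD
charge (1,028.27) and the per-patient single-session cost (1,029.15) as
printed, without reconciling them.

Money is carried as full-precision doubles throughout; rounding (half-up, to
cents) happens only at presentation. Two expected costs within one cent are
reported as a tie, since cost-minimization carries no preference information
at equality.

## Probabilistic sensitivity analysis

Uncertainty in the two re-intervention probabilities is propagated by Monte
Carlo: each trial draws $p_s$ independently per strategy from a beta
distribution and maps it through the affine cost form; 10,000 trials is the
default. Costs themselves are treated as fixed reimbursements (no
distributions on fees), so the probabilities are the model's only random
inputs.

Choices that the published analysis left unstated, and how this package
resolves them:

* **Beta parameterization.** The default `counts` rule uses
  $\mathrm{Beta}(k, n-k)$, whose mean $k/n$ equals the base-case point
  estimate, keeping the PSA mean consistent with the base case. A check
  during development: the 2.5% and 97.5% quantiles of
  $\mathrm{Beta}(8, 26)$ and $\mathrm{Beta}(17, 15)$, mapped through the
  affine cost forms, land on the published intervals
  (\$8,697.70–\$10,492.23 and \$13,712.44–\$14,040.07), which supports this
  reading. The rule fails for boundary counts ($k = 0$ or $k = n$), where
  the `jeffreys` option ($\alpha = k + \tfrac12$, $\beta = n - k +
  \tfrac12$) is available.
* **Interval type.** Percentile intervals (not normal-theory), matching the
  asymmetry of the published EUS-BD interval. Quantiles use linear
  interpolation (`stats::quantile()` type 7). Strategy-cost interval
  endpoints are computed as the affine map of the $p$-sample percentiles —
  numerically identical to percentiles of the cost samples (the transform
  is monotone affine) and exactly consistent with the closed cost form,
  which the test suite asserts bit-for-bit.
* **Correlation.** The two strategies' probabilities are drawn
  independently; nothing in the source suggests a joint distribution.
* **Reproducibility.** A single explicit seed controls the whole PSA;
  identical seed, identical result.

The probability that EUS-BD is cost-saving is the fraction of trials with
positive savings. Under the default inputs EUS-BD can only lose if its
probability exceeds $(13{,}369.98 - 8{,}002.48)/6{,}351.83 \approx 0.845$
while PTBD sits at 0 — a region carrying negligible
$\mathrm{Beta}(8, 26)$ mass — so this probability is 1.0 to Monte-Carlo
precision.

## Deterministic sensitivity analysis

The two-way analysis evaluates the closed cost form at every node of a grid
over $(p_{\mathrm{EUS}}, p_{\mathrm{PTBD}})$, recording savings and the
preferred strategy; the default grid is $[0, 0.5]^2$ in steps of 0.01,
matching the published evaluation range, with the full unit square
available. The one-way analyses are the two axis-aligned slices through the
base case. Because both cost forms are affine, the preference boundary is
the line

$$p_{\mathrm{EUS}}^* =
  \frac{C_{\mathrm{init},P} - C_{\mathrm{init},E} +
        p_{\mathrm{PTBD}}\, C_{\mathrm{reint},P}}{C_{\mathrm{reint},E}},$$

so conclusions drawn on the grid are step-independent; the package also
exposes the closed-form crossing (`equal_cost_threshold()`) and the largest
square $[0, b]^2$ on which EUS-BD is strictly preferred
(`favored_region_bound()`, $b \approx 0.845$ for the default inputs — the
binding corner is EUS-BD at $b$ against PTBD at 0). Strict preference
requires savings above one cent; smaller margins are ties.

## Trial-level cost comparison

The Korean analysis unit is one patient: hospital charges other than biliary
drainage, primary drainage cost, unscheduled re-intervention cost (zero if
none), a re-intervention count, a session count, and a flag marking whether
the patient is in the re-intervention denominator (index technical
success). Derived totals are `total_bd_cost = primary + re-intervention`
and `total_cost = hospital + total_bd_cost`; totals are summed per patient
before any summarizing, so arm medians of totals need not equal sums of
medians.

Statistical choices:

* **Mann-Whitney tests** (two-sided) compare arms per category, delegating
  to `stats::wilcox.test()`: exact enumeration when there are no ties and
  the smaller arm has at most 8 patients, otherwise the normal approximation
  with tie-corrected variance and continuity correction. The result records
  which path was taken, and the exact path is validated against a
  from-scratch enumeration oracle over all sample-size splits with
  $n_a + n_b \le 10$.
* **Bootstrap statistic.** The published bootstrap table's point differences
  (e.g. $-1{,}488.35$ for total cost) are inconsistent with differences of
  the published medians ($-1{,}216.34$), so the defensible reading is a
  difference of arm *means*; that is the default, with `statistic =
  "median"` exposed as an option. The accompanying phrase "automated
  stepwise variable selection" names no covariates or selection rule and is
  not implemented as a regression; the deliverable — a bias-corrected
  bootstrap CI of the between-arm cost difference — is.
* **Bias-corrected (BC) percentile bootstrap**, 1,000 stratified
  (within-arm, size-preserving) resamples by default. The correction is
  $z_0 = \Phi^{-1}(\text{fraction of bootstrap statistics below the
  observed value})$, with resamples landing exactly on the observed value
  counted half (so a symmetric bootstrap distribution yields $z_0 = 0$ and
  the interval reduces to the plain percentile interval), and the fraction
  clamped away from 0 and 1 so $z_0$ stays finite. Endpoints are order
  statistics of the bootstrap sample — the $\lceil B\,
  \Phi(2z_0 \pm z_{0.975})\rceil$-th sorted values — never extrapolated.
  BCa (jackknife acceleration) is available as an option; the published
  wording says only "bias-corrected", so BC is the default. Degenerate
  resampling distributions collapse the interval and are flagged. No
  multiple-testing adjustment is applied, matching the per-category
  reporting convention with two-sided $\alpha = 0.05$.

Because the patient-level records are not deposited, the published Korean
tables are **calibration targets and report layouts, not reproduction
targets**; the test suite validates this module with property-based checks
(enumeration oracles, null type-I error simulation, bootstrap coverage of a
known truth) instead of table comparisons.

## The synthetic trial generator

`simulate_trial()` provides patient-level data with the statistical
structure the Korean analysis assumes, so the trial-level pipeline is fully
testable. Per patient: a Bernoulli re-intervention indicator (eligible
patients only), a zero-truncated Poisson count given an event, per-event
unit costs, and hospital/primary costs from configured distributions. The
defaults are fixed to the published trial structure and are not tuning
knobs:

* arm sizes 34 (EUS-BD) and 32 (PTBD) enrolled, with re-intervention
  denominators 32 and 31 (index technical successes), configurable
  separately;
* re-intervention probabilities $8/32 = 25\%$ and $17/31 = 54.8\%$; the
  zero-truncated Poisson mean is solved so the mean re-intervention
  frequency per eligible patient is 0.34 and 0.93;
* primary drainage as discrete session patterns priced from the packaged
  Korean fee schedule: EUS-BD always one session; PTBD staged
  internalization (2 or 3 sessions) with probability 0.484, else
  single-session external drainage;
* hospital and per-event re-intervention charges as log-normals truncated
  to the published ranges. The log-normal family is a declared modelling
  choice — the source states no distribution — motivated by the strong
  right skew of the published summaries (median far below maximum) and the
  positivity of costs; it is config-exposed, not hard-wired.
* cost components are independent by default; a Gaussian-copula rank
  correlation between hospital and re-intervention charges is exposed for
  sensitivity exploration, since the true dependence structure is unknown.

`calibrate_to_targets()` turns published median (range) summaries into
configurations: location at the printed median; scale chosen so the extremes
of an arm-sized sample, placed at Blom plotting positions
$(i - 0.375)/(n + 0.25)$, span the printed range; truncation to the printed
range. A category whose printed minimum equals its median (EUS-BD primary
cost) becomes a floor-fee spike plus a spread component; a printed minimum
of zero (re-intervention cost, which the Bernoulli structure zeroes anyway)
anchors the conditional distribution by geometric reflection of the maximum
about the median. Finally, because medians of skewed components do not add,
the dominant hospital-charge component is rescaled multiplicatively — a
deterministic search on a large fixed-seed internal sample — until the
implied arm total-cost median matches the printed total. All of these rules
were fixed as part of the design, before any acceptance measurement, and
the acceptance check (arm total-cost medians within 15% of the published
4,175.53 and 5,391.87 in at least 90% of 200 seeded replicates) is run
against them as-is.

What passing these tests shows — and does not show. The generator emulates
marginal cost distributions, re-intervention structure, and session
patterns; it does not model lengths of stay, adverse-event types, clinical
endpoints, or any real between-category dependence. Agreement of the
trial-level statistics on synthetic data therefore validates the
*implementation* of those statistics, not the clinical conclusions of the
source trial.

## Problem sizes and numerical choices

The default analysis sizes are the ones used throughout the documentation
and tests: 10,000 PSA trials, 1,000 bootstrap resamples, 0.01 grid step,
500-replicate coverage and calibration loops, a 40,000-patient internal
sample for calibration anchoring and a 60,000-patient sample when a "true"
generator mean is needed as a coverage target (its residual error is
negligible against bootstrap interval widths). Ties at one cent, quantiles
by type-7 interpolation for Monte-Carlo summaries and by order statistics
for bootstrap intervals, and half-up rounding to cents at presentation are
the package-wide conventions. Every stochastic entry point takes an explicit
seed and restores the caller's RNG state.

## Known limitations

* The Medicare model inherits the bundled reimbursement amounts as given;
  it does not rebuild CPT/DRG arithmetic, and a single conversion factor
  stands in for exchange-rate modelling.
* Only two comparators, no effectiveness dimension, and no states beyond
  one re-intervention episode — by design, since the source establishes
  clinical equivalence.
* The bias-corrected bootstrap is exact only as $B \to \infty$; with the
  default $B = 1{,}000$ the endpoint granularity is the resample order
  statistic, which the tests account for.
* The synthetic generator's independence default understates any real
  correlation between hospital stay and re-intervention costs; the rank
  correlation knob is a sensitivity tool, not an estimate.
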