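test_that("per-patient totals are the stated sums", {
  rec <- toy_records(eus_reint = c(0, 500), ptbd_reint = c(0, 0))
  agg <- aggregate_costs(rec)
  expect_equal(agg$total_bd_cost, agg$primary_bd_cost + agg$reintervention_cost)
  expect_equal(agg$total_cost, agg$hospital_other_cost + agg$total_bd_cost)
  one <- aggregate_costs(toy_records(eus_hosp = 3000, ptbd_hosp = 1)[1, ])
  expect_equal(one$total_bd_cost, 1029.15)
  expect_equal(one$total_cost, 4029.15)
})

test_that("record validation enforces the cost/count invariants", {
  rec <- toy_records()
  rec$reintervention_cost[1] <- 100 # cost without an event
  expect_error(validate_patient_records(rec), "n_reinterventions")
  rec <- toy_records()
  rec$hospital_other_cost[2] <- -5
  expect_error(validate_patient_records(rec), "non-negative")
  rec <- toy_records()
  rec$arm[1] <- "surgery"
  expect_error(validate_patient_records(rec), "arm")
  expect_error(validate_patient_records(toy_records()[0, ]), "empty")
})

test_that("arm summaries give median (range) per category and arm", {
  rec <- toy_records(eus_hosp = 4200, ptbd_hosp = c(3500, 3700, 3900))
  cmp <- summarize_arms(rec)
  hosp <- cmp$costs[cmp$costs$category == "hospital_other_cost", ]
  # a one-patient arm has median = min = max = that patient's value
  expect_equal(hosp$median_eus, 4200)
  expect_equal(hosp$min_eus, 4200)
  expect_equal(hosp$max_eus, 4200)
  expect_equal(hosp$median_ptbd, 3700)
  expect_true(all(cmp$costs$min_eus <= cmp$costs$median_eus &
                    cmp$costs$median_eus <= cmp$costs$max_eus))
  # permutation invariance over record order
  shuffled <- withr::with_seed(3, rec[sample(nrow(rec)), ])
  expect_equal(tidy(summarize_arms(shuffled)), tidy(cmp))
  # an arm with no patients is an error
  expect_error(summarize_arms(rec[rec$arm == "PTBD", ]), "both arms")
})

test_that("the published re-intervention structure is recovered from records", {
  cmp <- summarize_arms(korea_structure_records())
  r <- cmp$reintervention
  expect_equal(r$rate[r$arm == "EUS-BD"], 0.25, tolerance = 1e-12)
  expect_equal(r$rate[r$arm == "PTBD"], 17 / 31, tolerance = 1e-12)
  expect_equal(round(100 * r$rate[r$arm == "PTBD"], 1), 54.8)
  expect_lt(abs(r$mean_frequency[r$arm == "EUS-BD"] - 0.34), 0.01)
  expect_lt(abs(r$mean_frequency[r$arm == "PTBD"] - 0.93), 0.01)
})

test_that("Mann-Whitney matches the published hand example and handles ties", {
  res <- mann_whitney_p(c(1, 2), c(3, 4))
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)
  expect_identical(res$method, "exact")
  # identical samples: ties force the approximation path, p = 1
  res <- mann_whitney_p(c(5, 6, 7), c(5, 6, 7))
  expect_identical(res$method, "normal-approximation")
  expect_equal(res$p_value, 1)
  expect_error(mann_whitney_p(numeric(0), 1), "non-empty")
})

test_that("exact and approximate Mann-Whitney paths agree on n = 8 + 8", {
  withr::local_seed(14)
  for (i in 1:10) {
    a <- rnorm(8)
    b <- rnorm(8, mean = runif(1, -1, 1))
    exact <- mann_whitney_p(a, b)$p_value
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("null Mann-Whitney p-values keep the 5% type-I error rate", {
  reject <- withr::with_seed(77, {
    replicate(1000, {
      a <- rnorm(34, 5000, 1500)
      b <- rnorm(32, 5000, 1500)
      mann_whitney_p(a, b)$p_value < 0.05
    })
  })
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("degenerate bootstrap arms collapse to the point difference", {
  rec <- toy_records(eus_hosp = rep(10, 4), ptbd_hosp = rep(14, 4))
  rec$primary_bd_cost <- 0
  ci <- bc_bootstrap_diff(rec, "hospital_other_cost", n_boot = 200, seed = 1)
  expect_equal(ci$point_difference, -4)
  expect_equal(ci$lower, -4)
  expect_equal(ci$upper, -4)
  expect_true(ci$degenerate)
  expect_equal(ci$z0, 0)
})

test_that("BC endpoints follow the bias-corrected order-statistic rule", {
  # two-point arms: the bootstrap mean distribution is symmetric about the
  # observed difference, so across seeds z0 = 0 occurs whenever the realized
  # below/above counts balance; verify the BC rule in general and the
  # reduction to the plain percentile interval whenever z0 = 0
  rec <- toy_records(eus_hosp = c(0, 2, 0, 2), ptbd_hosp = rep(5, 4))
  a <- c(0, 2, 0, 2)
  b <- rep(5, 4)
  obs <- mean(a) - mean(b)
  n_boot <- 400
  saw_z0_zero <- FALSE
  for (seed in 1:40) {
    ci <- bc_bootstrap_diff(rec, "hospital_other_cost", n_boot = n_boot,
                            seed = seed)
    stats <- withr::with_seed(as.integer(seed), {
      ra <- matrix(sample(a, 4 * n_boot, replace = TRUE), nrow = n_boot)
      rb <- matrix(sample(b, 4 * n_boot, replace = TRUE), nrow = n_boot)
      rowMeans(ra) - rowMeans(rb)
    })
    sorted <- sort(stats)
    frac <- mean(stats < obs) + 0.5 * mean(stats == obs)
    frac <- min(1 - 0.5 / n_boot, max(0.5 / n_boot, frac))
    z0 <- qnorm(frac)
    at <- function(p) sorted[min(n_boot, max(1, ceiling(n_boot * p)))]
    expect_equal(ci$z0, z0)
    expect_identical(ci$lower, at(pnorm(2 * z0 - qnorm(0.975))))
    expect_identical(ci$upper, at(pnorm(2 * z0 + qnorm(0.975))))
    # endpoints are order statistics, never extrapolated
    expect_true(ci$lower %in% stats && ci$upper %in% stats)
    if (z0 == 0) {
      saw_z0_zero <- TRUE
      expect_identical(ci$lower, at(0.025))
      expect_identical(ci$upper, at(0.975))
    }
  }
  expect_true(saw_z0_zero)
})

test_that("bootstrap CIs are seed-reproducible and bracket the estimate", {
  trial <- simulate_trial(korea_arm_configs(), seed = 31)
  a <- bc_bootstrap_diff(trial$records, "total_cost", seed = 5)
  b <- bc_bootstrap_diff(trial$records, "total_cost", seed = 5)
  expect_identical(a, b)
  expect_lt(a$lower, a$upper)
  expect_true(a$lower <= a$point_difference && a$point_difference <= a$upper)
  # BCa is available as an option and stays close to BC here
  bca <- bc_bootstrap_diff(trial$records, "total_cost", seed = 5, method = "bca")
  expect_lt(abs(bca$lower - a$lower) / (a$upper - a$lower), 0.25)
  tab <- bootstrap_cost_table(trial$records, n_boot = 200, seed = 9)
  expect_identical(nrow(tab), 5L)
  expect_true(all(tab$lower <= tab$upper))
})
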