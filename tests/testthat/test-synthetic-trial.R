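test_that("identical seed and config give byte-identical records", {
  cfgs <- korea_arm_configs()
  t1 <- simulate_trial(cfgs, seed = 123)
  t2 <- simulate_trial(cfgs, seed = 123)
  expect_identical(t1$records, t2$records)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_patient_records(t1$records, p1)
  write_patient_records(t2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
  t3 <- simulate_trial(cfgs, seed = 124)
  expect_false(identical(t1$records, t3$records))
})

test_that("generated trials respect arm sizes, bounds and session structure", {
  cfgs <- korea_arm_configs()
  rec <- simulate_trial(cfgs, seed = 6)$records
  expect_equal(sum(rec$arm == "EUS-BD"), 34)
  expect_equal(sum(rec$arm == "PTBD"), 32)
  expect_equal(sum(rec$reint_eligible[rec$arm == "EUS-BD"]), 32)
  expect_equal(sum(rec$reint_eligible[rec$arm == "PTBD"]), 31)
  # EUS-BD is always a single session; PTBD draws 1-3 sessions
  expect_true(all(rec$n_primary_sessions[rec$arm == "EUS-BD"] == 1))
  expect_true(all(rec$n_primary_sessions[rec$arm == "PTBD"] %in% 1:3))
  # hospital costs stay within the configured truncation bounds
  for (arm in c("eus", "ptbd")) {
    d <- cfgs[[arm]]$hospital_cost_dist
    x <- rec$hospital_other_cost[rec$arm == cfgs[[arm]]$arm]
    expect_true(all(x >= d$lo & x <= d$hi))
  }
  # every record passes validation (simulate_trial validates internally)
  expect_silent(validate_patient_records(rec))
})

test_that("zero re-intervention probability yields cost-free follow-up", {
  cfgs <- point_mass_configs(eus_p = 0, ptbd_p = 0)
  rec <- simulate_trial(cfgs, seed = 1)$records
  expect_true(all(rec$reintervention_cost == 0))
  expect_true(all(rec$n_reinterventions == 0))
})

test_that("point-mass costs give identical patients and exact medians", {
  rec <- simulate_trial(point_mass_configs(eus_p = 0, ptbd_p = 0),
                        seed = 2)$records
  cmp <- summarize_arms(rec)
  hosp <- cmp$costs[cmp$costs$category == "hospital_other_cost", ]
  expect_equal(hosp$median_eus, 3000)
  expect_equal(hosp$min_eus, 3000)
  expect_equal(hosp$max_eus, 3000)
  expect_equal(hosp$median_ptbd, 3600)
  tot <- cmp$costs[cmp$costs$category == "total_cost", ]
  expect_equal(tot$median_eus, 4000)
  expect_equal(tot$median_ptbd, 4800)
})

test_that("the generator recovers its own re-intervention parameters", {
  cfgs <- korea_arm_configs()
  sums <- withr::with_seed(99, {
    purrr::map_dfr(1:500, function(i) {
      rec <- simulate_trial(cfgs)$records
      r <- summarize_arms(rec)$reintervention
      tibble::tibble(
        eus_events = r$events[r$arm == "EUS-BD"],
        eus_n = r$n_eligible[r$arm == "EUS-BD"],
        eus_freq = r$mean_frequency[r$arm == "EUS-BD"],
        ptbd_freq = r$mean_frequency[r$arm == "PTBD"]
      )
    })
  })
  p <- 8 / 32
  pooled <- sum(sums$eus_events) / sum(sums$eus_n)
  se <- sqrt(p * (1 - p) / sum(sums$eus_n))
  expect_lt(abs(pooled - p), 3 * se)
  # mean re-intervention frequencies match their configured targets
  expect_equal(mean(sums$eus_freq), 0.34, tolerance = 0.02)
  expect_equal(mean(sums$ptbd_freq), 0.93, tolerance = 0.03)
})

test_that("calibration rejects infeasible targets and honors degenerate ones", {
  targets <- korea_cost_targets()
  bad <- targets
  bad$median[1] <- bad$min[1] - 1
  expect_error(calibrate_to_targets(bad), "infeasible")
  # min = median = max collapses to a point mass
  degen <- targets
  degen <- dplyr::mutate(degen,
                         min = ifelse(category == "hospital_other_cost", 3000, min),
                         median = ifelse(category == "hospital_other_cost", 3000, median),
                         max = ifelse(category == "hospital_other_cost", 3000, max))
  cfgs <- calibrate_to_targets(degen, anchor_total = FALSE)
  expect_identical(cfgs$eus$hospital_cost_dist$type, "point")
  expect_equal(cfgs$eus$hospital_cost_dist$value, 3000)
})

test_that("calibrated configs track the published category medians", {
  cfgs <- calibrate_to_targets()
  targets <- korea_cost_targets()
  meds <- withr::with_seed(55, {
    reps <- purrr::map(1:40, function(i) {
      agg <- aggregate_costs(simulate_trial(cfgs)$records)
      list(
        eus_hosp = median(agg$hospital_other_cost[agg$arm == "EUS-BD"]),
        ptbd_hosp = median(agg$hospital_other_cost[agg$arm == "PTBD"]),
        eus_total = median(agg$total_cost[agg$arm == "EUS-BD"]),
        ptbd_total = median(agg$total_cost[agg$arm == "PTBD"])
      )
    })
    purrr::map(purrr::transpose(reps), ~ median(unlist(.x)))
  })
  tgt <- function(arm, cat) {
    targets$median[targets$arm == arm & targets$category == cat]
  }
  expect_equal(meds$eus_total, tgt("EUS-BD", "total_cost"), tolerance = 0.15)
  expect_equal(meds$ptbd_total, tgt("PTBD", "total_cost"), tolerance = 0.15)
  expect_equal(meds$eus_hosp, tgt("EUS-BD", "hospital_other_cost"), tolerance = 0.2)
  expect_equal(meds$ptbd_hosp, tgt("PTBD", "hospital_other_cost"), tolerance = 0.2)
})

test_that("the rank-correlation knob couples hospital and re-intervention costs", {
  base <- korea_arm_configs()
  cor_cfg <- base
  cor_cfg$ptbd$rank_correlation <- 0.9
  rec <- simulate_trial(cor_cfg, seed = 12)$records
  sub <- rec[rec$arm == "PTBD" & rec$n_reinterventions > 0, ]
  rho <- stats::cor(sub$hospital_other_cost,
                    sub$reintervention_cost / sub$n_reinterventions,
                    method = "spearman")
  expect_gt(rho, 0.5)
})
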