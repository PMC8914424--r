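test_that("the preference surface matches direct pairwise cost comparison", {
  model <- us_medicare_model()
  surf <- preference_surface(model, grid_spec(0, 0.5, 0.02))
  prof <- purrr::map(model$strategies, "profile")
  cost_e <- expected_cost(prof[[1]], surf$`p_eus-bd`)
  cost_p <- expected_cost(prof[[2]], surf$p_ptbd)
  expect_identical(surf$savings, cost_p - cost_e)
  oracle <- ifelse(cost_p - cost_e > 0.01, "EUS-BD",
                   ifelse(cost_e - cost_p > 0.01, "PTBD", "tie"))
  expect_identical(surf$preferred, oracle)
  # published range: EUS-BD favored at every node of [0, 0.5]^2
  expect_true(all(surf$preferred == "EUS-BD"))
})

test_that("savings are affine along every grid row and column", {
  surf <- preference_surface(us_medicare_model(), grid_spec(0, 1, 0.1))
  by_row <- split(surf$savings, surf$`p_eus-bd`)
  by_col <- split(surf$savings, surf$p_ptbd)
  for (s in c(by_row, by_col)) {
    expect_lt(max(abs(diff(diff(s)))), 1e-9)
  }
})

test_that("the surface at the base-case point reproduces the base-case savings", {
  model <- us_medicare_model()
  # a grid whose axes pass exactly through both base-case probabilities
  surf <- preference_surface(model, grid_spec(8 / 34, 17 / 32, 17 / 32 - 8 / 34))
  node <- surf[abs(surf$`p_eus-bd` - 8 / 34) < 1e-12 &
                 abs(surf$p_ptbd - 17 / 32) < 1e-12, ]
  expect_identical(nrow(node), 1L)
  expect_identical(node$preferred, "EUS-BD")
  expect_equal(node$savings, 4381.41, tolerance = 0.02)
  expect_identical(node$savings, run_base_case(model)$savings)
})

test_that("identical profiles tie exactly on the diagonal", {
  prof <- strategy_profile("A", 5000, 1000)
  inputs <- list(
    list(profile = prof, evidence = reintervention_evidence(3, 10)),
    list(profile = strategy_profile("B", 5000, 1000),
         evidence = reintervention_evidence(3, 10))
  )
  surf <- preference_surface(decision_model(inputs), grid_spec(0, 0.5, 0.1))
  diag <- surf$p_a == surf$p_b
  expect_true(all(surf$preferred[diag] == "tie"))
  off <- !diag
  expect_identical(surf$preferred[off],
                   ifelse(surf$p_a[off] < surf$p_b[off], "A", "B"))
})

test_that("equal-cost thresholds solve the affine crossing", {
  model <- us_medicare_model()
  # vary EUS-BD against PTBD at its base case
  p_star <- equal_cost_threshold(model, vary = "EUS-BD")
  expect_equal(p_star, (13369.98 + 17 / 32 * 957.11 - 8002.48) / 6351.83,
               tolerance = 1e-12)
  expect_equal(p_star, 0.9251, tolerance = 1e-4)
  # vary PTBD: no crossing in [0, 1] (PTBD at p = 0 already costs more)
  expect_true(is.na(equal_cost_threshold(model, vary = "PTBD")))
  # identical strategies: threshold is the fixed probability itself
  inputs <- list(
    list(profile = strategy_profile("A", 5000, 1000),
         evidence = reintervention_evidence(3, 10)),
    list(profile = strategy_profile("B", 5000, 1000),
         evidence = reintervention_evidence(3, 10))
  )
  same <- decision_model(inputs)
  expect_equal(equal_cost_threshold(same, "A", fixed_p = 0.37), 0.37)
  expect_error(equal_cost_threshold(model, "surgery"), "unknown")
})

test_that("the threshold lies on the surface preference boundary", {
  model <- us_medicare_model()
  step <- 0.01
  surf <- preference_surface(model, grid_spec(0, 1, step))
  # along the PTBD base-case row, find where preference leaves EUS-BD
  p_fix <- model$strategies[[2]]$evidence$point_estimate
  row <- surf[abs(surf$p_ptbd - 0.53) < step / 2, ]
  row <- row[order(row$`p_eus-bd`), ]
  boundary <- row$`p_eus-bd`[min(which(row$preferred != "EUS-BD"))]
  p_star <- equal_cost_threshold(model, "EUS-BD", fixed_p = row$p_ptbd[1])
  expect_lt(abs(boundary - p_star), step + 1e-9)
})

test_that("the favored region bound covers the published 0-50% range", {
  model <- us_medicare_model()
  expect_gte(favored_region_bound(model), 0.5)
  expect_equal(favored_region_bound(model, exact = TRUE),
               (13369.98 - 8002.48) / 6351.83, tolerance = 1e-12)
  # grid bound within one step of the exact bound
  expect_lt(abs(favored_region_bound(model, step = 0.01) -
                  favored_region_bound(model, exact = TRUE)), 0.01 + 1e-9)
  # equal profiles tie at the origin
  inputs <- list(
    list(profile = strategy_profile("A", 5000, 1000),
         evidence = reintervention_evidence(3, 10)),
    list(profile = strategy_profile("B", 5000, 1000),
         evidence = reintervention_evidence(3, 10))
  )
  expect_equal(favored_region_bound(decision_model(inputs)), 0)
})

test_that("surface plots and empty grids behave", {
  surf <- preference_surface(us_medicare_model(), grid_spec(0, 0.2, 0.1))
  expect_s3_class(autoplot(surf), "ggplot")
  expect_error(grid_spec(0.6, 0.4), "p_min")
  expect_error(grid_spec(0, 0.5, 0), "positive")
})
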