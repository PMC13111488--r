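test_that("the baseline arm collapses to one certain pathway", {
  base <- fixed_appliance_arm(2501)
  pw <- enumerate_pathways(base, discount_spec(), fixed_cost = 2501)
  expect_equal(nrow(pw), 1)
  expect_equal(pw$probability, 1)
  expect_equal(pw$cost, 2501)
  expect_equal(pw$effect, 1)
  # invariant under arbitrary timing parameters
  for (timing in list(discount_spec(0), discount_spec(0.1, 20, 12),
                      discount_spec(0.03, 8, 0))) {
    expect_equal(expected_cost(enumerate_pathways(base, timing, 2501)), 2501)
    expect_equal(expected_effect(enumerate_pathways(base, timing, 2501)), 1)
  }
})

test_that("an interceptive arm expands to the five tree pathways", {
  qh <- table2_arms()$quad_helix
  pw <- enumerate_pathways(qh, discount_spec(), fixed_cost = 2501)
  expect_equal(nrow(pw), 5)
  expect_equal(pw$probability,
               c(0.821 * 0.75, 0.821 * 0.25, 0.087 * 0.5, 0.087 * 0.5, 0.092))
  expect_equal(sum(pw$probability), 1, tolerance = 1e-12)
  expect_equal(pw$effect, c(1, 1, 0, 0, 0))
  # rescue pathways carry the discounted fixed-appliance cost on top
  rescue <- 2501 * 1.03^-5
  expect_equal(pw$cost, 1254 + c(0, rescue, 0, rescue, rescue))
})

test_that("an always-failing arm keeps zero-probability pathways", {
  arm <- treatment_arm("fail", 500, outcome_probabilities(0, 0, 1))
  pw <- enumerate_pathways(arm, discount_spec(), fixed_cost = 2501)
  expect_equal(nrow(pw), 5)
  expect_equal(pw$probability, c(0, 0, 0, 0, 1))
  expect_equal(expected_effect(pw), 0)
})

test_that("expected cost is the probability-weighted pathway sum", {
  single <- data.frame(label = "fixed", probability = 1, cost = 2501, effect = 1)
  expect_equal(expected_cost(single), 2501)
  two <- data.frame(label = c("a", "b"), probability = c(0.5, 0.5),
                    cost = c(100, 300), effect = c(1, 0))
  expect_equal(expected_cost(two), 200)
  # undiscounted rescue: hand-summed from the Table 2 quad-helix row
  qh <- table2_arms()$quad_helix
  pw0 <- enumerate_pathways(qh, discount_spec(annual_rate = 0), fixed_cost = 2501)
  expect_equal(expected_cost(pw0), 1254 + 0.34075 * 2501)
})

test_that("expected effect equals the initial full-success probability", {
  arms <- table2_arms()
  timing <- discount_spec()
  effects <- vapply(arms[-1], function(a) {
    expected_effect(enumerate_pathways(a, timing, 2501))
  }, numeric(1))
  expect_equal(round(effects[["quad_helix"]], 2), 0.82)
  expect_equal(round(effects[["activator"]], 2), 0.56)
  expect_equal(round(effects[["extra_oral_traction"]], 2), 0.57)
})

test_that("the long-term effect definition credits stable outcomes only", {
  qh <- table2_arms()$quad_helix
  pw <- enumerate_pathways(qh, discount_spec(), 2501, effect_definition = "long-term")
  expect_equal(pw$effect, c(1, 0, 1, 0, 0))
  expect_equal(expected_effect(pw), 0.821 * 0.75 + 0.087 * 0.5)
})

test_that("degenerate pathway inputs are rejected", {
  empty <- data.frame(label = character(), probability = numeric(),
                      cost = numeric(), effect = numeric())
  expect_error(expected_cost(empty), "empty", class = "orthocea_validation_error")
  expect_error(expected_effect(empty), "empty", class = "orthocea_validation_error")
  leaky <- data.frame(label = c("a", "b"), probability = c(0.5, 0.4),
                      cost = c(1, 2), effect = c(0, 1))
  expect_error(expected_cost(leaky), "sum", class = "orthocea_validation_error")
})

test_that("pathway enumeration conserves probability and matches the joint-distribution oracle", {
  set.seed(101)
  timing <- discount_spec()
  for (i in 1:200) {
    arm <- random_arm()
    fixed_cost <- runif(1, 0, 5000)
    pw <- enumerate_pathways(arm, timing, fixed_cost)
    expect_equal(sum(pw$probability), 1, tolerance = 1e-9)
    expect_equal(expected_cost(pw),
                 oracle_expected_cost(arm, timing, fixed_cost),
                 tolerance = 1e-12)
    # expected cost lies inside the pathway cost hull
    ec <- expected_cost(pw)
    expect_gte(ec, min(pw$cost) - 1e-9)
    expect_lte(ec, max(pw$cost) + 1e-9)
  }
})

test_that("expected cost is monotone in the rescue cost and in failure probabilities", {
  set.seed(202)
  timing <- discount_spec()
  for (i in 1:30) {
    arm <- random_arm()
    costs <- vapply(c(0, 1000, 2501, 4000), function(fc) {
      expected_cost(enumerate_pathways(arm, timing, fc))
    }, numeric(1))
    expect_true(all(diff(costs) >= -1e-9))
    # raise initial failure, renormalising on the success component
    p <- arm$outcomes
    room <- min(p[["success"]], 1 - p[["failure"]])
    bump <- room / 2
    shifted <- treatment_arm(
      arm$name, arm$initial_cost,
      outcome_probabilities(p[["success"]] - bump, p[["partial"]], p[["failure"]] + bump),
      arm$long_term
    )
    # with a common rescue year, moving mass from success to failure can only
    # add rescue cost (failures always rescue; successes only on relapse)
    expect_gte(
      expected_cost(enumerate_pathways(shifted, timing, 2501)),
      expected_cost(enumerate_pathways(arm, timing, 2501)) - 1e-9
    )
    # and raising the long-term failure rate (lower stability) does the same
    softer <- arm
    softer$long_term <- long_term_assumptions(
      after_success = arm$long_term[["after_success"]] / 2,
      after_partial = arm$long_term[["after_partial"]] / 2
    )
    expect_gte(
      expected_cost(enumerate_pathways(softer, timing, 2501)),
      expected_cost(enumerate_pathways(arm, timing, 2501)) - 1e-9
    )
  }
})

test_that("evaluate_arms reproduces per-arm enumeration and flags the baseline", {
  arms <- table2_arms()
  ev <- evaluate_arms(arms)
  expect_equal(nrow(ev), 5)
  expect_equal(sum(ev$is_baseline), 1)
  expect_equal(ev$expected_cost[ev$arm == "fixed_appliance"], 2501)
  qh_pw <- enumerate_pathways(arms$quad_helix, discount_spec(), 2501)
  expect_equal(ev$expected_cost[ev$arm == "quad_helix"], expected_cost(qh_pw))
  expect_error(evaluate_arms(arms[-1]), "baseline",
               class = "orthocea_validation_error")
})
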