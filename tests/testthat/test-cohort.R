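table1_probs <- function() {
  counts <- table1_counts()
  probs <- lapply(seq_len(nrow(counts)), function(i) {
    outcome_probabilities(counts$success[i] / counts$n[i],
                          counts$partial[i] / counts$n[i],
                          counts$failure[i] / counts$n[i])
  })
  names(probs) <- counts$arm
  probs
}

test_that("generated cohorts have the requested sizes and structure", {
  counts <- table1_counts()
  sizes <- setNames(counts$n, counts$arm)
  cohort <- generate_cohort(sizes, table1_probs(), seed = 42)
  expect_equal(nrow(cohort), sum(sizes))
  expect_equal(as.vector(table(cohort$arm)[counts$arm]), counts$n)
  expect_true(all(cohort$n_visits >= 1))
  expect_true(all(cohort$duration_months > 0))
  expect_true(all(cohort$outcome %in% c("success", "partial", "failure")))
  # observed success rates within 3 binomial SEs of truth
  summ <- estimate_rates(cohort)
  for (i in seq_len(nrow(counts))) {
    arm <- counts$arm[i]
    p <- counts$success[i] / counts$n[i]
    se <- sqrt(max(p * (1 - p), 1e-12) / counts$n[i])
    obs <- summ$p_success[summ$arm == arm]
    expect_lte(abs(obs - p), 3 * se + 1e-9)
  }
})

test_that("degenerate cohort requests behave predictably", {
  probs <- list(a = outcome_probabilities(1, 0, 0),
                b = outcome_probabilities(0.5, 0.3, 0.2))
  cohort <- generate_cohort(c(a = 50, b = 0), probs, seed = 1)
  expect_equal(nrow(cohort), 50)
  expect_true(all(cohort$outcome == "success"))
  expect_false("b" %in% cohort$arm)
  expect_error(generate_cohort(c(c = 10), probs), "missing probability",
               class = "orthocea_validation_error")
})

test_that("cohort generation is deterministic under a fixed seed", {
  sizes <- c(quad_helix = 300)
  probs <- list(quad_helix = outcome_probabilities(0.821, 0.087, 0.092))
  a <- generate_cohort(sizes, probs, seed = 9)
  b <- generate_cohort(sizes, probs, seed = 9)
  expect_identical(a, b)
  c <- generate_cohort(sizes, probs, seed = 10)
  expect_false(identical(a, c))
})

test_that("rate estimation reproduces the registry summary percentages", {
  cohort <- cohort_from_counts(table1_counts())
  summ <- estimate_rates(cohort)
  p <- setNames(summ$p_success, summ$arm)
  expect_equal(round(100 * p[["removable_plate"]], 1), 64.9)
  expect_equal(round(100 * p[["quad_helix"]], 1), 82.1)
  expect_equal(round(100 * p[["extra_oral_traction"]], 1), 57.4)
  expect_equal(round(100 * p[["activator"]], 1), 56.2)
  # conservation invariants
  expect_equal(summ$p_success + summ$p_partial + summ$p_failure,
               rep(1, nrow(summ)))
  expect_equal(summ$n_success + summ$n_partial + summ$n_failure, summ$n)
})

test_that("Wilson intervals bracket the estimate and degrade gracefully", {
  cohort <- cohort_from_counts(table1_counts())
  summ <- estimate_rates(cohort)
  expect_true(all(summ$ci_lower <= summ$p_success))
  expect_true(all(summ$ci_upper >= summ$p_success))
  expect_true(all(summ$ci_lower >= 0 & summ$ci_upper <= 1))
  # all-success arm: upper limit is exactly 1
  all_success <- summ[summ$arm == "fixed_appliance", ]
  expect_equal(all_success$ci_upper, 1)
  expect_lt(all_success$ci_lower, 1)
  expect_error(estimate_rates(data.frame()), "empty",
               class = "orthocea_validation_error")
})

test_that("count tables that do not sum to n are rejected", {
  bad <- table1_counts()
  bad$failure[2] <- bad$failure[2] + 14
  expect_error(cohort_from_counts(bad), "sum to n",
               class = "orthocea_validation_error")
})

test_that("cohort summaries rebuild model-ready arms", {
  summ <- estimate_rates(cohort_from_counts(table1_counts()))
  cost_table <- data.frame(
    arm = c("fixed_appliance", "removable_plate", "quad_helix",
            "extra_oral_traction", "activator"),
    cost_eur = c(2501, 1144, 1254, 994, 1152),
    is_baseline = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  arms <- cohort_to_params(summ, cost_table)
  expect_length(arms, 5)
  expect_true(arms$fixed_appliance$is_baseline)
  ev <- evaluate_arms(arms)
  eff <- setNames(round(ev$expected_effect, 2), ev$arm)
  expect_equal(eff[["quad_helix"]], 0.82)
  expect_equal(eff[["extra_oral_traction"]], 0.57)
  expect_equal(eff[["activator"]], 0.56)

  expect_identical(cohort_to_params(summ[0, ], cost_table), list())
  expect_error(cohort_to_params(summ, cost_table[-2, ]), "missing cost",
               class = "orthocea_validation_error")
  one <- cohort_to_params(summ[summ$arm == "quad_helix", ], cost_table)
  expect_length(one, 1)
})

test_that("surplus visits add to the visit count when switched on", {
  sizes <- c(a = 2000)
  probs <- list(a = outcome_probabilities(0.8, 0.1, 0.1))
  plain <- generate_cohort(sizes, probs, seed = 3)
  surplus <- generate_cohort(sizes, probs, surplus_visit_rate = 2, seed = 3)
  expect_gt(mean(surplus$n_visits), mean(plain$n_visits) + 1)
})
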