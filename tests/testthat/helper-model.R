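# Shared fixtures and the independent expected-cost oracle.

# Base-case arm set built in code (mirrors the packaged parameter fixture).
table2_arms <- function() {
  list(
    fixed_appliance = fixed_appliance_arm(2501),
    removable_plate = treatment_arm("removable_plate", 1144,
                                    outcome_probabilities(0.649, 0.274, 0.077)),
    quad_helix = treatment_arm("quad_helix", 1254,
                               outcome_probabilities(0.821, 0.087, 0.092)),
    extra_oral_traction = treatment_arm("extra_oral_traction", 994,
                                        outcome_probabilities(0.574, 0.089, 0.337)),
    activator = treatment_arm("activator", 1152,
                              outcome_probabilities(0.562, 0.139, 0.299))
  )
}

table1_counts <- function() {
  data.frame(
    arm = c("fixed_appliance", "removable_plate", "quad_helix",
            "extra_oral_traction", "activator"),
    n = c(4000, 1764, 655, 101, 1327),
    success = c(4000, 1145, 538, 58, 746),
    partial = c(0, 484, 57, 9, 184),
    failure = c(0, 135, 60, 34, 397),
    stringsAsFactors = FALSE
  )
}

# A random non-baseline arm drawn uniformly over valid parameters.
random_arm <- function(name = "random") {
  raw <- runif(3)
  p <- raw / sum(raw)
  treatment_arm(
    name, cost = runif(1, 0, 5000),
    outcomes = outcome_probabilities(p[1], p[2], p[3]),
    long_term = long_term_assumptions(runif(1), runif(1))
  )
}

# Brute-force oracle: materialise the joint distribution over
# (initial outcome) x (long-term outcome) and sum cost mass cell by cell.
# Independent of enumerate_pathways().
oracle_expected_cost <- function(arm, timing, fixed_cost) {
  rate <- timing$annual_rate
  pv_rescue <- function(year) fixed_cost / (1 + rate)^year
  if (arm$is_baseline) return(arm$initial_cost)
  p_init <- c(success = arm$outcomes[["success"]],
              partial = arm$outcomes[["partial"]],
              failure = arm$outcomes[["failure"]])
  q_stable <- c(success = arm$long_term[["after_success"]],
                partial = arm$long_term[["after_partial"]],
                failure = 0)
  total <- 0
  for (init in names(p_init)) {
    for (stable in c(TRUE, FALSE)) {
      pr <- p_init[[init]] * if (stable) q_stable[[init]] else 1 - q_stable[[init]]
      cost <- arm$initial_cost
      if (!stable) {
        year <- if (init == "success") timing$relapse_start_year else timing$follow_up_start_year
        cost <- cost + pv_rescue(year)
      }
      total <- total + pr * cost
    }
  }
  total
}
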