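#' Enumerate the root-to-leaf pathways of a treatment arm
#'
#' Expands the decision tree for one strategy. An interceptive arm has
#' exactly five pathways:
#' \enumerate{
#'   \item initial success, long-term stable;
#'   \item initial success, relapse, rescue fixed appliance;
#'   \item partial success, long-term stable;
#'   \item partial success, long-term failure, rescue fixed appliance;
#'   \item initial failure, fixed appliance.
#' }
#' The baseline fixed-appliance arm collapses to a single certain pathway.
#' Probability-0 pathways are retained so pathway counts are stable across
#' degenerate parameter settings.
#'
#' Pathway costs book the arm's own cost at year 0 (undiscounted) and add
#' the rescue fixed-appliance cost discounted to its start year
#' (`relapse_start_year` for pathway 2, `follow_up_start_year` for pathways
#' 4 and 5). The effect indicator is 1 exactly when the initial outcome is
#' full success (and for the baseline pathway); with
#' `effect_definition = "long-term"` it instead marks long-term success
#' without rescue treatment (pathways 1 and 3).
#'
#' @param arm A validated [treatment_arm()].
#' @param timing A [discount_spec()].
#' @param fixed_cost Cost of the rescue fixed-appliance course (EUR),
#'   undiscounted; typically the baseline arm's `initial_cost`.
#' @param effect_definition `"initial-success"` (default) or `"long-term"`.
#' @return A data frame with columns `label`, `probability`, `cost`,
#'   `effect`; probabilities sum to 1.
#' @examples
#' qh <- treatment_arm("quad_helix", 1254, outcome_probabilities(0.821, 0.087, 0.092))
#' enumerate_pathways(qh, discount_spec(), fixed_cost = 2501)
#' @export
enumerate_pathways <- function(arm, timing = discount_spec(), fixed_cost,
                               effect_definition = c("initial-success", "long-term")) {
  validate_arm(arm)
  effect_definition <- match.arg(effect_definition)
  if (!inherits(timing, "discount_spec")) timing <- do.call(discount_spec, timing)
  if (!is_number(fixed_cost) || fixed_cost < 0) {
    validation_error("fixed_cost", "must be a single non-negative number")
  }

  if (arm$is_baseline) {
    return(data.frame(
      label = "fixed",
      probability = 1,
      cost = arm$initial_cost,
      effect = 1,
      stringsAsFactors = FALSE
    ))
  }

  p <- arm$outcomes
  q <- arm$long_term
  c0 <- arm$initial_cost
  rescue_relapse <- present_value(fixed_cost, timing$relapse_start_year, timing$annual_rate)
  rescue_followup <- present_value(fixed_cost, timing$follow_up_start_year, timing$annual_rate)

  initial_success <- c(1, 1, 0, 0, 0)
  long_term_success <- c(1, 0, 1, 0, 0)
  data.frame(
    label = c(
      "success->stable", "success->relapse->fixed",
      "partial->stable", "partial->relapse->fixed",
      "failure->fixed"
    ),
    probability = c(
      p[["success"]] * q[["after_success"]],
      p[["success"]] * (1 - q[["after_success"]]),
      p[["partial"]] * q[["after_partial"]],
      p[["partial"]] * (1 - q[["after_partial"]]),
      p[["failure"]]
    ),
    cost = c(c0, c0 + rescue_relapse, c0, c0 + rescue_followup, c0 + rescue_followup),
    effect = if (effect_definition == "initial-success") initial_success else long_term_success,
    stringsAsFactors = FALSE
  )
}

check_pathways <- function(pathways) {
  if (!is.data.frame(pathways) || nrow(pathways) == 0) {
    validation_error("pathways", "empty pathway list")
  }
  if (abs(sum(pathways$probability) - 1) > 1e-9) {
    validation_error("pathways", sprintf(
      "pathway probabilities sum to %.10g, must be 1", sum(pathways$probability)
    ))
  }
  pathways
}

#' Expected cost of a strategy
#'
#' Probability-weighted sum of pathway costs:
#' `expected cost = sum(probability * cost)` over all pathways of the arm.
#'
#' @param pathways Pathway table from [enumerate_pathways()].
#' @return Expected cost in EUR.
#' @export
expected_cost <- function(pathways) {
  check_pathways(pathways)
  sum(pathways$probability * pathways$cost)
}

#' Expected effect of a strategy
#'
#' Probability-weighted sum of the pathway effect indicators. Under the
#' default effect definition this equals the arm's initial full-success
#' probability (1 for the baseline).
#'
#' @inheritParams expected_cost
#' @return Expected effect in `[0, 1]`.
#' @export
expected_effect <- function(pathways) {
  check_pathways(pathways)
  sum(pathways$probability * pathways$effect)
}

#' Evaluate the base case for a set of arms
#'
#' Enumerates pathways for every arm and returns per-arm expected costs and
#' effects. The rescue fixed-appliance cost is the baseline arm's own cost.
#'
#' @param arms Named list of validated arms, exactly one of them baseline.
#' @param timing A [discount_spec()].
#' @param effect_definition Passed to [enumerate_pathways()].
#' @return A data frame with columns `arm`, `expected_cost`,
#'   `expected_effect`, `is_baseline` (one row per arm).
#' @examples
#' arms <- read_arm_table(orthocea_example("table2_params.csv"))
#' evaluate_arms(arms)
#' @export
evaluate_arms <- function(arms, timing = discount_spec(),
                          effect_definition = c("initial-success", "long-term")) {
  effect_definition <- match.arg(effect_definition)
  baseline <- find_baseline(arms)
  rows <- lapply(arms, function(arm) {
    pw <- enumerate_pathways(arm, timing, fixed_cost = baseline$initial_cost,
                             effect_definition = effect_definition)
    data.frame(
      arm = arm$name,
      expected_cost = expected_cost(pw),
      expected_effect = expected_effect(pw),
      is_baseline = arm$is_baseline,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
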