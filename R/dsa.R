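#' Deterministic scenario grid
#'
#' The default one-at-a-time grid: treatment costs increased by 10% and 50%
#' (`c`), and the long-term failure rates after initial success (`sf`) and
#' after initial partial success (`psf`) varied by 10%, 50%, and 90% in
#' both directions.
#'
#' @param cost_changes Relative cost changes (default `c(0.10, 0.50)`).
#' @param rate_changes Relative failure-rate changes (default
#'   `c(-0.90, -0.50, -0.10, 0.10, 0.50, 0.90)`).
#' @return Data frame with columns `parameter` (`"c"`, `"sf"`, `"psf"`) and
#'   `relative_change`.
#' @export
scenario_grid <- function(cost_changes = c(0.10, 0.50),
                          rate_changes = c(-0.90, -0.50, -0.10, 0.10, 0.50, 0.90)) {
  rbind(
    data.frame(parameter = rep("c", length(cost_changes)),
               relative_change = cost_changes, stringsAsFactors = FALSE),
    data.frame(parameter = rep("sf", length(rate_changes)),
               relative_change = rate_changes, stringsAsFactors = FALSE),
    data.frame(parameter = rep("psf", length(rate_changes)),
               relative_change = rate_changes, stringsAsFactors = FALSE)
  )
}

#' Apply a one-parameter scenario to an arm
#'
#' Scenario semantics:
#' * `c` — multiply the arm's own treatment cost by `1 + relative_change`;
#' * `sf` — multiply the long-term failure rate after initial success
#'   (`1 - q_after_success`) by `1 + relative_change`, clamp to `[0, 1]`,
#'   and set the success rate to the complement;
#' * `psf` — same for the failure rate after initial partial success.
#'
#' Changes are multiplicative on the failure probability so every grid point
#' stays feasible for every arm. A `relative_change` of 0 returns the arm
#' unchanged (identity scenario). The baseline arm is invariant under `sf`
#' and `psf` (its long-term failure rate is 0).
#'
#' @param arm A validated [treatment_arm()].
#' @param parameter One of `"c"`, `"sf"`, `"psf"`.
#' @param relative_change Signed relative change (e.g. `0.5` for +50%).
#' @return The modified, re-validated arm.
#' @export
apply_scenario <- function(arm, parameter, relative_change) {
  validate_arm(arm)
  if (!is_number(relative_change)) validation_error("relative_change", "must be a single finite number")
  if (relative_change == 0) return(arm)
  if (parameter == "c") {
    new_cost <- arm$initial_cost * (1 + relative_change)
    if (new_cost < 0) validation_error("relative_change", "cost change below -100%")
    arm$initial_cost <- new_cost
  } else if (parameter %in% c("sf", "psf")) {
    field <- if (parameter == "sf") "after_success" else "after_partial"
    fail <- (1 - arm$long_term[[field]]) * (1 + relative_change)
    fail <- min(max(fail, 0), 1)
    arm$long_term[[field]] <- 1 - fail
  } else {
    validation_error("parameter", sprintf("unknown scenario parameter %s (use c, sf, psf)", parameter))
  }
  validate_arm(arm)
}

#' Run the deterministic sensitivity analysis
#'
#' Evaluates the expected cost of every arm under each scenario, varying one
#' parameter at a time while holding all others at base-case values, and
#' reports the change versus the base case (tornado-ready long format).
#'
#' For cost scenarios the rescue fixed-appliance cost scales with the
#' baseline arm's cost by default (`covary_fixed_cost = TRUE`), reflecting a
#' system-wide change in resource use or overheads; set it to `FALSE` to
#' inflate only the interceptive arms' own costs.
#'
#' @param arms Named list of validated arms (exactly one baseline).
#' @param timing A [discount_spec()].
#' @param scenarios Data frame with `parameter` and `relative_change`
#'   columns, e.g. [scenario_grid()]; an optional `arm` column restricts a
#'   scenario to one named arm (`NA` = all non-baseline arms).
#' @param covary_fixed_cost Should `c` scenarios also scale the baseline /
#'   rescue fixed-appliance cost? Default `TRUE`.
#' @param effect_definition Passed to [evaluate_arms()].
#' @return A list of class `"dsa_result"` with `base_case` (the
#'   [evaluate_arms()] table) and `scenarios` (long data frame: `scenario`,
#'   `parameter`, `relative_change`, `arm`, `expected_cost`,
#'   `delta_vs_base`).
#' @export
run_dsa <- function(arms, timing = discount_spec(), scenarios = scenario_grid(),
                    covary_fixed_cost = TRUE,
                    effect_definition = c("initial-success", "long-term")) {
  effect_definition <- match.arg(effect_definition)
  find_baseline(arms)
  base_case <- evaluate_arms(arms, timing, effect_definition)
  base_costs <- setNames(base_case$expected_cost, base_case$arm)

  rows <- vector("list", nrow(scenarios))
  for (s in seq_len(nrow(scenarios))) {
    par <- scenarios$parameter[s]
    rc <- scenarios$relative_change[s]
    scope <- if ("arm" %in% names(scenarios)) scenarios$arm[s] else NA_character_
    modified <- lapply(arms, function(arm) {
      in_scope <- if (is.na(scope)) !arm$is_baseline else identical(arm$name, scope)
      if (arm$is_baseline && par == "c" && covary_fixed_cost && is.na(scope)) {
        in_scope <- TRUE
      }
      if (in_scope) apply_scenario(arm, par, rc) else arm
    })
    ev <- evaluate_arms(modified, timing, effect_definition)
    rows[[s]] <- data.frame(
      scenario = sprintf("%s%+g%%", par, 100 * rc),
      parameter = par,
      relative_change = rc,
      arm = ev$arm,
      expected_cost = ev$expected_cost,
      delta_vs_base = ev$expected_cost - as.vector(base_costs[ev$arm]),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(scenario = character(), parameter = character(),
               relative_change = numeric(), arm = character(),
               expected_cost = numeric(), delta_vs_base = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(base_case = base_case, scenarios = out), class = "dsa_result")
}

#' @export
print.dsa_result <- function(x, ...) {
  cat(sprintf("<dsa_result> %d scenario evaluations over %d arms\n",
              nrow(x$scenarios), nrow(x$base_case)))
  invisible(x)
}
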