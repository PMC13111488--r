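#' Classify a point on the cost-effectiveness plane
#'
#' Strict-sign mapping of an incremental (effect, cost) pair to a quadrant:
#' northeast = costlier and more effective, northwest = costlier and less
#' effective, southeast = cheaper and more effective (dominant), southwest =
#' cheaper and less effective (trade-off). Any zero component maps to
#' `"boundary"`.
#'
#' @param delta_cost Incremental cost(s) versus baseline (vectorised).
#' @param delta_effect Incremental effect(s) versus baseline.
#' @return Character vector of quadrant labels.
#' @export
classify_quadrant <- function(delta_cost, delta_effect) {
  if (length(delta_cost) != length(delta_effect)) {
    validation_error("delta_cost", "delta_cost and delta_effect must have equal length")
  }
  out <- character(length(delta_cost))
  out[delta_cost > 0 & delta_effect > 0] <- "northeast"
  out[delta_cost > 0 & delta_effect < 0] <- "northwest"
  out[delta_cost < 0 & delta_effect > 0] <- "southeast"
  out[delta_cost < 0 & delta_effect < 0] <- "southwest"
  out[delta_cost == 0 | delta_effect == 0] <- "boundary"
  out
}

#' Incremental cost and effect versus the baseline
#'
#' @param outcome One-row data frame (or list) with `arm`/`arm_name`,
#'   `expected_cost`, `expected_effect` — e.g. a row of [evaluate_arms()].
#' @param baseline Same shape, for the baseline arm.
#' @return One-row data frame with `arm`, `delta_cost`, `delta_effect`,
#'   `quadrant`. Comparing an arm with itself gives zero deltas and quadrant
#'   `"boundary"`.
#' @export
incremental <- function(outcome, baseline) {
  dc <- outcome$expected_cost - baseline$expected_cost
  de <- outcome$expected_effect - baseline$expected_effect
  data.frame(
    arm = if (!is.null(outcome$arm)) outcome$arm else outcome$arm_name,
    delta_cost = dc,
    delta_effect = de,
    quadrant = classify_quadrant(dc, de),
    stringsAsFactors = FALSE
  )
}

#' Minimum required effectiveness for cost-neutrality
#'
#' The success level at which a cheaper strategy offers the same value for
#' money as the baseline, computed as the ratio of its expected cost to the
#' baseline's. Scale-invariant in the currency unit.
#'
#' @param arm_cost Expected cost of the strategy (vectorised).
#' @param baseline_cost Expected cost of the baseline, `> 0`.
#' @return `arm_cost / baseline_cost`.
#' @examples
#' min_required_effectiveness(1497, 2501) # ~0.60
#' @export
min_required_effectiveness <- function(arm_cost, baseline_cost) {
  if (!is_number(baseline_cost) || baseline_cost <= 0) {
    validation_error("baseline_cost", "must be > 0")
  }
  if (any(!is.finite(arm_cost)) || any(arm_cost < 0)) {
    validation_error("arm_cost", "must be >= 0")
  }
  arm_cost / baseline_cost
}

#' Margin to cost-neutrality, in percentage points
#'
#' `(observed - required) * 100`. Positive margins mean the strategy's
#' observed success rate exceeds the cost-neutral minimum; negative margins
#' are the increase in success rate that would be required to reach
#' cost-neutrality.
#'
#' @param observed Observed success proportion(s), in `[0, 1]`.
#' @param required Minimum required effectiveness, in `[0, 1]`.
#' @return Margin(s) in percentage points (not rounded; reporting rounds to
#'   whole points).
#' @export
effectiveness_margin <- function(observed, required) {
  for (nm in c("observed", "required")) {
    val <- get(nm)
    if (any(!is.finite(val)) || any(val < 0) || any(val > 1)) {
      validation_error(nm, "must lie in [0, 1]")
    }
  }
  (observed - required) * 100
}

#' Base-case cost-effectiveness table
#'
#' Builds the full incremental/threshold table from per-arm expected
#' outcomes, regardless of whether those outcomes came from the model
#' ([evaluate_arms()]) or from an externally supplied expected-cost table.
#' With `round = TRUE` the reporting rounding rules are applied: costs to
#' whole euros, effects and required effectiveness to two decimals, margins
#' to whole percentage points (all computed from unrounded values).
#'
#' @param outcomes Data frame with columns `arm`, `expected_cost`,
#'   `expected_effect`, `is_baseline` (exactly one baseline row).
#' @param round Apply reporting rounding (default `TRUE`).
#' @return Data frame with columns `arm`, `expected_cost`,
#'   `incremental_cost`, `expected_effect`, `incremental_effect`,
#'   `required_effectiveness`, `margin_points`, `quadrant`. Incremental and
#'   margin columns are `NA` for the baseline row.
#' @examples
#' printed <- read_expected_outcomes(orthocea_example("table3_expected.csv"))
#' cea_table(printed)
#' @export
cea_table <- function(outcomes, round = TRUE) {
  needed <- c("arm", "expected_cost", "expected_effect", "is_baseline")
  missing <- setdiff(needed, names(outcomes))
  if (length(missing) > 0) {
    validation_error("outcomes", sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (sum(outcomes$is_baseline) != 1) {
    validation_error("outcomes", "exactly one baseline row is required")
  }
  base <- outcomes[outcomes$is_baseline, ]
  dc <- outcomes$expected_cost - base$expected_cost
  de <- outcomes$expected_effect - base$expected_effect
  required <- min_required_effectiveness(outcomes$expected_cost, base$expected_cost)
  margin <- effectiveness_margin(outcomes$expected_effect, pmin(required, 1))
  out <- data.frame(
    arm = outcomes$arm,
    expected_cost = outcomes$expected_cost,
    incremental_cost = dc,
    expected_effect = outcomes$expected_effect,
    incremental_effect = de,
    required_effectiveness = required,
    margin_points = margin,
    quadrant = classify_quadrant(dc, de),
    stringsAsFactors = FALSE
  )
  out[outcomes$is_baseline, c("incremental_cost", "incremental_effect", "margin_points")] <- NA
  if (round) {
    out$expected_cost <- round(out$expected_cost)
    out$incremental_cost <- round(out$incremental_cost)
    out$expected_effect <- round(out$expected_effect, 2)
    out$incremental_effect <- round(out$incremental_effect, 2)
    out$required_effectiveness <- round(out$required_effectiveness, 2)
    out$margin_points <- round(out$margin_points)
  }
  rownames(out) <- NULL
  out
}

#' Read an externally supplied expected-outcome table
#'
#' Reads a CSV with columns `arm, expected_cost_eur, expected_effect` into
#' the shape [cea_table()] expects. The baseline is taken to be the row
#' named `fixed_appliance` unless an `is_baseline` column is present. The
#' packaged fixture `table3_expected.csv` carries the published base-case
#' expected costs and effects, whose total-cost composition is not
#' derivable from the arm parameter table alone.
#'
#' @param path Path to the CSV file.
#' @return Data frame with `arm`, `expected_cost`, `expected_effect`,
#'   `is_baseline`.
#' @export
read_expected_outcomes <- function(path) {
  if (!file.exists(path)) validation_error("path", sprintf("file not found: %s", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("arm", "expected_cost_eur", "expected_effect")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    validation_error("expected outcomes", sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  is_base <- if ("is_baseline" %in% names(tab)) as.logical(tab$is_baseline) else tab$arm == "fixed_appliance"
  data.frame(
    arm = tab$arm,
    expected_cost = tab$expected_cost_eur,
    expected_effect = tab$expected_effect,
    is_baseline = is_base,
    stringsAsFactors = FALSE
  )
}
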