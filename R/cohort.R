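#' Generate a synthetic registry-like cohort
#'
#' Emulates a patient-level extract from a regional clinical database:
#' per-arm outcome categories are independent multinomial draws at the given
#' true proportions, visit counts follow a shifted Poisson (minimum one
#' visit), and treatment durations a lognormal. The visit and duration
#' distributions are inventions of the generator — real registries report
#' only their empirical summaries — and are configurable per arm. Emergency
#' (surplus) visits are excluded by default; `surplus_visit_rate` adds a
#' Poisson count of extra visits per patient to support cost-inflation
#' experiments.
#'
#' @param arm_sizes Named integer vector: patients per arm.
#' @param true_probs Named list of [outcome_probabilities()] (one entry per
#'   arm in `arm_sizes`).
#' @param visit_mean Mean number of visits; scalar or named per-arm vector
#'   (default 8).
#' @param duration_mean_months Mean treatment duration in months; scalar or
#'   named per-arm vector (default 24).
#' @param duration_sdlog Lognormal log-scale SD of durations (default 0.4).
#' @param surplus_visit_rate Mean surplus (emergency) visits per patient
#'   (default 0 = excluded).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return Data frame of class `"cohort"` with columns `patient_id`, `arm`,
#'   `outcome` (`"success"`, `"partial"`, `"failure"`), `n_visits`,
#'   `duration_months`.
#' @examples
#' cohort <- generate_cohort(
#'   c(quad_helix = 100), list(quad_helix = outcome_probabilities(0.821, 0.087, 0.092)),
#'   seed = 1
#' )
#' table(cohort$outcome)
#' @export
generate_cohort <- function(arm_sizes, true_probs, visit_mean = 8,
                            duration_mean_months = 24, duration_sdlog = 0.4,
                            surplus_visit_rate = 0, seed = NULL) {
  if (is.null(names(arm_sizes)) || any(!nzchar(names(arm_sizes)))) {
    validation_error("arm_sizes", "must be a named vector")
  }
  if (any(arm_sizes < 0)) validation_error("arm_sizes", "sizes must be >= 0")
  missing <- setdiff(names(arm_sizes), names(true_probs))
  if (length(missing) > 0) {
    validation_error("true_probs", sprintf("missing probability entry for arm(s): %s",
                                           paste(missing, collapse = ", ")))
  }
  per_arm <- function(param, arm, default) {
    if (length(param) == 1 && is.null(names(param))) return(param)
    if (!is.null(names(param)) && arm %in% names(param)) return(param[[arm]])
    default
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  blocks <- lapply(names(arm_sizes), function(arm) {
    size <- arm_sizes[[arm]]
    if (size == 0) return(NULL)
    p <- true_probs[[arm]]
    if (!inherits(p, "outcome_probs")) p <- do.call(outcome_probabilities, as.list(p))
    vmean <- per_arm(visit_mean, arm, 8)
    dmean <- per_arm(duration_mean_months, arm, 24)
    if (vmean < 1) validation_error("visit_mean", "mean visits must be >= 1")
    if (dmean <= 0) validation_error("duration_mean_months", "mean duration must be > 0")
    outcome <- sample(c("success", "partial", "failure"), size, replace = TRUE,
                      prob = as.numeric(p))
    n_visits <- 1L + rpois(size, vmean - 1)
    if (surplus_visit_rate > 0) n_visits <- n_visits + rpois(size, surplus_visit_rate)
    duration <- rlnorm(size, meanlog = log(dmean) - duration_sdlog^2 / 2,
                       sdlog = duration_sdlog)
    data.frame(
      patient_id = sprintf("%s-%06d", arm, seq_len(size)),
      arm = arm,
      outcome = outcome,
      n_visits = n_visits,
      duration_months = duration,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), arm = character(),
                      outcome = character(), n_visits = integer(),
                      duration_months = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("cohort", class(out))
  out
}

#' Expand an aggregated outcome-count table into a cohort
#'
#' Turns a per-arm count table (columns `arm, n, success, partial, failure`)
#' into a degenerate patient-level cohort with the stated outcome counts
#' (visit counts and durations set to `NA`). Useful for feeding published
#' aggregate tables through [estimate_rates()]. Counts must sum to `n` per
#' arm.
#'
#' @param counts Data frame with columns `arm`, `n`, `success`, `partial`,
#'   `failure`.
#' @return A `"cohort"` data frame.
#' @examples
#' counts <- read.csv(orthocea_example("table1_counts.csv"))
#' estimate_rates(cohort_from_counts(counts))
#' @export
cohort_from_counts <- function(counts) {
  needed <- c("arm", "n", "success", "partial", "failure")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    validation_error("counts", sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  bad <- counts$success + counts$partial + counts$failure != counts$n
  if (any(bad)) {
    validation_error("counts", sprintf(
      "outcome counts do not sum to n for arm(s): %s",
      paste(counts$arm[bad], collapse = ", ")
    ))
  }
  blocks <- lapply(seq_len(nrow(counts)), function(i) {
    outcome <- rep(c("success", "partial", "failure"),
                   times = c(counts$success[i], counts$partial[i], counts$failure[i]))
    if (length(outcome) == 0) return(NULL)
    data.frame(
      patient_id = sprintf("%s-%06d", counts$arm[i], seq_along(outcome)),
      arm = counts$arm[i],
      outcome = outcome,
      n_visits = NA_integer_,
      duration_months = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("cohort", class(out))
  out
}

# Wilson score interval; closed form, no continuity correction.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Per-arm outcome rates from a cohort
#'
#' Sample proportions of success / partial success / failure per arm, with a
#' Wilson score confidence interval for the success rate, plus mean visit
#' counts and durations. Output mirrors a registry summary table.
#'
#' @param cohort A [generate_cohort()] / [cohort_from_counts()] data frame.
#' @param conf Confidence level for the Wilson interval (default 0.95).
#' @return Data frame of class `"cohort_summary"`: `arm`, `n`, `n_success`,
#'   `n_partial`, `n_failure`, `p_success`, `p_partial`, `p_failure`,
#'   `ci_lower`, `ci_upper`, `mean_visits`, `mean_duration_months`.
#' @export
estimate_rates <- function(cohort, conf = 0.95) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    validation_error("cohort", "empty cohort")
  }
  rows <- lapply(split(cohort, cohort$arm), function(d) {
    n <- nrow(d)
    ns <- sum(d$outcome == "success")
    np <- sum(d$outcome == "partial")
    nf <- sum(d$outcome == "failure")
    ci <- wilson_interval(ns, n, conf)
    data.frame(
      arm = d$arm[1], n = n,
      n_success = ns, n_partial = np, n_failure = nf,
      p_success = ns / n, p_partial = np / n, p_failure = nf / n,
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      mean_visits = mean(d$n_visits),
      mean_duration_months = mean(d$duration_months),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Build model arms from a cohort summary and a cost table
#'
#' Converts estimated per-arm outcome proportions into [treatment_arm()]
#' inputs for the decision tree, attaching each arm's treatment cost and the
#' configured long-term stability assumptions. A `TRUE` entry in the cost
#' table's `is_baseline` column marks the fixed-appliance comparator.
#'
#' @param summary A [estimate_rates()] table (or any data frame with `arm`,
#'   `p_success`, `p_partial`, `p_failure`).
#' @param cost_table Data frame with columns `arm`, `cost_eur` and optional
#'   `is_baseline`.
#' @param long_term A [long_term_assumptions()] applied to every
#'   non-baseline arm.
#' @return Named list of `"treatment_arm"` objects (empty summary gives an
#'   empty list).
#' @export
cohort_to_params <- function(summary, cost_table,
                             long_term = long_term_assumptions()) {
  if (nrow(summary) == 0) return(list())
  missing <- setdiff(summary$arm, cost_table$arm)
  if (length(missing) > 0) {
    validation_error("cost_table", sprintf("missing cost entry for arm(s): %s",
                                           paste(missing, collapse = ", ")))
  }
  arms <- lapply(seq_len(nrow(summary)), function(i) {
    arm_name <- summary$arm[i]
    row <- cost_table[cost_table$arm == arm_name, ][1, ]
    is_base <- isTRUE(as.logical(row$is_baseline))
    treatment_arm(
      name = arm_name,
      cost = row$cost_eur,
      outcomes = outcome_probabilities(summary$p_success[i], summary$p_partial[i],
                                       summary$p_failure[i]),
      long_term = if (is_base) {
        long_term_assumptions(after_success = 1, after_partial = 0)
      } else {
        long_term
      },
      baseline = is_base
    )
  })
  names(arms) <- summary$arm
  arms
}
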