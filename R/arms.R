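#' Initial treatment outcome probabilities
#'
#' Probabilities of the three initial outcomes of an interceptive (or
#' comparator) treatment course: full success, partial success (clear but
#' incomplete correction of the primary indication), and failure. The three
#' components must lie on the probability simplex.
#'
#' @param success,partial,failure Probabilities of the three initial outcome
#'   categories; each in `[0, 1]`, summing to 1 within `1e-9`.
#' @return A named numeric vector of class `"outcome_probs"` with components
#'   `success`, `partial`, `failure`.
#' @examples
#' outcome_probabilities(0.821, 0.087, 0.092) # quad helix
#' @export
outcome_probabilities <- function(success, partial, failure) {
  p <- c(success = success, partial = partial, failure = failure)
  for (nm in names(p)) {
    if (!is_number(p[[nm]])) validation_error(nm, "must be a single finite number")
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      validation_error(nm, sprintf("probability %.6g outside [0, 1]", p[[nm]]))
    }
  }
  if (abs(sum(p) - 1) > 1e-9) {
    validation_error(
      "outcome probabilities",
      sprintf("success + partial + failure = %.10g, must sum to 1", sum(p))
    )
  }
  structure(p, class = "outcome_probs")
}

#' Long-term stability assumptions
#'
#' Expert-set probabilities that an initial result remains stable over the
#' model horizon: the long-term success rate after an initially fully
#' successful treatment, and after a partial success. The complements are the
#' long-term failure (relapse) rates that trigger rescue fixed-appliance
#' therapy.
#'
#' @param after_success Long-term success probability given initial full
#'   success (default 0.75).
#' @param after_partial Long-term success probability given initial partial
#'   success (default 0.5).
#' @return A named numeric vector of class `"long_term_assumptions"`.
#' @export
long_term_assumptions <- function(after_success = 0.75, after_partial = 0.5) {
  q <- c(after_success = after_success, after_partial = after_partial)
  for (nm in names(q)) {
    if (!is_number(q[[nm]])) validation_error(nm, "must be a single finite number")
    if (q[[nm]] < 0 || q[[nm]] > 1) {
      validation_error(nm, sprintf("probability %.6g outside [0, 1]", q[[nm]]))
    }
  }
  structure(q, class = "long_term_assumptions")
}

#' Define a treatment strategy (arm) of the decision tree
#'
#' An arm bundles the strategy's own (initial) treatment cost with its initial
#' outcome probabilities and long-term stability assumptions. The baseline
#' comparator — comprehensive fixed-appliance therapy — is modelled as
#' certain: initial success 1 with long-term success 1.
#'
#' @param name Arm identifier, e.g. `"quad_helix"`.
#' @param cost Initial treatment cost in EUR, `>= 0`.
#' @param outcomes An [outcome_probabilities()] object.
#' @param long_term A [long_term_assumptions()] object.
#' @param baseline Logical; is this the baseline (fixed-appliance) arm?
#' @return A validated list of class `"treatment_arm"` with fields `name`,
#'   `initial_cost`, `outcomes`, `long_term`, `is_baseline`.
#' @seealso [validate_arm()], [fixed_appliance_arm()], [read_arm_table()]
#' @export
treatment_arm <- function(name, cost, outcomes,
                          long_term = long_term_assumptions(),
                          baseline = FALSE) {
  if (!inherits(outcomes, "outcome_probs")) {
    outcomes <- do.call(outcome_probabilities, as.list(outcomes))
  }
  if (!inherits(long_term, "long_term_assumptions")) {
    long_term <- do.call(long_term_assumptions, as.list(long_term))
  }
  arm <- structure(
    list(
      name = as.character(name),
      initial_cost = cost,
      outcomes = outcomes,
      long_term = long_term,
      is_baseline = isTRUE(baseline)
    ),
    class = "treatment_arm"
  )
  validate_arm(arm)
}

#' Baseline fixed-appliance arm
#'
#' Convenience constructor for the comparator: a 2-year fixed-appliance
#' course with assumed certain success (initial success 1, long-term
#' success 1).
#'
#' @param cost Treatment cost in EUR (default 2501, the base-case total).
#' @param name Arm identifier.
#' @return A `"treatment_arm"` with `is_baseline = TRUE`.
#' @export
fixed_appliance_arm <- function(cost = 2501, name = "fixed_appliance") {
  treatment_arm(
    name, cost,
    outcome_probabilities(1, 0, 0),
    long_term_assumptions(after_success = 1, after_partial = 0),
    baseline = TRUE
  )
}

#' Validate a treatment arm
#'
#' Checks every arm invariant: outcome probabilities on the simplex,
#' long-term probabilities in `[0, 1]`, non-negative cost, and — for a
#' baseline arm — certain success (`p_success = 1` and long-term success 1).
#' Violations raise a classed error (`"orthocea_validation_error"`) naming
#' the offending field.
#'
#' @param arm A `"treatment_arm"`.
#' @return The arm, unchanged, if valid.
#' @export
validate_arm <- function(arm) {
  if (!inherits(arm, "treatment_arm")) {
    validation_error("arm", "not a treatment_arm object")
  }
  if (!is_number(arm$initial_cost) || arm$initial_cost < 0) {
    validation_error("initial_cost", sprintf("cost must be >= 0, got %s", format(arm$initial_cost)))
  }
  # re-run component validation in case fields were modified in place
  do.call(outcome_probabilities, as.list(unclass(arm$outcomes)))
  do.call(long_term_assumptions, as.list(unclass(arm$long_term)))
  if (arm$is_baseline) {
    if (abs(arm$outcomes[["success"]] - 1) > 1e-9) {
      validation_error("p_success", "a baseline arm must have initial success probability 1")
    }
    if (abs(arm$long_term[["after_success"]] - 1) > 1e-9) {
      validation_error("q_success_after_success", "a baseline arm must have long-term success probability 1")
    }
  }
  arm
}

#' @export
print.treatment_arm <- function(x, ...) {
  cat(sprintf(
    "<treatment_arm> %s%s\n  cost %.0f EUR | initial s/p/f = %.3f/%.3f/%.3f | long-term success %.2f (after success), %.2f (after partial)\n",
    x$name, if (x$is_baseline) " [baseline]" else "",
    x$initial_cost,
    x$outcomes[["success"]], x$outcomes[["partial"]], x$outcomes[["failure"]],
    x$long_term[["after_success"]], x$long_term[["after_partial"]]
  ))
  invisible(x)
}

#' Read treatment arms from a delimited parameter table
#'
#' Reads a CSV with header columns `arm, cost_eur, p_success, p_partial,
#' p_failure, q_success_after_success, q_success_after_partial, is_baseline`
#' (one row per strategy) and returns a named list of validated arms. The
#' packaged fixture `table2_params.csv` holds the base-case inputs
#' (see [orthocea_example()]).
#'
#' @param path Path to the CSV file.
#' @return Named list of `"treatment_arm"` objects.
#' @examples
#' arms <- read_arm_table(orthocea_example("table2_params.csv"))
#' names(arms)
#' @export
read_arm_table <- function(path) {
  if (!file.exists(path)) validation_error("path", sprintf("file not found: %s", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c(
    "arm", "cost_eur", "p_success", "p_partial", "p_failure",
    "q_success_after_success", "q_success_after_partial", "is_baseline"
  )
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    validation_error("arm table", sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  arms <- lapply(seq_len(nrow(tab)), function(i) {
    treatment_arm(
      name = tab$arm[i],
      cost = tab$cost_eur[i],
      outcomes = outcome_probabilities(tab$p_success[i], tab$p_partial[i], tab$p_failure[i]),
      long_term = long_term_assumptions(
        after_success = tab$q_success_after_success[i],
        after_partial = tab$q_success_after_partial[i]
      ),
      baseline = as.logical(tab$is_baseline[i])
    )
  })
  names(arms) <- tab$arm
  arms
}

#' Locate a packaged example/fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path to the file (or a character vector of file names).
#' @export
orthocea_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "orthocea")))
  }
  path <- system.file("extdata", file, package = "orthocea")
  if (!nzchar(path)) validation_error("file", sprintf("no packaged file named %s", file))
  path
}

# Internal: single baseline arm from a list, with clear errors.
find_baseline <- function(arms) {
  idx <- which(vapply(arms, function(a) isTRUE(a$is_baseline), logical(1)))
  if (length(idx) == 0) validation_error("arms", "no baseline arm present")
  if (length(idx) > 1) validation_error("arms", "more than one baseline arm present")
  arms[[idx]]
}
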