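#' Default analysis configuration
#'
#' Houses the global settings of the evaluation: 3% annual discounting over
#' an 8-year horizon, rescue fixed-appliance treatment booked at year 5,
#' 10000 PSA iterations with a success-draw SD of 0.05, the standard DSA
#' grid, and the 2024 SEK-to-EUR rate 0.0875. Paths default to the packaged
#' fixtures: `table2_params.csv` (arm parameters) and `table3_expected.csv`
#' (the published base-case expected outcomes used for the CEA/threshold
#' table; set `expected_outcomes_file` to `NULL` to derive that table from
#' the model-evaluated base case instead).
#'
#' @return Nested list of class `"orthocea_config"`.
#' @export
default_config <- function() {
  structure(
    list(
      arms_file = orthocea_example("table2_params.csv"),
      expected_outcomes_file = orthocea_example("table3_expected.csv"),
      discount = list(
        annual_rate = 0.03,
        horizon_years = 8,
        follow_up_start_year = 5,
        relapse_start_year = 5
      ),
      psa = list(n_iterations = 10000, seed = 2020, target_sd = 0.05),
      dsa = list(
        cost_changes = c(0.10, 0.50),
        rate_changes = c(-0.90, -0.50, -0.10, 0.10, 0.50, 0.90),
        covary_fixed_cost = TRUE
      ),
      currency = list(eur_per_sek = 0.0875),
      effect_definition = "initial-success",
      rounding = list(costs = 0, effects = 2, required = 2, margins = 0)
    ),
    class = "orthocea_config"
  )
}

#' Load and validate an analysis configuration
#'
#' Reads a YAML configuration, overlays it on [default_config()], rejects
#' unknown keys, and validates every numeric range (delegating the
#' discounting block to [discount_spec()]). An empty or absent file yields
#' the defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `"orthocea_config"`.
#' @export
load_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    if (!file.exists(path)) validation_error("path", sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    check_keys(user, cfg, "config")
    cfg <- modifyList(cfg, user)
  }
  validate_config(structure(cfg, class = "orthocea_config"))
}

check_keys <- function(user, reference, where) {
  unknown <- setdiff(names(user), names(reference))
  if (length(unknown) > 0) {
    validation_error(where, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(reference[[nm]]) && !is.null(names(reference[[nm]]))) {
      if (!is.list(user[[nm]])) validation_error(nm, "must be a mapping")
      check_keys(user[[nm]], reference[[nm]], nm)
    }
  }
  invisible(TRUE)
}

validate_config <- function(cfg) {
  do.call(discount_spec, cfg$discount)  # range checks with field-level errors
  if (!is_number(cfg$psa$n_iterations) || cfg$psa$n_iterations < 1) {
    validation_error("psa.n_iterations", "must be >= 1")
  }
  if (!is_number(cfg$psa$target_sd) || cfg$psa$target_sd <= 0) {
    validation_error("psa.target_sd", "must be > 0")
  }
  if (!is_number(cfg$currency$eur_per_sek) || cfg$currency$eur_per_sek <= 0) {
    validation_error("currency.eur_per_sek", "must be > 0")
  }
  if (!cfg$effect_definition %in% c("initial-success", "long-term")) {
    validation_error("effect_definition", "must be 'initial-success' or 'long-term'")
  }
  if (!file.exists(cfg$arms_file)) {
    validation_error("arms_file", sprintf("file not found: %s", cfg$arms_file))
  }
  if (!is.null(cfg$expected_outcomes_file) && !file.exists(cfg$expected_outcomes_file)) {
    validation_error("expected_outcomes_file", sprintf("file not found: %s", cfg$expected_outcomes_file))
  }
  cfg
}

#' @export
print.orthocea_config <- function(x, ...) {
  cat("<orthocea_config>\n")
  cat(sprintf("  arms_file: %s\n", x$arms_file))
  cat(sprintf("  discount: %.0f%%/year over %g years; rescue at year %g\n",
              100 * x$discount$annual_rate, x$discount$horizon_years,
              x$discount$follow_up_start_year))
  cat(sprintf("  psa: %d iterations, seed %d, target SD %.3g\n",
              x$psa$n_iterations, x$psa$seed, x$psa$target_sd))
  invisible(x)
}
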