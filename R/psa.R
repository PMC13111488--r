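#' Calibrate a Dirichlet distribution to a target marginal dispersion
#'
#' Centers a Dirichlet on the observed outcome proportions and chooses the
#' concentration so that one component — by default the success
#' probability — has a given marginal standard deviation. Since each
#' Dirichlet marginal is Beta with variance `p(1-p)/(a0+1)`, the
#' concentration solving `sd^2 = p(1-p)/(a0+1)` is
#' `a0 = p(1-p)/sd^2 - 1`, and the calibration is exact in closed form.
#' With the default `target_sd = 0.05` roughly 95% of draws fall within
#' +/-0.10 of the observed success rate.
#'
#' @param center An [outcome_probabilities()] triple (the observed
#'   proportions).
#' @param target_sd Desired marginal SD of the calibrated component
#'   (default 0.05).
#' @param component Which component the SD targets (default `"success"`).
#' @return A list of class `"dirichlet_spec"` with fields `center`,
#'   `concentration`, `alpha` (= concentration x center), `calibrated_sd`,
#'   `component`.
#' @examples
#' calibrate_dirichlet(outcome_probabilities(0.821, 0.087, 0.092))
#' @export
calibrate_dirichlet <- function(center, target_sd = 0.05, component = "success") {
  if (!inherits(center, "outcome_probs")) {
    center <- do.call(outcome_probabilities, as.list(center))
  }
  if (!component %in% names(center)) {
    validation_error("component", sprintf("unknown component %s", component))
  }
  p <- center[[component]]
  if (p <= 0 || p >= 1) {
    validation_error("center", sprintf(
      "degenerate %s probability %g: a point-mass arm (e.g. the fixed baseline) cannot be calibrated and should be excluded from sampling",
      component, p
    ))
  }
  if (!is_number(target_sd) || target_sd <= 0) {
    validation_error("target_sd", "must be > 0")
  }
  a0 <- p * (1 - p) / target_sd^2 - 1
  if (a0 <= 0) {
    validation_error("target_sd", sprintf(
      "infeasible dispersion: need target_sd^2 < p(1-p) = %.6g", p * (1 - p)
    ))
  }
  structure(
    list(
      center = center,
      concentration = a0,
      alpha = a0 * unclass(center),
      calibrated_sd = target_sd,
      component = component
    ),
    class = "dirichlet_spec"
  )
}

# Gamma-normalisation construction of Dirichlet draws; alpha-0 components
# are degenerate at 0 (permitted: they stay exactly on the simplex face).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(0, nrow = n, ncol = k)
  pos <- alpha > 0
  g[, pos] <- matrix(
    rgamma(n * sum(pos), shape = rep(alpha[pos], each = n)),
    nrow = n
  )
  g / rowSums(g)
}

#' Sample outcome probabilities from a calibrated Dirichlet
#'
#' @param spec A [calibrate_dirichlet()] specification.
#' @param n Number of draws.
#' @return An `n x 3` matrix with columns `success`, `partial`, `failure`;
#'   every row lies on the probability simplex.
#' @export
sample_outcomes <- function(spec, n = 1) {
  if (!inherits(spec, "dirichlet_spec")) validation_error("spec", "not a dirichlet_spec")
  if (!is_number(n) || n < 1) validation_error("n", "must be >= 1")
  draws <- rdirichlet(n, spec$alpha)
  colnames(draws) <- names(spec$center)
  draws
}

#' Probabilistic sensitivity analysis
#'
#' For each non-baseline arm, samples `n` outcome-probability triples from a
#' Dirichlet centered on the arm's observed proportions (calibrated so the
#' success component has marginal SD `target_sd`) and propagates each draw
#' through the decision tree. The baseline arm, whose effect is assumed
#' certain, is held fixed and not sampled. Long-term stability assumptions
#' are held at their point values.
#'
#' Pathway costs do not depend on the outcome probabilities, so each arm's
#' five pathway costs are computed once via [enumerate_pathways()] and
#' recombined with the sampled probabilities; the result is identical to
#' re-enumerating the tree per draw.
#'
#' Reproducibility: each arm uses a private random substream whose seed is
#' derived from `(seed, arm position)`, so appending a new arm leaves the
#' draws of existing arms unchanged.
#'
#' @param arms Named list of validated arms (exactly one baseline).
#' @param timing A [discount_spec()].
#' @param n Number of Monte Carlo iterations (default 10000).
#' @param seed Master integer seed.
#' @param target_sd Calibrated marginal SD of the success draw (default 0.05).
#' @param effect_definition Passed to [enumerate_pathways()].
#' @return A list of class `"psa_result"` with elements `draws` (long data
#'   frame: `arm`, `draw`, `p_success`, `p_partial`, `p_failure`,
#'   `expected_cost`, `expected_effect`), `summary` (per-arm means and
#'   Monte Carlo standard errors), `baseline` (its fixed expected outcome),
#'   `base_case` (deterministic [evaluate_arms()] table), `n`, `seed`,
#'   `target_sd`.
#' @export
run_psa <- function(arms, timing = discount_spec(), n = 10000, seed = 1L,
                    target_sd = 0.05,
                    effect_definition = c("initial-success", "long-term")) {
  effect_definition <- match.arg(effect_definition)
  if (!is_number(n) || n < 1) validation_error("n", "must be >= 1")
  baseline <- find_baseline(arms)
  base_case <- evaluate_arms(arms, timing, effect_definition)

  draw_blocks <- list()
  for (i in seq_along(arms)) {
    arm <- arms[[i]]
    if (arm$is_baseline) next
    spec <- calibrate_dirichlet(arm$outcomes, target_sd = target_sd)
    set.seed(substream_seed(seed, i))
    probs <- sample_outcomes(spec, n)

    pw <- enumerate_pathways(arm, timing, fixed_cost = baseline$initial_cost,
                             effect_definition = effect_definition)
    # pathway probabilities are linear in the sampled triple:
    q <- arm$long_term
    path_probs <- cbind(
      probs[, "success"] * q[["after_success"]],
      probs[, "success"] * (1 - q[["after_success"]]),
      probs[, "partial"] * q[["after_partial"]],
      probs[, "partial"] * (1 - q[["after_partial"]]),
      probs[, "failure"]
    )
    cost_draws <- as.vector(path_probs %*% pw$cost)
    effect_draws <- as.vector(path_probs %*% pw$effect)

    draw_blocks[[arm$name]] <- data.frame(
      arm = arm$name,
      draw = seq_len(n),
      p_success = probs[, "success"],
      p_partial = probs[, "partial"],
      p_failure = probs[, "failure"],
      expected_cost = cost_draws,
      expected_effect = effect_draws,
      stringsAsFactors = FALSE
    )
  }
  draws <- do.call(rbind, draw_blocks)
  rownames(draws) <- NULL

  structure(
    list(
      draws = draws,
      summary = psa_summary_from_draws(draws, n),
      baseline = base_case[base_case$is_baseline, ],
      base_case = base_case,
      n = n,
      seed = seed,
      target_sd = target_sd
    ),
    class = "psa_result"
  )
}

substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483647)
}

psa_summary_from_draws <- function(draws, n) {
  split_draws <- split(draws, draws$arm)
  rows <- lapply(split_draws, function(d) {
    data.frame(
      arm = d$arm[1],
      mean_cost = mean(d$expected_cost),
      se_cost = sd(d$expected_cost) / sqrt(n),
      mean_effect = mean(d$expected_effect),
      se_effect = sd(d$expected_effect) / sqrt(n),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-arm PSA summary
#'
#' @param psa A [run_psa()] result.
#' @return Data frame with `arm`, `mean_cost`, `se_cost`, `mean_effect`,
#'   `se_effect` (Monte Carlo standard errors).
#' @export
psa_summary <- function(psa) {
  if (!inherits(psa, "psa_result")) validation_error("psa", "not a psa_result")
  psa$summary
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, seed %d, success-draw SD target %.3g\n",
              x$n, x$seed, x$target_sd))
  print(x$summary, ...)
  invisible(x)
}

#' Cost-effectiveness plane scatter from a PSA
#'
#' Draw-level incremental coordinates versus the fixed baseline, one row per
#' draw per sampled arm (the baseline, which is not varied, does not
#' appear). Each row also carries the arm's mean minimum required
#' effectiveness (mean draw cost over baseline cost) — the vertical
#' cost-neutrality line of the plane — and an `is_mean` flag marking one
#' extra row per arm holding the arm's mean point.
#'
#' @param psa A [run_psa()] result.
#' @return Data frame with columns `arm`, `draw`, `delta_cost`,
#'   `delta_effect`, `quadrant`, `mean_required_effectiveness`, `is_mean`.
#' @export
ce_scatter <- function(psa) {
  if (!inherits(psa, "psa_result")) validation_error("psa", "not a psa_result")
  base <- psa$baseline
  d <- psa$draws
  dc <- d$expected_cost - base$expected_cost
  de <- d$expected_effect - base$expected_effect
  mean_req <- tapply(d$expected_cost, d$arm, mean) / base$expected_cost
  out <- data.frame(
    arm = d$arm,
    draw = d$draw,
    delta_cost = dc,
    delta_effect = de,
    quadrant = classify_quadrant(dc, de),
    mean_required_effectiveness = as.vector(mean_req[d$arm]),
    is_mean = FALSE,
    stringsAsFactors = FALSE
  )
  means <- psa$summary
  mean_dc <- means$mean_cost - base$expected_cost
  mean_de <- means$mean_effect - base$expected_effect
  mean_rows <- data.frame(
    arm = means$arm,
    draw = NA_integer_,
    delta_cost = mean_dc,
    delta_effect = mean_de,
    quadrant = classify_quadrant(mean_dc, mean_de),
    mean_required_effectiveness = as.vector(mean_req[means$arm]),
    is_mean = TRUE,
    stringsAsFactors = FALSE
  )
  rbind(out, mean_rows)
}
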