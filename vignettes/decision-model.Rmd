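---
title: "A decision-tree model for the cost-effectiveness of interceptive orthodontics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree model for the cost-effectiveness of interceptive orthodontics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthocea)
```

## The decision problem

Publicly funded dental services face a choice between early, limited-objective
(interceptive) orthodontic treatment in the mixed dentition and later
comprehensive fixed-appliance therapy. Interceptive appliances — Quad Helix,
extra-oral traction (EOT), removable plates, Activator — are cheaper but less
reliable; failures and relapses are rescued by fixed appliances later.
`orthocea` models this trade-off as a decision tree and asks, from the payer's
perspective: what does each strategy cost in expectation, and how successful
must it be to break even against going straight to fixed appliances?

## Model structure

Each interceptive arm has three initial outcomes (full success, partial
success, failure) and, conditional on an initial success or partial success,
a long-term outcome (stable, or failure/relapse). Every long-term failure and
every initial failure receives rescue fixed-appliance therapy, assumed
certain to succeed. That yields exactly five root-to-leaf pathways per
interceptive arm; the baseline fixed-appliance arm is a single certain
pathway. Pathway probabilities are products along the branches, and

\[
\textrm{expected cost} = \sum_{\text{pathways}} \textrm{probability} \times \textrm{cost},
\]

evaluated by exhaustive enumeration (`enumerate_pathways()`,
`expected_cost()`). Zero-probability pathways are retained so the pathway
count is stable under degenerate parameters.

**Effect definition.** An arm's effect is the probability of initial full
success; partial success contributes no effect. This makes the baseline's
effect 1 and an interceptive arm's expected effect its observed initial
success rate. An alternative crediting long-term stability instead
(`effect_definition = "long-term"`) is available but not the default,
because the threshold analysis is framed around initial success rates.

## Parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| `annual_rate` | 0.03 | annual discount rate on costs |
| `horizon_years` | 8 | model horizon (interceptive start to end of any rescue course) |
| `follow_up_start_year` | 5 | year rescue fixed appliance starts after failure / failed partial success |
| `relapse_start_year` | 5 | year rescue starts after relapse of an initial success |
| long-term success after success | 0.75 | expert-set stability assumption |
| long-term success after partial success | 0.5 | expert-set stability assumption |
| PSA iterations | 10000 | Monte Carlo draws per arm |
| PSA `target_sd` | 0.05 | calibrated SD of the success draw |
| `eur_per_sek` | 0.0875 | 2024 average exchange rate |

Costs enter as per-treatment totals in EUR (each arm's full cost booked at
its start year; interceptive arms at year 0, undiscounted). Where a total
must be assembled from resource use, `assemble_cost()` adds materials,
professional fees, overhead, and visits × chair-time × personnel rate, and
`sek_to_eur()` converts at input time.

**Timing is a declared parameter, not an estimate.** Interceptive care
typically starts around ages 8–10 and fixed appliances around ages 14–16, so
rescue treatment is booked five years after model start by default. The
published base-case expected costs for the interceptive arms cannot be
reproduced from the arm parameter table under any single rescue-cost
discounting choice — their cost composition lives in supplementary costing
schedules — so the incremental/threshold layer (`cea_table()`) deliberately
accepts expected outcomes from any origin. The packaged
`table3_expected.csv` carries the published expected costs and effects for
validation, and the default pipeline configuration uses it for the
CEA/threshold table; setting `expected_outcomes_file` to null derives that
table from the model-evaluated base case instead.

```{r base-case}
arms <- read_arm_table(orthocea_example("table2_params.csv"))
evaluate_arms(arms)
cea_table(read_expected_outcomes(orthocea_example("table3_expected.csv")))
```

The threshold ("required effectiveness") is the ratio of an arm's expected
cost to the baseline's — the success level at which a cheaper strategy gives
value-for-money parity — and the margin is the observed success rate minus
that threshold, in percentage points. Reporting rounds costs to whole
euros, effects and thresholds to two decimals, margins to whole points;
all derived quantities are computed from unrounded values. One consequence
worth knowing: the published quad-helix incremental cost differs by 1 EUR
from the printed expected costs' difference (rounding of unprinted
intermediates), so comparisons there allow ±1 EUR.

## Probabilistic sensitivity analysis

Outcome probabilities estimated from observational data carry sampling
uncertainty. The PSA samples each interceptive arm's (success, partial,
failure) triple from a Dirichlet centered on the observed proportions. Since
each Dirichlet marginal is Beta with variance \(p(1-p)/(\alpha_0+1)\), the
concentration solving for a target success-component SD \(s\) is

\[
\alpha_0 = \frac{p(1-p)}{s^2} - 1,
\]

which `calibrate_dirichlet()` applies in closed form; the default
\(s = 0.05\) puts about 95% of draws within ±0.10 of the observed success
rate. The baseline arm is a point mass (assumed certain effect) and is not
varied; long-term stability assumptions are held at their point values.
Draws use a gamma-normalisation Dirichlet sampler; a zero component in the
center receives zero concentration and stays degenerate at zero.

Because pathway costs do not depend on the outcome probabilities, each arm's
five pathway costs are enumerated once and recombined with the sampled
triples; this is algebraically identical to re-evaluating the tree per draw,
and the test suite checks that PSA means recover the deterministic base case
within Monte Carlo error. Each arm draws from a private substream seeded by
(master seed, arm position), so adding an arm leaves existing arms' draws
unchanged.

```{r psa}
psa <- run_psa(arms, n = 2000, seed = 2020)
psa_summary(psa)
head(ce_scatter(psa), 3)
```

## Deterministic scenario analysis

One-at-a-time variation over a fixed grid: treatment costs +10% and +50%
(`c`), and the long-term failure rates after initial success (`sf`) and
after partial success (`psf`) varied ±10/50/90%. Rate changes are
multiplicative on the *failure* probability, with the paired success
probability absorbing the complement and clamping to [0, 1]; multiplicative
changes keep every grid point feasible for every arm, which additive changes
would not. Cost scenarios scale the rescue fixed-appliance course along with
the arms' own costs by default (`covary_fixed_cost = TRUE`), reading a cost
shock as system-wide; the switch restricts it to the interceptive arms. The
null scenario reproduces the base case bit-for-bit, and expected cost is
monotone along every grid axis — these properties, rather than published
bar heights, validate the implementation.

```{r dsa}
dsa <- run_dsa(arms, scenarios = scenario_grid())
head(dsa$scenarios)
```

## The synthetic cohort generator

Individual-level registry data behind analyses like this are
access-restricted, so `generate_cohort()` stands in for the registry
extract: per-arm outcome categories are independent multinomial draws at
given true proportions; visit counts follow a shifted Poisson (minimum one
visit, default mean 8); durations are lognormal (default mean 24 months,
`sdlog` 0.4, matching a roughly two-year interceptive course). The visit and
duration distributions are inventions of the generator — real registries
report only empirical summaries — and are configurable per arm. Emergency
(surplus) visits are excluded by default, mirroring the practice of dropping
less robust emergency-appointment data; a surplus-visit rate can be switched
on for cost-inflation experiments.

`estimate_rates()` returns per-arm proportions with Wilson score intervals
(closed form, no continuity correction), and `cohort_to_params()` rebuilds
model-ready arms from a summary plus a cost table. The packaged
`table1_counts.csv` reproduces the published registry outcome counts; its
removable-plate row is reconciled (failure = N − success − partial = 135)
because the source table's printed counts do not sum to its arm total while
its printed percentages do.

**What the recovery tests show.** Generating cohorts at the registry arm
sizes (1764/655/101/1327 plus 4000 baseline), re-estimating, and re-running
the model recovers success rates without bias (mean error below 0.01 over
200 replicates) and reproduces the truth run's cost-effectiveness-plane
quadrants exactly, with recovered required-effectiveness within 0.10 of
truth, in at least 95% of seeds. The 0.10 band is set by sampling theory
before anything else: the smallest arm (EOT, n = 101) gives the
required-effectiveness estimator a delta-method SE near 0.03, so three SEs
is about 0.09. A sharper conclusion — the *sign* of the cost-neutrality
margin — is genuinely undecidable at these sample sizes for the quad-helix
arm, whose margin under the default timing sits within about one standard
error of zero; no test asserts it. Passing these tests shows the estimator
and model plumbing are consistent, not that real registry data meet the
generator's assumptions (independence across patients, no clinic or
operator effects, no age structure, stationary outcome probabilities).

## Numerical choices and edge cases

- Probability triples must sit on the simplex within 1e-9; pathway
  probability conservation is checked at the same tolerance.
- Validation errors are classed (`orthocea_validation_error`) and name the
  offending field.
- A baseline arm must have success probability 1 and long-term success 1;
  exactly one baseline arm is required per analysis.
- Dirichlet calibration refuses degenerate centers (p ∈ {0, 1}; the fixed
  arm is excluded from sampling rather than calibrated) and infeasible
  dispersions (concentration ≤ 0).
- Identity scenarios (`relative_change = 0`) return the arm object itself,
  so null-scenario results are bitwise equal to the base case.
- Problem sizes in the shipped tests: 10,000 PSA iterations, 1,000
  random-arm oracle comparisons, 200 recovery replicates at full registry
  sizes — the scales at which the statistical checks above are stated.

## Known limitations

- A single decision tree, not a state-transition model: no per-tooth or
  per-malocclusion stratification, no repeated interceptive attempts.
- Rescue fixed-appliance therapy is assumed certain, an idealisation that
  flatters the baseline.
- Long-term stability parameters are expert-set constants; the PSA varies
  only initial outcome probabilities (cost uncertainty is handled in the
  deterministic scenarios, not the PSA).
- No willingness-to-pay threshold or net-monetary-benefit ranking; the
  plane coordinates and cost-neutrality thresholds are the outputs.
- Payer perspective only: no patient, family, or societal costs.
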