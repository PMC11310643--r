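---
title: "Methods: trial-based economic evaluation with DALY outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based economic evaluation with DALY outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dalyeval)
```

## Scope and model

`dalyeval` evaluates a health intervention against usual care in three
stages — costing, probabilistic cost-effectiveness, and budget impact —
starting from arm-level summaries of a two-arm individually randomized
trial with binary endline outcomes. Its motivating use case is an
underpowered trial: when confidence intervals are wide, a point null from
hypothesis testing is not evidence of zero effect, and the appropriate
question becomes *"what is the probability the intervention is
cost-effective, given the uncertainty?"*. The bundled example evaluates an
mHealth messaging-and-outreach programme for female entertainment workers
in Cambodia.

### From risk differences to DALYs averted

Each outcome *i* contributes an absolute risk difference
`ARD_i = R_intervention,i − R_control,i` (percentage points) and maps to a
disability weight `dw_i` in (0, 1). Under a 1-year horizon with no
mortality pathway, the DALYs attached to a health state for that year
equal its disability weight, so

```
ΔE = Σ_i (ARD_i / 100) · dw_i   [DALYs averted per person per year]
```

Assumptions this encodes, all deliberate:

* **No years of life lost.** Every outcome is a morbidity state; each
  outcome's contribution is bounded by its weight (`|ΔE_i| ≤ dw_i`).
* **Additivity and independence across outcomes.** Co-occurring states are
  not multiplicatively combined; outcomes are simulated and summed
  independently.
* **Signs carry through.** Outcomes on which the intervention
  underperforms (negative ARD) reduce the total; the model never clips
  them.
* **All five example outcomes are coded so the higher endline "risk" is
  the favourable state** (tested, used contraception, no forced drinking,
  low/no violence); the weight measures the burden avoided in that state.

The percent→proportion division by 100 happens exactly once, in
`dalys_averted()`; everything upstream stays on the percent scale of the
trial summaries.

The generic `adjust_dw()` hook exists for users supplying raw
burden-of-disease weights for screening outcomes, where the weight should
be scaled by disease prevalence and the probability of treatment after a
positive test. The bundled weights are treated as already adjusted, and
the hook defaults to the identity: the exact adjustment used to produce
them was not published, and the package does not guess it.

## Uncertainty propagation

`sample_draws()` draws, per simulation and outcome, the two arm risks and
the disability weight, independently:

* **Risks** come from the configured family, moment-matched to each arm's
  reported mean and SD: `normal` (base case), `beta` (moments matched on
  the proportion scale, requiring `sd² < mean(1−mean)`), or `uniform`
  (bounds `mean ± √3·sd`). Infeasible beta moments raise a named error
  rather than silently clamping.
* **Disability weights** always come from a moment-matched beta.

Numerical and reproducibility choices:

* **Normal risk draws are not truncated to [0, 100].** Truncation would
  bias the mean and SD away from the reported moments that define the
  model; out-of-range draws are rare at the example's SDs and are the
  price of exact moment matching.
* **Zero-SD inputs are point masses**, so a degenerate configuration
  reproduces the deterministic point estimate — a useful end-to-end check.
* **Single seeded generator, fixed draw order** (outcome-major: control
  risks, intervention risks, then weights, per outcome), so a seed fully
  determines the draw matrix and result files can be reproduced
  bit-identically from their metadata sidecars.
* **The "95% predicted interval" is defined as the 5th–95th percentile
  range** of the simulated values (a 90% interval by the usual coverage
  convention). The package follows that field convention for this quantity
  by default but exposes the percentile pair in `psa_config()`; intervals
  use linear interpolation between order statistics (R quantile type 7).

The uniform family deserves a caveat: the package parameterizes it by
moment matching, which keeps all three families mean-consistent. Published
uniform-family results for the bundled example evidently used asymmetric,
confidence-interval-derived bounds that were never printed, so the uniform
column is mean-shifted relative to them; it is retained as a sensitivity
family, not as a reproduction target.

## Decision layer

* **ICER = ΔC / E[ΔE]**, the ratio of expected values. Averaging per-sim
  ratios is undefined and unstable when the effect distribution crosses
  zero — which the example's predicted intervals show it does. The per-sim
  ratio distribution is still emitted (`ce_result()$per_sim_icer`) for
  inspection. Results carry the cost-effectiveness-plane quadrant and an
  explicit undefined flag instead of throwing on a zero mean effect.
* **Acceptability frontier**: at each willingness-to-pay λ the probability
  a strategy is cost-effective is the share of simulations in which it has
  the higher net monetary benefit (usual care being the zero-NMB
  reference); the *frontier* reports the strategy with the higher expected
  NMB, whose switch point is algebraically the ICER. The default grid,
  $0–$50,000 in $250 steps, covers the range over which reversals are
  plausible for this intervention class. The example's threshold range,
  $835–$1,671 per DALY averted, is 50–100% of Cambodia's 2019 per-capita
  GDP.
* **Break-even diagnostics**: `required_cost_reduction()` returns
  `1 − λ·E[ΔE]/ΔC` floored at zero; `required_effect()` returns `ΔC/λ`
  and, against a reference effect, both the plain ratio and ratio − 1.
  Prose statements of "X times higher" conflate the two conventions —
  for the example, ratio ≈ 6.6 and ratio − 1 ≈ 5.6 — so both are emitted,
  labelled, and neither is privileged.

## Costing

Payer costs enter as a flat ledger (funder × activity × input type ×
arm scope). Allocation is top-down: lines benefiting both arms are divided
evenly over *all* participants (both denominators summed), intervention-
only lines over intervention participants, which conserves money —
summing per-person costs times denominators recovers the ledger total.

Two example-specific choices:

* **Per-person overrides are first-class config.** The example's published
  per-person costs ($230 usual care, $429 intervention) are primary
  inputs, because the denominators behind them were never published. The
  package does not present a reverse-engineered denominator as ground
  truth; the allocation path is exercised by synthetic ledgers instead.
* **The bundled ledger reconciles a $1 rounding inconsistency** in its
  published source: the two education-and-communication lines of the
  larger funder sum to one dollar more than their published subtotal and
  total, so the personnel line is carried as 254,432 (not 254,433) to make
  every subtotal and funder total reproduce exactly.

Patient costs are time costs only: savings per person =
wage × (time without outreach − time with outreach) × contacts ×
arm contact rate, with time valued at the population's earnings rate
($270/week over a 40-hour week = $6.75/h in the example, 2.2 h vs 0.6 h
per care-seeking episode, two contacts). The combined payer-patient
perspective subtracts each arm's savings from its payer cost. The
example's arm-specific contact rates (0.600 vs 0.415) are **back-derived
synthetic values**: only their difference (0.185) is pinned down by the
published incremental cost, the levels were never published. Out-of-pocket
and transportation costs are excluded, matching the source evaluation's
scope. All money is in 2019 US dollars, as plain doubles; no discounting
(1-year horizon).

## Budget impact

The scale-up model is linear: a constant number of new enrollees per year
(default 6,958 toward a 50,000-person population — the published count is
kept primary over the rounder "14% per year", because five times 6,958
matches the published final coverage of 34,790). Costs accrue on
*cumulative* coverage — everyone enrolled keeps receiving messaging
($2.66/person/year) and outreach services ($9.54/person/year) — which is
what reproduces the published category shares (~62% outreach, ~17%
messaging). A one-off startup cost lands in year one; the example's
$316,700 is a **back-derived** figure reconciling the published ~$1.59M
horizon total, since the constituent capital-cost lines were never
itemized (a second published headline, $1.64M, is inconsistent with the
first; the package asserts internal consistency only, not either headline).
Outreach headcount (`ceiling(coverage / 280)`) is informational; costs use
the per-person rate. Nothing is discounted: budget impact is the financial
cost a payer must budget per year.

## What the synthetic trial generator does and does not show

`simulate_trial()` emulates exactly the statistical structure the
downstream summaries assume: per-arm Bernoulli outcomes at configurable
true risks, independent across participants and outcomes, with
missing-completely-at-random dropout (the example trial reported no
significant differences between dropouts and stayers, which this
idealizes). `estimate_risks()` then returns percent-scale risks with
binomial standard errors, and `sd_from_ci()` recovers an SD from a
reported mean and upper 95% limit via `(upper − mean)/1.96` — the exact
inverse of the normal upper-limit construction.

Passing parameter-recovery tests therefore show the estimators are correct
*under the model's own assumptions*. They do not show robustness to what
the generator omits: informative dropout, within-venue clustering,
correlated outcomes, covariate-adjusted (multilevel logistic) effect
estimation, or baseline/midline longitudinal structure. In the bundled
example the risk SDs were derived from adjusted odds-ratio confidence
intervals in unpublished appendices, so the fixture carries the published
SDs directly rather than recomputing them.

## Validation resolution

The test suite validates moment recovery of every sampler at 10^5 draws
(within 4 Monte Carlo standard errors), mean convergence of the DALY model
at 10^4 draws (3–4 MC SEs), estimator recovery of the synthetic trial at
10^4 participants per arm (3 binomial SEs), and the full decision-layer
identities (NMB/ICER consistency, break-even inverses, frontier
monotonicity for the normal and beta families) on 4,000-draw matrices.
These sizes make the whole suite run in seconds while leaving Monte Carlo
error well below every asserted tolerance.

## Known limitations

* One-year horizon; no years of life lost, no age weighting, no health or
  cost discounting, no QALY pathway.
* Two strategies only; no value-of-information analysis; no correlated
  probabilistic analysis (no copulas/Cholesky) — the model states no
  correlation structure to calibrate one against.
* The published total mean DALYs averted (0.018) slightly exceeds the
  analytic sum of its own published components (≈0.01746, which this
  package reproduces at full precision); exact reproduction of every
  published rounding is not possible from published inputs, and the
  package documents rather than forces such discrepancies.
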