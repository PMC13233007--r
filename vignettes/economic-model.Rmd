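---
title: "The dual-framework ED efficiency economic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual-framework ED efficiency economic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edmargin)
```

## The problem

Emergency departments run largely on standby capacity: most of their cost
is incurred whether or not another patient walks in. An intervention that
shortens length of stay (LOS) therefore has very different financial value
depending on how costs are modelled. A policy-style costing — cost imputed
from charges through a cost-to-charge ratio — moves cost in lockstep with
revenue and shows almost no margin effect from efficiency. A
management-style costing, which recognises that only part of cost responds
to throughput, attributes most of the extra revenue (or avoided labor) to
operating margin. `edmargin` implements both, side by side, so the same
operational change can be valued from either perspective.

## Model structure and assumptions

A period is summarised by visit volume $V$, total ED revenue $R$, and
median ED LOS $L$ (`period_summary()`). Baseline cost is anchored to
revenue through the expected operating margin rate $m$:

$$C = R\,(1 - m), \qquad \text{margin} = R - C .$$

The anchoring assumes the baseline period actually achieved the expected
margin rate; $m$ itself is an input (default 0.058), not estimated by the
package — deriving it from payer-specific margin benchmarks is out of
scope.

**Hospital-management framework.** $C$ is partitioned as 70% fixed
(standby labor, facility, equipment, overhead), 20% variable with patient
volume (supplies, pharmaceuticals), and 10% modifiable labor (contract
labor, overtime) that flexes with *care hours*, the product $V \times L$.
With volume ratio $v$ and care-hours ratio $h$,

$$C_{\mathrm{HM}} = 0.70\,C + 0.20\,C\,v + 0.10\,C\,h .$$

The partition is an assumption about ED cost behaviour, not a fit; all
three shares and $m$ are overridable through `model_params()`.

**Public-policy framework.** Cost proportional to revenue at the baseline
ratio: $C_{\mathrm{pol}} = R'(1-m)$. Note this is *proportional to
revenue*, not literally "constant cost per visit": the two coincide only
while revenue per visit is constant. The proportional dialect is the
primary implementation because it is the one consistent with the
framework's defining property that the margin rate never moves from $m$;
a literal constant-cost-per-visit variant is available as
`policy_cost(mode = "per_visit")` for users who want it.

## Scenarios, sweeps, and break-even

An efficiency change $e$ multiplies LOS by $(1-e)$. Two operating contexts
translate it into financials (`project_scenario()`):

* **Capacity-constrained** (demand exceeds supply): the freed time is
  refilled, volume moves equally and inversely, $V' = V(1+e)$, revenue
  scales at constant revenue per visit, $R' = R(1+e)$, and the care-hours
  ratio is $(1+e)(1-e) = 1-e^2$. We deliberately use $V' = V(1+e)$ rather
  than exact care-hours conservation $V' = V/(1-e)$: "equal and inverse"
  is the operative convention, and the two differ in the third decimal of
  the resulting break-even figures.
* **Volume-stable** (demand is met): $V$ and $R$ are unchanged; the
  care-hours reduction can be converted into modifiable-labor savings,
  $C_{\mathrm{HM}} = 0.70C + 0.20C + 0.10C\,(1 - e\,\kappa)$ with a
  *capture* fraction $\kappa \in [0,1]$ (default 1, i.e. the saving is
  fully commensurate with the LOS change; real staffing frictions argue
  for letting users set $\kappa < 1$). Policy-level cost is volume-driven
  and therefore unchanged, so the policy margin is flat in $e$: under that
  lens any positive tool price reduces margin.

`sweep_scenarios()` evaluates a grid (default $e \in [-0.10, 0.10]$ in
steps of 0.01, 21 points — wide enough to bracket plausible single-tool
effects). The break-even tool price per visit is

$$B = \frac{\text{margin}' - \text{margin}}{V'},$$

reported signed: a negative $B$ is flagged as "no sustainable tool cost"
rather than clamped to zero, so decreased-efficiency branches remain
visible in sweeps.

```{r}
pre <- period_summary(81464, 138309296, 311)
sweep_scenarios(pre, "capacity_constrained",
                e_grid = c(-0.05, 0, 0.05))[, c("e", "ed_los", "hm_margin",
                                                "hm_break_even",
                                                "policy_break_even")]
```

## Visit-level revenue processing

`process_visits()` turns raw visit records into period summaries in a
fixed order — attribute, cap, impute — chosen so that imputed values are
computed from capped values and therefore never exceed the cap:

1. **Attribution** (`attribute_admission_revenue()`): a discharged
   patient's revenue is wholly ED revenue; an admitted patient's ED share
   of the whole-stay revenue is $24/\mathrm{LOS_h}$ for stays of at least
   24 hours and $\min(1, 12/\mathrm{LOS_h})$ for shorter stays. Two
   boundary choices are ours: the fraction is capped at 1 (stays under
   12 h would otherwise be credited more than the stay earned), and
   exactly 24 h takes the long-stay branch so the fraction reaches 1
   there. The rule is inherently discontinuous at 24 h; no branch
   assignment removes that.
2. **Capping** (`cap_revenue()`): the cap is the 95th percentile of
   non-missing attributed revenue pooled over both periods (one cohort,
   one cap), computed by linear interpolation between order statistics;
   a nearest-rank convention is available. Capping is a deliberate
   conservative bias: high-revenue outliers follow high-acuity pathways
   unrelated to triage efficiency.
3. **Imputation** (`impute_missing_revenue()`): missing revenue takes the
   mean capped revenue of its disposition × payer stratum (pooled over
   periods). An all-missing stratum falls back to the overall mean with a
   warning; an all-missing cohort is an error.

Currency is kept at full double precision throughout; rounding (whole
dollars, cents for per-visit values, one decimal for rates) happens only
in printed reports. CSV input is validated strictly — unknown payer codes
are rejected with row numbers — with an opt-in lenient mode that maps them
to an `"other"` stratum.

## The synthetic cohort generator

`generate_cohort()` exists so every downstream stage can be exercised on
data with the right statistical shape. Design choices:

* **Distributions.** Attributed revenue per stratum and both LOS variables
  are log-normal: strictly positive and right-skewed, the standard minimal
  choice when only moments and quantiles are available to match. ED LOS
  uses `meanlog = log(311)` and a log-scale set from the target IQR ratio
  (182–554 min); with the median pinned, a two-parameter log-normal cannot
  match both quartiles exactly, so the ratio is used and both quartiles
  land within a few percent.
* **Calibration.** `study_like_config()` solves, by nested univariate
  root-finding, for the base log-location and common log-scale of the
  8-stratum revenue mixture such that the mixture's 95th percentile equals
  the target cap (US $7241) and the post-cap mean equals the target
  revenue per visit (US $1698). Stratum offsets (admissions above
  discharges; private > Medicare > Medicaid > self-pay) and the default
  admission rate (0.25) and payer mix (0.35/0.25/0.30/0.10) are fixed,
  realistic US-ED values; they shape the strata but the calibration keeps
  the aggregate targets exact. With mean and cap pinned, the revenue SD is
  an output (~1890), not an input.
* **Attributed-scale specification.** Distributions are specified on the
  ED-attributed scale, and whole-stay revenue for admits is
  back-constructed by dividing by the attribution fraction implied by the
  drawn hospital LOS. The processing pipeline then recovers exactly the
  configured attributed distribution — calibration would otherwise have to
  invert the attribution step numerically.
* **Missingness** is completely at random at rate 0.0319. Stratified-mean
  imputation is unbiased under MCAR, so generator-target recovery is exact
  in expectation.
* **Seeding.** One master seed; each period × field draw uses a substream
  seed derived deterministically from it, so changing one knob (say, the
  missingness rate) does not reshuffle unrelated fields. Generation is a
  pure function of the configuration.

What the generator does **not** emulate: arrival processes, boarding and
queueing dynamics, site heterogeneity, payer-dependent missingness (MAR),
within-patient correlation between LOS and revenue, and the exact revenue
SD of any real cohort. Tests passing on synthetic data therefore
demonstrate the pipeline's correctness and the model's internal
consistency — not that any particular hospital's data meet the
distributional assumptions.

## Numerical choices and degenerate inputs

* Percentile convention: linear interpolation (nearest-rank optional);
  `percentile = 1` disables capping exactly.
* All-equal revenue: cap equals the common value and nothing changes.
* Zero revenue: margins are defined, margin *rates* are an explicit error.
* `e = 0` reproduces the baseline bit-for-bit in both scenarios; the two
  frameworks coincide at the pre period by construction.
* Scenario sanity bound $|e| \le 0.5$; ratios must be positive.

## Problem sizes

Module tests run the generator at 50,000–100,000 visits, where three
standard errors of the recovered mean revenue per visit are about US $25
and of the median LOS about 4 minutes; cross-path consistency checks
(aggregate projection vs regenerated visit-level data) use 20,000–21,000
visits per period with tolerances computed from the realised per-visit
revenue variance. The acceptance script processes a 100,000-visit seeded
cohort. These sizes make Monte-Carlo noise small relative to every
tolerance while keeping the whole suite fast.

## Limitations

The model is deterministic and single-period: no probabilistic sensitivity
analysis, discounting, multi-year horizons, or learning curves. It values
the ED in isolation — downstream inpatient financial effects, physician
professional fees, and patient out-of-pocket costs are out of scope. The
70/20/10 partition and the margin rate are assumptions to be localised,
not estimates; results are linear in each, so one-way sensitivity on them
is straightforward with `model_params()`.
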