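---
title: "Budget impact methodology in bimpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Budget impact methodology in bimpact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimpact)
```

## The model

`bimpact` implements deterministic budget impact analysis (BIA) as used in
formulary and health-technology-assessment work: given a payer's eligible
population, the per-patient annual cost of each treatment option, and two
market-share trajectories — the *baseline* (current practice, the "control"
scenario) and a *projected* uptake scenario — it reports, for each year of a
short horizon,

* the total cost of each scenario,
  $C(t) = \sum_k N(t)\, s_k(t)\, c_k(t)$,
* the incremental budget impact
  $\Delta C(t) = C_{\text{proj}}(t) - C_{\text{base}}(t)$
  (negative values are savings),
* the per-patient impact $\Delta C(t) / N(t)$, rounded to integer currency,
  classified against an affordability threshold, and
* the cumulative impact $\sum_t \Delta C(t)$.

BIA is distinct from cost-effectiveness analysis: there are no QALYs, no
ICERs, and — following standard BIA practice for short horizons — **no
discounting or inflation adjustment**. Money is reported in the nominal year
it is spent. Any real-world price drift belongs in the per-year unit-cost
table, not in a deflator.

The shipped fixtures model the adoption of CDK4/6 inhibitors (abemaciclib,
ribociclib, palbociclib) with endocrine therapy for HR+/HER2− advanced
breast cancer in a single national cancer-care payer over 2024–2028, in
Qatari riyals (QAR, fixed at QAR 3.65 per USD).

### Population projection

The treated cohort starts at `base_count` patients and changes by a *net
prevalence rate* $g$ = incidence − dropout (additive, not compounded
multiplicatively: the two rates describe flows into and out of the same
cohort within a year). Counts are projected sequentially,

$$N(t) = \operatorname{round}\bigl(N(t-1)\,(1+g)\bigr),$$

with rounding to the nearest integer, ties away from zero, and the *rounded*
count feeding the next year's growth. This is the convention under which a
cohort of 173 at $g = 5\%$ gives 173, 182, 191, 201, 211: the 2027 value
200.55 requires ties-away-from-zero, and the 2028 value 211.05 requires
nearest rounding rather than ceiling. `rounding_policy = "none"` keeps the
exact closed form $N(0)(1+g)^t$ for analysis work.

### Arms, unit costs, and the baseline

Arms are opaque cost-bearing baskets. A `comparator_mix` arm may stand for a
blend of drugs plus standard care priced at one per-patient rate — the
fixtures price "PLBO/RIBO/Other Tx" as a single basket because that is the
resolution at which payer planning tables are published, and no per-drug
decomposition is available. Unit costs are stored per (arm, year): the
back-derived fixture costs drift non-uniformly across years and no inflation
rule reproduces them.

The baseline scenario is carried by a dedicated `std_care` basket arm whose
per-year rate is the published baseline total divided by $N(t)$, with the
baseline trajectory giving it share 1. The scenario narrative describes the
current market as already containing some abemaciclib, but the published
baseline totals equal $N(t)$ times a single blended rate, so that is what
the fixture encodes.

For new analyses built bottom-up rather than back-derived,
`annual_cost_from_components()` assembles a per-patient year from itemised
components (drug cost per cycle × cycles per year — 13 for a 28-day
schedule — plus annual laboratory, imaging, cardiac monitoring, outpatient
and hospitalisation costs).

### Engine arithmetic

Within a year, the year-level count $N(t)$ is an integer but arm-level
populations stay fractional: arm cost is $N \cdot s_k \cdot c_k$ with
$s_k N$ unrounded. The published cells match this fractional arithmetic
(e.g. an arm cost divided by 34.6 patient-years), not integer headcounts.
Only two reported quantities are rounded: per-patient impacts (to integer
QAR, ties away from zero) and converted USD figures (truncated toward zero,
the convention that reproduces the published USD value).

### Affordability

The threshold is a GDP-per-capita multiple, by default 1.5×, with a 10%
tolerance band: per-patient impacts ≤ 0 are `saving`, up to the threshold
$T$ `affordable`, within $(1+0.10)\,T$ `borderline`, above that
`unacceptable`. The fixtures pin $T$ by `override_value` to QAR 453,822 —
the value the published analysis adopts — rather than the formula product
$1.5 \times 302{,}172 = 453{,}258$, which does not equal the adopted figure;
the override field exists precisely so a model can carry the
decision-maker's stated threshold verbatim.

## Back-derivation of the fixture unit costs

No machine-readable unit costs are deposited anywhere; every number needed
is, however, printed in (or derivable from) the two published scenario
tables. `derive_unit_costs()` inverts the engine arithmetic on those cells:

$$c_k(t) = \frac{\text{arm cost cell}}{s_k(t)\, N(t)}, \qquad
  c_{\text{base}}(t) = \frac{\text{baseline total}}{N(t)}.$$

Printed cells are rounded to integer QAR, which leaves the tables internally
inconsistent by ±1 QAR: arm cells need not sum exactly to the printed
scenario total, and one printed incremental differs by 1 from the difference
of its own printed totals. Two derivation conventions are exposed:

* `reconcile = "none"` — the literal per-cell division above;
* `reconcile = "totals"` (fixture default) — the intervention cost comes
  from its own cell, and the comparator-mix cost from the residual
  (scenario total − intervention cell). Anchoring the blend to the printed
  totals reproduces every scenario total and every per-patient integer
  exactly; the cost of this choice is that recomputed comparator arm cells
  can differ from their printed values by 1 QAR (relative error ~1e-7).

`fixture_consistency()` recomputes all ~60 printed cells per scenario
through the engine and reports per-cell deviations; both fixtures pass at a
maximum relative deviation below 1e-6, well inside the 1e-4 gate.

Two details of the published study are deliberately *not* reproduced as
defaults. First, the narrative describes uptake trajectories
(10/20/35/50/60% and 40/50/60/70/80%) that conflict with the tables' own
share columns (20/30/40/50/60% and 30/40/50/65/80%); the tables are
arithmetically self-consistent, so they are authoritative, and the narrative
variants ship as `scenario*_fixture(uptake = "methods")`. Second, the
published per-patient-per-year average saving (QAR 14,613) uses an unknown
divisor — cumulative savings over total patient-years gives 14,001,749 / 958
≈ 14,616 — so the package reports no such average.

## One-way sensitivity analysis

Uncertainty is explored deterministically, one parameter at a time
(probabilistic sensitivity analysis is standard for cost-effectiveness, not
for BIA, and is intentionally absent). Two axis types exist:

* **Cost factors** multiply selected arms' unit costs by $(1+f)$. By
  default a cost change applies wherever the arm appears
  (`scenario_scope = "both"`). Because unit costs live in one (arm, year)
  table, a one-sided scope is only meaningful when the selected arm appears
  in a single trajectory; `perturb_spec()` refuses the ambiguous case
  rather than guessing.
* **Uptake shifts** add $\pm x$ *percentage points* to the intervention
  share in every projected year, the comparator arms absorbing the
  complement in proportion to their shares; shifts that would push any
  year's share outside $[0,1]$ fail loudly. The percentage-point reading
  is pinned by the published sensitivity results: scaling the year-5 saving
  by 0.7/0.6 and 0.5/0.6 reproduces the printed QAR 5,270,684 and
  3,764,774 exactly, while a relative ±10% does not.

The published cost-perturbation sensitivity figures (e.g. the standard-care
reduction series) are not reproducible under any scope/selector convention
we tried — the engine exposes the conventions as configuration instead of
hard-coding an unverifiable one, and those figures carry no tests.

`spider_series()` returns the long (axis, level, outcome) table behind a
spider plot, with the base case at level 0 for every axis; cumulative
impact is affine in a uniform uptake shift, so those three points are
collinear (tested to 1e-6).

## The synthetic generator

`generate_synthetic_spec()` draws reproducible random models for property
testing: a base cohort of 50–500 patients, net growth 0–10%/year, per-arm
base costs of QAR 50k–250k with ±3%/year multiplicative drift, a monotone
intervention uptake path, and comparator baskets at fixed weights. These
ranges bracket the fixture conditions (173 patients, 5% growth, costs
around QAR 144k–180k). The expected result is computed in closed form —
$\Delta C(t) = N(t)\,s(t)\,(c_{\text{int}} - \bar c_{\text{comp}})$ —
independently of the engine's evaluation loop, and must match to 1e-9
relative.

What the generator does *not* emulate: treatment-duration attrition within
a year (patients are costed for full years, as in the published model),
adverse-event micro-costing, dose reductions or wastage, correlated price
changes across arms, and share trajectories that are anything but monotone.
Passing tests therefore certify the accounting arithmetic, not the clinical
realism of any particular input set.

## Numerical choices and limitations

* Share sums are validated to 1e-9; blended weights likewise.
* Ties in rounding always go away from zero (`round_half_away()`), for both
  patient counts and per-patient QAR.
* All computation is double precision over quantities ≤ 1e8, so worst-case
  representation error (~1e-8 QAR) is far below the 1 QAR print resolution.
* Horizons are capped at 50 years; undiscounted BIA past a decade is not
  meaningful, and the cap catches unit errors in config files.
* The test suite and examples run in seconds on one CPU: every scenario is
  a 5-year, 2–4-arm model, and the sensitivity grid is at most a few dozen
  engine evaluations.
* Validation reports (`validate_model_spec()`) collect *all* violations
  rather than stopping at the first, so a hand-edited YAML can be fixed in
  one pass.

## Worked example

```{r example}
res <- run_budget_impact(scenario1_fixture())
result_table(res)
res$cumulative
convert_currency(abs(res$cumulative))
```

```{r sensitivity}
sp <- one_way_analysis(
  scenario1_fixture(),
  sensitivity_axis("uptake_pp", "uptake_trajectory", levels = c(-0.1, 0.1)))
spider_series(sp, "cumulative")
```
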