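---
title: "Methods: hierarchical forecasting of blood donations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical forecasting of blood donations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

donorcast forecasts monthly blood-donation counts organised in a strict
balanced tree — total donations, split by donor gender, split again by ABO
blood group — and guarantees that the forecasts are *coherent*: every
parent forecast equals the sum of its children. This vignette documents
the model, the tunable parameters, the synthetic data the package is
validated on, and the design decisions taken where several defensible
choices existed.

## The hierarchy and the summing matrix

A hierarchy is declared as a parent → children mapping
(`hierarchy_spec()`); only strict balanced trees are accepted — one root,
one parent per node, all leaves at the same depth. Grouped or unbalanced
structures are rejected with a classed error rather than guessed at,
because the summing-matrix construction below is only unambiguous for
trees.

The summing matrix `S` (nodes × bottom nodes) has a 1 wherever a bottom
series contributes to a node. Node order is fixed once — root, then each
level left to right — and every matrix, tibble and CSV the package emits
follows it, so outputs are reproducible column for column. For the blood
tree `S` is 11 × 8 with an all-ones first row, two gender selector rows
and an identity block.

`check_coherence()` reports the largest absolute violation of
`y = S · bottom` per upper node. The default tolerance is `1e-6`
(floating-point sums on real-valued series); integer-valued series can be
checked at `0` because aggregation of integers in double precision is
exact. A practical note: published tables often round each node
independently, so a printed parent can differ from the sum of printed
children by a unit or two — checking such tables needs a tolerance of the
rounding width (2 units suffices for the published donation tables), and
the package documents this rather than forcing printed parents to match.

## Base forecasters

Each node's series is forecast independently; reconciliation is a separate
concern.

**Seasonal ARIMA.** `fit_auto_arima()` selects `(p,d,q)(P,D,Q)[12]` by:

* `D` (seasonal differencing, 0 or 1) from an STL seasonal-strength
  statistic, `max(0, 1 − Var(remainder)/Var(seasonal + remainder))`,
  with threshold 0.64;
* `d` by repeated KPSS level-stationarity decisions (Bartlett/Newey–West
  long-run variance with bandwidth `trunc(4·(n/100)^0.25)`, 5% critical
  value 0.463), capped at `max_d = 2`;
* `(p,q,P,Q)` by a stepwise AICc search over `p,q ≤ 3`, `P,Q ≤ 1`: four
  standard starting orders, then single-step and paired (same- and
  opposite-direction) neighbour moves until no neighbour improves.
  `stepwise = FALSE` searches the whole grid; on series with a clearly
  identified generating process the stepwise shortcut finds the same model
  as the exhaustive grid in at least 9 of 10 seeded simulations (a
  documented test), and like any local search it can stop one move short
  on ambiguous series.

Candidates are fitted with `stats::arima()` (CSS-ML); fits that fail, or
whose expanded AR/MA polynomial has a root within 0.001 of the unit
circle, are discarded. AICc adds the small-sample correction
`2k(k+1)/(n−k−1)` with `k` counting coefficients plus the innovation
variance. A constant series short-circuits to a degenerate `(0,0,0)` model
whose forecasts equal the mean — fitting noise to a flat line helps
nobody. A mean term is included only when `d + D = 0`, since differencing
already absorbs the level.

**Holt–Winters.** `fit_hw()` estimates the classical level/trend/seasonal
recursions with α, β, γ ∈ [0, 1]. Fitting delegates to
`stats::HoltWinters()` — bounded L-BFGS-B on the one-step squared-error
sum with decomposition-based initial states — which is deterministic and
needs no extra dependency; writing a bespoke optimiser would duplicate
base R without changing any result the package reports. The seasonal mode
is multiplicative or additive; `"auto"` fits both and keeps the smaller
AICc computed from the in-sample one-step errors with
`k = 3 + s + 2` parameters (smoothing constants plus initial states).
After fitting, the state is renormalised — multiplicative indices scaled
to mean 1 (additive: mean 0) with level and trend rescaled to compensate —
which leaves every forecast bit-identical while making the stored indices
interpretable as pure seasonal factors. Multiplicative mode requires
strictly positive data and refuses anything else.

Point forecasts only: the donation workflow compares methods by MAPE and
publishes point tables, so prediction intervals are out of scope.

## Reconciliation

Five methods, all returning coherent tibbles:

* **Bottom-up** keeps bottom base forecasts and aggregates upward. Exact
  and conservative at the leaves; inherits all leaf-level noise.
* **Top-down** splits the root's base forecast by a proportion vector:
  average historical proportions (`tdhp`), proportions of historical
  averages (`tdha`), or forecast proportions (`tdfp`) recomputed at every
  horizon step as the ancestor-chain product of base-forecast shares.
  Per-step recomputation is what makes the `tdfp` proportions sum to one
  at every step (the products telescope).
* **Optimal combination** (`oc`) regresses the full base-forecast vector
  on `S` by least squares; with identity weights this is the orthogonal
  projection `S(S'S)⁻¹S'`, so coherent inputs pass through unchanged and
  the map is idempotent. A diagonal-weights option is exposed for
  variance-style weighting; full error-covariance (MinT-style)
  reconciliation is deliberately out of scope.

Two definitional points deserved explicit decisions. The *proportions of
historical averages* scheme is implemented as (mean of child) / (mean of
root total), the standard reading of the name. The *average historical
proportions* denominator is ambiguous between the root total and the
parent's total; the default follows the explicit ratio-to-root formula,
and `within = "parent"` switches to the two-stage within-parent product
for users who prefer the recursive presentation. The two coincide for
two-level trees only in special cases, so the choice is surfaced as an
argument, not hidden.

Negative base forecasts are passed through reconciliation untouched:
clamping before the linear algebra would silently break the projection
and conservation identities. Rounding to whole units (and any clamping)
belongs to the export layer (`write_forecast_csv(round_units = TRUE)`),
off by default.

## Evaluation and selection

MAPE is `100 × mean(|y − ŷ| / y)`. Zero actuals raise an error instead of
being skipped — silently dropping months would bias method comparison.
`accuracy_table()` fits on the history window, forecasts the holdout span
(default: the final 12 months, matching the annual forecasting cadence),
and tabulates MAPE per node with an `Average` row; `select_best()` takes
the column with the smallest average, breaking exact ties by the declared
column order (methods bu, tdfp, tdha, tdhp, oc crossed with models ets,
arima) and saying so. Evaluation uses a single chronological split;
rolling-origin schemes can be built from `split_history()` but are not
the default claim. MAPEs are reported to 2 d.p. in displays while all
comparisons use unrounded values, so ties are not manufactured by
rounding.

## The synthetic registry

Real national-registry donation data are not redistributable, so the
package generates its own test bed. `simulate_donations()` draws each
bottom series as

```
base_total × gender share × group share × seasonal(month)
           × (1 + slope·(t−1)) × lognormal noise
```

with defaults chosen to emulate the reported registry structure: 144
months, gender shares M 0.54 / F 0.46, group shares O 0.54 / A 0.24 /
B 0.18 / AB 0.04, a neutral-month total of 5265 units (the sum of the
published per-group means), seasonal factors of 1.15 in April, August and
December (the named public/school-holiday peak months; the peak size is
not published, so +15% against a 0.95 baseline — mean exactly 1 — is the
package's choice), a mild decline of 0.05% per month, and mean-one
lognormal noise with σ = 0.08, which keeps counts positive, yields the
mild positive skew seen in registry summaries, and together with the
seasonal spread produces realistic coefficients of variation. Upper
levels are built by aggregation, so the output is coherent to machine
precision, and values stay real-valued inside the pipeline (integer
rounding only at export, for exactness of the coherence algebra).

What the generator does *not* emulate: serial correlation beyond the
trend/seasonal skeleton, donor-level behaviour, calendar effects other
than the three peak months, and regime changes — so green tests say the
machinery is correct on data with this structure, not that any particular
MAPE will transfer to a real registry. `inject_shock()` adds the one
regime change the workflow must face: a level drop of a configurable
magnitude (default 40%, the reported pandemic collapse) over a window,
optionally fading linearly, applied at the bottom level and re-aggregated
so coherence survives exactly.

## Problem sizes and determinism

The shipped tests exercise: the full 144-month, 11-node pipeline with
both base models and all five methods (a 12 × 10 accuracy table and a
60-month coherent forecast table); coherence of all methods across 100
randomly shaped seeded hierarchies; optimal combination against an
explicit pseudoinverse oracle on all toy trees with up to 4 bottom nodes,
50 random base-forecast vectors each; AR(1) parameter recovery over 20
seeded length-500 simulations; and 10 seeded shock replicates. Every
stochastic input is seeded; fitting itself consumes no randomness, so a
fixed configuration reproduces byte-identical outputs (the run log records
a configuration hash to make that checkable).

## Known limitations

* Strict balanced trees only — no grouped/crossed hierarchies.
* Point forecasts only; no prediction intervals or probabilistic
  reconciliation.
* Optimal combination offers identity or diagonal weights, not estimated
  error covariances.
* The automatic ARIMA search is a local (stepwise) search; the exhaustive
  flag exists for small grids.
* MAPE is the only headline accuracy measure, mirroring the donation
  forecasting practice the package serves.
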