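---
title: "Methods: hospital volume allocation with patient choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hospital volume allocation with patient choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volalloc)
```

This vignette documents the models, the tunable parameters, the numerical
choices and the deliberate design decisions behind `volalloc`, in the spirit
of a methods section: what the package assumes, why, and what its tests do
and do not demonstrate.

## The volume-outcome curve

The whole package rests on treating the volume-outcome association — the
empirical finding that hospitals performing more of a procedure have lower
risk-adjusted mortality for it — as a *deterministic* function `m(x)` of
annual volume. This is a strong simplification: in reality the association
is noisy, and the noise is largest exactly at low volumes. We accept it
because it is what makes allocation a well-posed optimisation problem; the
deviation band and the performance coefficient (below) reintroduce a
bounded amount of hospital-level heterogeneity.

National outcome programmes publish the shape of such curves but not
re-usable parametric forms, so the package provides two monotone-decreasing
families chosen to reproduce the qualitative shape (steep decline at low
volume, plateau at high volume):

* **exponential plateau** (default): `m(x) = m_floor + m_scale·exp(−decay·x)`;
* **shifted power law**: `m(x) = m_floor + m_scale·(x + 1)^(−decay)`.

Defaults `m_floor = 0.02`, `m_scale = 0.08`, `decay = 0.02` give 10%
mortality for a hospital doing no volume, 4.9% at the colon-surgery
guideline threshold of 50, and a 2% floor — rates of the order published
for colon-cancer surgery. Both forms are clamped to `[0, 1]` and validated
to be non-increasing.

The deviation band is modelled proportionally, `dev(x) = γ·m(x)` with
`dev_fraction` γ = 0.3 by default. The published construction of the band
(an average deviation of observed hospital rates from the curve) requires
the underlying hospital-level data, which are not public; a proportional
band is the simplest one-knob alternative and guarantees
`m(x) − dev(x) ≥ 0` for any γ ≤ 1, so a best-performing hospital can never
have negative mortality.

The **performance coefficient** concretises "compare the hospital's real
previous-year outcome with what the curve predicts" as the band-normalised
residual, clamped:

```
v = clamp( (observed − m(prev_volume)) / dev(prev_volume), −1, +1 )
```

with `v = 0` for hospitals without history and a sign-saturated value when
the band is zero. A hospital's objective contribution is then
`x·m(x) + x·v·dev(x)`: the literal second objective term, applied at
whatever volume the plan assigns.

## The strategic model and its exact solver

The decision maker minimises total expected deaths subject to:

* **volume bounds**: an open hospital performs between the guideline
  threshold `T` and its capacity; a closed one performs zero. Hospitals
  whose capacity cannot reach their lower bound are dropped up front.
* **hospitality windows**: each province's subtotal must lie in
  `[I_n − Σ_{n'≠n} δ_{n'}·I_{n'},  I_n + δ_n·I_n]`. The lower side of this
  printed inequality subtracts the *other* provinces' δ-weighted
  populations, which is looser than a literal own-outflow cap would be; the
  source formulation is implemented verbatim rather than second-guessed,
  and this note is the only place the discrepancy matters. With all δ = 0
  every province serves exactly its own demand.
* **conservation**: volumes sum to regional demand (universal coverage).
* an optional **budget** on `Σ_j c_j·x_j`.

Case-study-style flags reshape the bounds: capacity as twice the
previous-year volume (a ward can at most double in one planning step),
threshold halving outside the capital province, and a forced-open rule for
hospitals that exceeded `T` last year (it is more defensible to close wards
that demonstrably under-perform the guideline than ones that met it).

**Why dynamic programming, not MILP.** The objective is nonlinear in the
integer volume, but every hospital's admissible volume set
`{0} ∪ [lower, cap]` has at most a few hundred elements, so the objective
can be tabulated exactly per level. With an unbounded budget the optimum is
found by a two-level scalar DP: per province over cumulative volume, then
across provinces over provincial subtotals. This is exact, needs no
external solver, and runs in milliseconds at realistic sizes. With a finite
budget the DP states carry Pareto frontiers of (deaths, cost) pairs —
still exact, at a cost that grows with the number of non-dominated pairs,
which is why budgeted instances are intended for moderate sizes.
Infeasibility (demand above capacity, budget below any feasible plan's
cost) is reported as a status, never silently repaired.

**Tie-breaking.** Equal-objective optima are resolved deterministically to
the lexicographically smallest open-pattern and volume vector in
hospital-id order (reconstruction considers closure first, then ascending
volumes). The choice is arbitrary; determinism is what matters for
reproducibility and testing. Objective comparisons in reconstruction use a
`1e-9` absolute tolerance.

`verify_plan()` audits any plan against every constraint family and is used
by the tests to check the solver's own output; `brute_force_allocate()`
enumerates all feasible integer allocations on tiny instances and serves as
the independent optimality oracle.

## The patient model

Hospital choice is a conditional logit. Utilities are linear in distance
and in the *previous year's* volume — patients receive quality information
with a one-year lag, which also removes reverse causality between current
demand and current outcomes. Five chooser characteristics (standardised
age; binary sex, rurality, urgent admission, comorbidity) shift both
slopes. The characteristic encoding is this package's choice; sources in
this literature do not publish encodings.

**The probability convention.** Written literally, a share rule
`p_j = U_j / Σ U_j'` is ill-defined whenever utilities are non-positive —
and distance terms are negative by construction. Because the model family
is explicitly McFadden's conditional logit, the package defaults to the
softmax form `p_j = exp(U_j)/Σ exp(U_j')`, computed with log-sum-exp
stabilisation. The literal ratio is retained as an opt-in
`convention = "literal-ratio"` that refuses non-positive utilities rather
than guessing. This is the single most consequential interpretation in the
package. Probabilities are treated as continuous in `[0, 1]` throughout
(their sum over the choice set is 1; a realised choice is a draw, not a
degenerate probability).

Predicted hospital volumes are sums of probabilities, so they are
fractional and conserve the patient count exactly; the mortality of an
operational solution is evaluated at these fractional volumes, which the
objective accepts.

**Estimation.** The log-likelihood is concave in
(β_d, β_q, α_d, α_q) because utilities are linear in them; the fitter uses
damped Newton-Raphson from a zero start on internally standardised
features, with a `1e-8` relative gradient tolerance, and reports standard
errors from the observed information. Non-identified designs (only
singleton choice sets, constant characteristics) surface as
`converged = FALSE` with `NA` standard errors. No alternative-specific
constants or province fixed effects are included: nothing in the source
material indicates them, and adding them would change what β_q measures.

## The integrated planner

Phase 1 enumerates choice sets. Eligibility defaults to `capacity ≥ T`,
which is the reading consistent with the published per-province eligible
counts; the alternative prose reading (`prev_volume ≥ T`) is available via
`criterion = "prev_volume"`. The minimum number of open hospitals per
province is the shortest prefix of descending eligible capacities covering
provincial demand, with a floor of one facility even at zero demand (under
δ = 0 every province must serve its own patients somewhere). Per-province
subsets are filtered by total capacity against demand; regional sets are
the cross product, indexed lazily in lexicographic order so that large
enumerations need not be materialised.

Phase 2 evaluates each admissible set through the patient model (lagged
volumes as the quality signal, performance coefficients included in the
mortality — the hospitals offered to patients are exactly the ones whose
past performance the planner has vetted) and then applies the θ-rule.
Mortality values are grouped on their nearest integer — a fraction of an
expected death is not a meaningful planning distinction — and the groups at
the lowest, second-lowest and third-lowest values are kept, the latter two
only within θ% of the lowest. Consequently the guarantee
`integrated ≤ (1 + θ/100)·min` holds on rounded group values and can admit
up to half a death of rounding slack on raw values. Predicted volumes
below `T` at open hospitals are reported on every evaluation; an optional
strict mode disqualifies such sets instead, since the published account is
ambiguous about which behaviour was used.

Phase 3 skims the candidates. The *structural* criterion re-solves the
strategic model restricted to each candidate's open hospitals (forced open,
so patients face exactly that choice set) and picks the candidate whose
predicted volumes are closest in L1 to its own strategic optimum — the
configuration hospital managers can best prepare for. The *utility*
criterion has no published formula; it is operationalised here as the total
absolute gap between each open hospital's expected deaths at its lagged
volume and at its predicted volume, a proxy for the past-versus-experienced
performance gap that drives patient disappointment. A third published
criterion (workforce and university-hospital considerations) is qualitative
and out of scope.

## The synthetic-region generator

No discharge-level data are deposited anywhere for this problem class, so
the generator is a first-class module. It emulates the structural features
the methods need: provinces on a jittered grid in a ~220 km box (about the
extent of a north-Italian region), hospitals and patients scattered around
province centres, *right-skewed* hospital volumes (lognormal weights,
`sdlog = 0.6`, scaled to provincial demand), capacity at twice the previous
volume, and observed mortality within ±0.95 of the deviation band so that
generated performance coefficients span `(−1, 1)` without clipping. With
the default six hospitals per 270 patients (mean volume 45), the lognormal
skew puts roughly 30% of hospitals above the threshold of 50 — the
scattering pattern reported for real colon-surgery provision. Distances
are planar Euclidean; real road networks, waiting times and reputational
quality signals are deliberately *not* modelled, so passing tests show the
methods work under clean conditional-logit behaviour, not that the model
is correctly specified for any real population.

`piedmont_like_fixture()` is a fixed 8-province, 53-hospital,
1405-patient instance whose eligibility counts (5, 1, 1, 5, 2, 8, 2, 2 —
26 in total) and minimum-open counts (2, 1, 1, 2, 2, 4, 1, 1) match the
published provincial summary exactly at `T = 50`. Its capacities are
invented under those constraints (real capacities are not public), and the
1405 patients are split across provinces proportionally to hospital counts,
which is likewise an invention. The closed-form count of open/closed
combinations on this structure is 991,692 before capacity filtering; the
published *post*-filter count depends on the real capacities and is
therefore not reproducible.

All generation is a pure function of the seed: one seeded RNG stream,
isolated from the caller's RNG state.

## Problem sizes and verification

The test suite verifies each operation against an independent oracle at
sizes where the oracle is exact: brute-force enumeration for the allocator
(instances of up to 4 hospitals, demand ≤ 30, 50 seeded replicates),
explicit subset enumeration for the choice-set count (200 random
configurations with up to 8 eligible hospitals per province), a binomial
bound for choice simulation (10,000 draws), and parameter recovery within
3 standard errors on 5,000 simulated decisions from known coefficients.
The integrated pipeline's θ-band guarantees are asserted on a reduced
region (3 provinces, 6 hospitals, 300 patients), a size at which all 8
admissible choice sets are evaluated exhaustively in well under a second.
These sizes were chosen so that every check runs from scratch in seconds
while still exercising all code paths, including the budget-coupled
frontier solver.

## Known limitations

* Single procedure: no joint capacity across procedure lines.
* The volume-outcome relation is deterministic by design; its uncertainty
  (largest at low volume) is not propagated.
* The literal hospitality window (see above) is asymmetric in a way its
  textual description is not; we follow the formula.
* Budgeted regional solves are exact but not engineered for very large
  frontier states; the intended regime (and the one case studies use) is
  the unbudgeted decomposition.
* Patients are independent conditional-logit choosers informed only by
  lagged volume and distance; congestion, waiting lists and capacity
  feedback on choice are not modelled.
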