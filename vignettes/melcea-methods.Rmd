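---
title: "Methods: a Markov cohort cost-effectiveness model of adjuvant ipilimumab versus high-dose interferon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model of adjuvant ipilimumab versus high-dose interferon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melcea)
```

## The decision problem

Resected stage IIIB/IIIC/M1a/M1b melanoma carries a high relapse risk and is
treated with adjuvant systemic therapy. The E1609 trial showed that
ipilimumab 3 mg/kg improves overall survival and reduces toxicity compared
with high-dose interferon alfa-2b (HDI), the previous standard, but a course
of ipilimumab costs an order of magnitude more. `melcea` implements a
deterministic Markov cohort model that weighs that trade-off: it simulates a
cohort through four health states — stable disease on treatment, stable
disease off treatment, relapsed disease, and death — on monthly cycles over
a 10-year base-case horizon, attaches 2020-USD costs and health utilities to
state membership, and summarises the comparison as an incremental
cost-effectiveness ratio (ICER),

$$\mathrm{ICER} = \frac{C_{\text{ipi}} - C_{\text{HDI}}}{E_{\text{ipi}} - E_{\text{HDI}}}\quad [\$/\mathrm{QALY}],$$

judged against a willingness-to-pay threshold of \$100,000/QALY.

All patients enter in "stable disease on treatment". Permitted transitions
are: on-treatment → off-treatment (discontinuation or completing the
course), either stable state → relapse, any alive state → death. Relapse is
absorbing except for death: the model has no remission pathway.

## Cycle conventions, half-cycle correction and discounting

Occupancy is measured at cycle boundaries; transitions are modelled by one
row-stochastic 4×4 matrix per cycle with no intra-cycle event ordering
(death and relapse compete within a single matrix row). State membership for
cycle $m$ is the trapezoid $\tfrac12(\mathrm{occ}_m + \mathrm{occ}_{m+1})$,
the usual half-cycle correction; the summed alive membership therefore
equals the trapezoidal integral of the survival curve exactly.

Rewards are attached in two ways:

* **State-attached rewards** (disease-management costs, expected toxicity
  costs, caregiver costs, all QALYs) accrue over the whole cycle: they
  multiply the half-cycle membership and are discounted at the cycle
  midpoint, $(1+r)^{-(m+0.5)/12}$ with $r = 0.03$ per year.
* **Event-attached costs** accrue at a point in time: drug administrations,
  infusion fees and societal visit costs multiply the *start-of-cycle*
  on-treatment occupancy and are discounted at the cycle start; the one-time
  palliative/death cost (\$22,731) multiplies the newly dead mass of the
  cycle.

Whether the half-cycle correction should also apply to costs is not a
settled convention; we apply it to all state-attached rewards (costs and
QALYs alike) for internal consistency, and keep administration costs on
occupancy so that a cohort that completes treatment buys exactly the
protocol's dose count (8 ipilimumab infusions). The difference between
midpoint and boundary discounting is ~0.12% per reward stream.

## Treatment courses and dosing

Ipilimumab: four induction infusions every 3 weeks, then one maintenance
infusion every 12 weeks up to four more, capped at 60 weeks. On the monthly
grid this maps to administrations (2, 1, 1) over cycles 0–2 and single
infusions at cycles 5, 8, 11 and 14; remaining on-treatment mass is forced
off treatment at cycle 14. HDI: one induction month (IV daily × 5
days/week × 4 weeks) followed by subcutaneous maintenance to the 52-week
cap; HDI drug costs enter as the published per-cycle aggregates (induction
\$26,750, maintenance \$7,782), so cycles 1–12 are maintenance cycles.

The trial reports that 39.1% of ipilimumab patients discontinued before the
60-week cap, without a time profile. We spread it as a constant per-cycle
hazard $q$ with $1-(1-q)^{14} = 0.391$, i.e. $q \approx 0.0348$. HDI
discontinuation defaults to 0 (no aggregate figure is published) and is
configurable.

## Calibration to survival targets

The calibration input is a pair of monthly target curves per arm —
overall survival $S_{OS}(m)$ and progression-free survival $S_{PFS}(m)$
over the 78-month trial follow-up — plus a background life table. Each
cycle is decomposed with Kaplan-Meier decrements
$e(m) = 1 - S_{PFS}(m{+}1)/S_{PFS}(m)$ and
$d(m) = 1 - S_{OS}(m{+}1)/S_{OS}(m)$:

1. the stable-state death probability is the background life-table monthly
   probability $b(m)$ at the cohort's current age, capped at $d(m)$
   (melanoma deaths are routed through the relapse state, the conventional
   assumption when the split is unreported);
2. the relapse probability from both stable states is $r(m) = e(m) - b(m)$,
   so the progression-free decrement is reproduced exactly;
3. the relapse-state death probability is solved each cycle against the
   evolving occupancy so that total deaths match the OS decrement, and
   clipped to $[b(m), 1]$.

In the first cycles the relapse state is (nearly) empty, so no choice of
its death probability can deliver the OS decrement. When that happens the
solver caps the relapse-state probability at 1 and routes the residual
decrement through the stable-state death probability (reducing $r(m)$
accordingly), which keeps *both* curves exact; the forward pass is
therefore feasible for any valid targets with $S_{PFS} \le S_{OS}$, and
infeasibility (e.g. a discontinuation hazard that overflows a matrix row)
is raised as an error naming the cycle, never silently renormalised.
Round-tripping the calibrated schedule through the cohort engine reproduces
the targets to ~1e-15 in the test suite; the documented contract is 1e-8.

Background mortality during trial follow-up is included (capped) by
default; whether the original analysis layered it on top of the
trial-derived probabilities is unstated, so `include_background = FALSE`
is exposed.

### Extrapolation beyond follow-up

Beyond month 78 the trial is silent and two modes are offered. **Registry**
(base case): every survivor carries a melanoma-specific annual mortality
(life-table column, combined with background mortality), and relapse keeps
flowing at the last calibrated monthly rate — melanoma risk persists.
**Cure** (sensitivity): survivors at 78 months are cured; background
mortality only, no further relapse. OS is continuous at the junction under
both modes, and cure OS dominates registry OS thereafter. Applying the
registry melanoma mortality to *all* survivors (not only relapsed ones) is
what makes the cure assumption a genuine counterfactual for non-relapsed
survivors, and reproduces the published direction of the cure scenario
(a modestly lower ICER).

## Toxicity

The transition diagram has no toxicity state; grade 3–5 toxicity enters as
an expected value while on treatment: a per-cycle probability multiplies
the toxicity management cost (\$7,975 ipilimumab, \$1,625 HDI per toxic
cycle) and the annualised disutility toll (0.0134 / 0.0126 per year),
both applied over on-treatment membership. Grade-5 (fatal) toxicity is not
added to mortality separately — it is already inside the calibrated OS
deaths — avoiding double counting. `toxicity_incidence()` produces the
cumulative incidence curve used for validation against trial-scale
aggregates; it compounds the per-cycle probability on not-yet-toxic
on-treatment membership and plateaus when treatment ends.

## Parameters

The configuration (`default_config()`) mirrors the published parameter
table: costs in 2020 USD (ipilimumab \$54,850 per infusion; stable disease
\$1,066/cycle; progressed disease \$11,365/cycle; palliative one-time
\$22,731; infusion fees and societal add-ons per cycle), annual utilities
(0.83 on treatment, 0.96 off treatment, 0.52 relapsed, 0 dead), entry age
54, 3% annual discounting. Whether the stable-disease monitoring cost also
applies during on-treatment cycles is ambiguous in the source table; we
include it (`stable_cost_on_treatment = TRUE`) and expose the switch.
ICERs are rounded to the nearest \$100 at reporting only; internal math is
full precision, with raw values kept in `icer_raw.csv` next to each
report.

## The synthetic trial emulation

The real E1609 Kaplan-Meier curves exist only as published figures, so the
generator emulates them as two-interval piecewise-exponential curves:
HDI monthly hazards 0.007/0.004 (OS) and 0.022/0.008 (PFS) switching at
month 24, with the ipilimumab arm linked through a proportional hazard of
0.78, i.e. $S_{\text{ipi}}(m) = S_{\text{HDI}}(m)^{0.78}$ exactly. These
hazards were chosen once so that 5-year OS (~73% HDI) and the PFS–OS gap
sit in the range reported for resected stage III melanoma; they are
synthetic, as are the life-table fixture (annual all-cause mortality 0.005
at age 54 growing 9%/year; melanoma-specific 0.04/year beyond follow-up)
and the per-cycle toxicity probabilities (cumulative ~37%/~79% over the
ipilimumab/HDI course). The generator does **not** emulate Kaplan-Meier
step noise, censoring, or the true E1609 curve shapes — so passing tests
demonstrate that the machinery is correct under the stated conditions, not
that the headline dollar figures of the original analysis are recovered.
With these inputs the base-case ICER lands at \$380,500/QALY, the same
order as the original analysis, but only the structural and directional
properties are asserted.

## Sensitivity machinery

**One-way analysis** re-runs the full pipeline — recalibration included —
at each grid value of a single configuration key. The ICER is affine in
the ipilimumab per-infusion price (the trace does not depend on price),
which the suite verifies to within \$1 on 5-point grids and exploits only
as a cross-check on the \$1-tolerance bisection of `threshold_price()`.

**Scenarios** provide the published comparators: cure extrapolation,
40-year/lifetime horizons (lifetime runs to age 100), hazard ratio 0.56,
60% discontinuation, societal perspective (which adds patient time/salary,
parking-meals-travel and caregiver costs; HDI's much larger visit burden
lowers the incremental cost, hence the ICER).

**Probabilistic sensitivity analysis** draws every cost from a gamma
distribution, utilities/tolls/probabilities from betas, and the hazard
ratio from a lognormal, moment-matched as
$\text{shape} = (\mu/\sigma)^2,\ \text{scale} = \sigma^2/\mu$ and
$\nu = \mu(1-\mu)/\sigma^2 - 1,\ \alpha = \mu\nu,\ \beta = (1-\mu)\nu$.
Standard deviations come from published 95% CI half-widths divided by
1.96; parameters without a CI use 20% of the mean (configurable 10–40%).
The trial's hazard-ratio CI is not printed in the source; the shipped
0.61–0.99 interval is a placeholder, clearly non-published. Each iteration
re-derives the ipilimumab curves as $S_{\text{HDI}}^{h}$ with the drawn
$h$, recalibrates and re-runs both arms; a single vectorised pass over
cycles carries all iterations, so 100,000 iterations complete in well
under a minute on one core, and a degenerate run (all SDs zero)
reproduces the deterministic pipeline to machine precision. Entry age is
also drawn (gamma), which moves the background-mortality lookup per
iteration. Infeasible draws (an overflowing matrix row) are resampled and
counted, aborting if they exceed 1% of iterations; none occur under the
default configuration. The acceptability curve reports, per
willingness-to-pay value, the fraction of iterations in which each arm has
the larger net monetary benefit $\lambda E - C$; ties are credited to the
reference arm, so the two fractions always sum to 1.

## Numerical choices

* Transition matrices are validated to row sums within 1e-12, with
  renormalisation refused (errors, not silent fixes); the half-cycle and
  conservation invariants are tested at 1e-9.
* Bisection stops at \$1 on the ICER (or a relative bracket width of
  1e-9); thresholds are reported with the implied percent price reduction.
* Life-table lookups use the floor of the current fractional age, clamped
  to the tabulated range.
* Degenerate inputs: zero discounting gives unit factors; a zero SD gives
  point-mass draws; equal OS and PFS targets leave the relapse state
  empty; an empty override list reproduces the base case exactly.
* Report manifests include the configuration hash, seed and package
  version but deliberately no wall-clock timestamp, so identical inputs
  produce byte-identical report directories.

## Problem sizes

The shipped analyses use the 120-cycle (10-year) base horizon, 480 cycles
for the 40-year scenario, 100,000 PSA iterations for reported
acceptability values, and 1,500–10,000 iterations where the test suite
checks reproducibility and Monte-Carlo agreement between seeds.

## Limitations

* The synthetic curves are smooth proportional-hazards emulations; real
  trial curves would change every dollar figure (they are inputs, not
  outputs, of this package).
* Two strategies only; no cost-effectiveness frontier or expected value of
  perfect information.
* Toxicity is an expected-value adjustment, not an explicit state, so
  toxicity-driven discontinuation dynamics are not separable from the
  aggregate discontinuation hazard.
* The discontinuation hazard is constant over the course; front-loaded
  discontinuation would shift drug costs earlier.

## A worked base case

```{r base-case}
cfg <- default_config()
run_base_case(cfg)
scenario("societal", cfg)$icer
threshold_ipi_price(cfg)$pct_reduction
```
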