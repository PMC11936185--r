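---
title: "A partitioned-survival cost-effectiveness model for first-line immunochemotherapy in ES-SCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned-survival cost-effectiveness model for first-line immunochemotherapy in ES-SCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The model

`psmcea` implements a three-state partitioned-survival model (PSM) for
extensive-stage small cell lung cancer (ES-SCLC), comparing first-line
tislelizumab plus platinum/etoposide against platinum/etoposide alone from a
Chinese health-system perspective. The three states are progression-free
(PF), progressed-alive (PD) and dead. A PSM does not use transition
probabilities: state occupancy is read directly off the two survival curves,

$$PF(t) = \min\{S_{PFS}(t), S_{OS}(t)\},\qquad
  dead(t) = 1 - S_{OS}(t),\qquad
  PD(t) = S_{OS}(t) - PF(t).$$

The $\min$ clips extrapolated PFS curves that cross above OS (a standard
PSM repair), so occupancy always lies on the probability simplex; this is
property-tested on random parameter decks, including decks engineered to
cross.

Both arms' PFS and OS are log-logistic,

$$S(t) = \frac{1}{1 + \lambda t^{\gamma}},\qquad
  \text{median} = (1/\lambda)^{1/\gamma},$$

with shape $\gamma$ and rate-type scale $\lambda$ (units
months$^{-\gamma}$). Time is in **months**: under this convention the
implied medians (tislelizumab OS $\approx$ 16.5 months, chemotherapy PFS
$\approx$ 4.7 months) match the trial medians the parameters derive from.
The time unit is nonetheless configurable through the distribution objects.
Five comparator families (exponential, Weibull, Gompertz, gamma,
log-normal) support distribution selection.

## Curve fitting from digitized figures

Published Kaplan–Meier figures only give coordinates, so the fitting stage
works from `digitized_curve` objects (time, survival pairs). Reconstruction
(`interval_counts()`) converts survival drops into pseudo event counts for
an assumed closed cohort: with $n_i$ at risk entering interval $i$,

$$d_i = \operatorname{round}\!\left(n_i \frac{S_i - S_{i+1}}{S_i}\right),$$

no loss to follow-up before the last point, and the residual cohort
right-censored there. This is a simplified Guyot-style scheme: published
figures in this setting rarely come with usable numbers-at-risk rows, and
with administrative censoring only, the drop fractions identify the event
counts. The default assumed cohort size is 230 per arm (the approximate arm
size of the trial setting being emulated); it is a constructor argument.

`fit_parametric()` maximises the interval-censored multinomial likelihood

$$\ell(\theta) = \sum_i d_i \log\{S_\theta(t_i) - S_\theta(t_{i+1})\}
  + c \log S_\theta(t_m)$$

on the log-parameter scale (Nelder–Mead; Brent for the one-parameter
exponential), starting from regression linearisations of $S(t)$ (e.g.
$\log(1/S - 1)$ on $\log t$ for the log-logistic). Non-convergence is
flagged on the result, never silently replaced. `select_distribution()`
takes the minimum AIC, breaking ties by minimum BIC and then by parsimony,
and retains the full ranking table. BIC uses the assumed cohort size as its
effective $n$.

Numerical conventions worth knowing:

* interval probabilities are floored at $10^{-300}$ before logging, so a
  family that puts vanishing mass on an observed interval is penalised,
  not `NaN`-ed;
* a curve with fewer than 3 points, or no survival drop, is rejected up
  front (a 2-point "curve" cannot identify 2 parameters);
* digitized survival values are repaired to a non-increasing sequence by a
  running minimum before any counting, and the repair is flagged.

## The synthetic-data generator

Because no individual patient data exist for this comparison, the package
tests itself against its own generator: `simulate_event_times()` draws
event times by inverse-transform sampling (log-logistic quantile
$t = (u/((1-u)\lambda))^{1/\gamma}$), censors administratively at a fixed
horizon, `km_curve()` computes the product-limit estimate (via the
`survival` package), and `digitize_curve()` samples the step function on a
monthly grid (default 0–36 months, typical of figure extraction), adds
truncated Gaussian jitter (default sd 0.01 survival units, a plausible
manual-digitization error), and repairs monotonicity. The full loop
simulate → KM → digitize → fit recovers all four base-deck curve parameter
pairs within 5% relative error at $n = 5000$, which is the problem size the
test suite uses for recovery checks.

What the generator deliberately does **not** emulate: informative
(dropout-correlated) censoring, numbers-at-risk attrition before the
censoring horizon, and the pixel-quantisation artefacts of real graph
digitizers. Passing tests therefore show the estimator chain is correct
under clean administrative censoring, not that digitization of any
particular published figure is accurate.

## Cohort trace and accrual

The deterministic engine (`build_trace()`, `run_arm()`) evaluates occupancy
on a 21-day cycle grid over a 10-year horizon — 174 cycles, chosen because
5-year survival in ES-SCLC is under 5%, so the horizon is effectively
lifetime. Discounting is per-cycle compound at 5%/year with 365.25-day
years: cycle $k$ carries $(1+r)^{-21k/365.25}$.

Accrual rules (each a modelling decision the package makes explicitly,
since cost-timing conventions are rarely published):

* **Drug acquisition while progression-free.** The induction deck
  (etoposide 100 mg/m² × 3 days, platinum, plus 200 mg tislelizumab in
  that arm) is charged for the first 4 dosing cycles, the maintenance deck
  (tislelizumab only) afterwards, weighted by PF occupancy. Maintenance
  every 3 weeks until progression is the label schedule, and a cohort
  trace has no per-patient treatment clock; a `max_treatment_cycles` cap
  exists for scenario use.
* **Dosing.** Etoposide and cisplatin are body-surface-area doses
  (BSA 1.72 m²); carboplatin uses the Calvert formula
  $\text{dose} = \text{AUC} \times (\text{GFR} + 25)$ with AUC 5 and renal
  function 70 mL/min (the deck's "creatinine clearance" input is
  interpreted as GFR in mL/min; its published unit is inconsistent).
  The platinum choice is an expected cost with a 50/50
  cisplatin/carboplatin split. Per-mg pricing implies linear costing; no
  vial rounding. Body weight (60 kg) is carried in the profile but no
  listed dosing rule consumes it.
* **Monitoring while PF** (follow-up, labs, abdominal CT per cycle) and
  **best supportive care while PD** (per cycle, standing in for
  post-second-progression care since the model has a single PD state).
* **Subsequent systemic therapy** is a one-time cost at progression:
  uptake (60% / 74% by arm) × the per-cycle increase of $1 - S_{PFS}$,
  floored at zero. Using progression events rather than PD occupancy
  matches uptake percentages quoted as shares of randomized patients.
* **Adverse events** (grade ≥ 3, incidence > 1%: anaemia, leukopenia,
  neutropenia, thrombocytopenia) are charged once per patient at entry —
  incidence-weighted management costs, and disutility applied for one
  dosing cycle's duration. Event timing and duration are not published;
  one-time-at-entry is the conservative simple choice and the sensitivity
  machinery varies all of its inputs.

QALYs accrue as $\sum_k (PF_k u_{PF} + PD_k u_{PD})\,\Delta t\, d_k$ with
$u_{PF} = 0.67$, $u_{PD} = 0.47$, $\Delta t$ the cycle length in years,
minus the one-time AE loss.

**Half-cycle handling.** By default occupancy is evaluated at cycle starts
(simple accrual, matching the common decision-tree-software default), with
`settings$half_cycle = TRUE` switching to midpoint evaluation. The
midpoint scheme is second-order accurate — halving the cycle length moves
totals by well under 1% — while cycle-start accrual converges at first
order (halving the step shifts the steeper chemotherapy-arm QALY total by
about 1.2%). Per-cycle cost inputs are defined per 21-day *dosing* cycle
(`settings$cost_cycle_days`) and rescaled if the model step is changed, so
the cycle length remains a pure discretization choice.

## Economics

`incremental_analysis()` computes $\Delta C$, $\Delta E$, the ICER
$\Delta C / \Delta E$, and net monetary benefit
$NMB = \lambda_{WTP}\Delta E - \Delta C$ at the willingness-to-pay
threshold of \$39,855.79 per QALY (three times 2023 Chinese GDP per
capita).
Dominance quadrants are labelled (`"dominant"`, `"dominated"`) instead of
reporting sign-meaningless ratios, $\Delta E = 0$ yields an undefined-ICER
label rather than a division error, and the decision is
`cost_effective == (NMB >= 0)` in every quadrant — an identity the suite
property-tests on random decks.

## Sensitivity analyses

**One-way (tornado).** Every varied parameter is set to its low and high
bound with all else at base and the full model rerun; rows are sorted by
ICER swing. Ranges are the published minima/maxima where printed (these
are ±25% bands for costs and utilities; 0.04–0.06 for the discount rate)
and constructed ±25% bands where none are printed (the AE incidences); the
cisplatin fraction is varied over 0.25–0.75. The parameter set is every
cost, utility, disutility, incidence, uptake, the BSA, the discount rate
and the platinum mix — `param_specs()` is the authoritative list.

**Probabilistic.** `run_psa()` draws every parameter independently per
iteration — gamma for costs, beta for probabilities/utilities — matched by
method of moments to mean = base and sd = (high − low)/3.92, i.e. the
range read as a 95% interval. This spread convention is the standard one
when only ranges are published; it is a package choice, recorded in run
manifests. Two wrinkles:

* a "beta" parameter whose base lies outside $(0,1)$ (the body surface
  area) is drawn as a scaled beta on $[\text{low}, \text{high}]$;
* an infeasible beta moment match (sd² ≥ m(1−m)) falls back to a shrunken
  sd with a warning.

Survival parameters $(\gamma, \lambda)$ are **fixed** in the PSA: no
distribution is published for them, and inventing one would change the
question the PSA answers. The draw matrix is generated up front from one
seed, so results are bit-reproducible and a failed draw (recorded and
excluded, never resampled) cannot shift later iterations.
`ceac()` summarises the same draws as an acceptability curve; at the deck
WTP it equals the PSA's acceptability fraction exactly.

The reference PSA size is 10,000 iterations (about half a minute on one
core); the test suite uses the full size for the acceptance checks and
smaller runs (hundreds of draws) for structural properties.

## Known limitations

* Cohort model: no individual treatment clocks, so "treatment until
  progression" is approximated by PF-weighted drug cost; no time-varying
  utilities; no background-mortality floor under the extrapolation.
* The single PD state bundles all post-progression lines; BSC pricing
  stands in for third-line care.
* Grade 1–2 adverse events, administration/infusion fees and imaging in
  PD are excluded (not in the input set).
* Published base-case totals for this comparison are not exactly
  recoverable from the published inputs under any accrual convention we
  examined; the package reports what the stated inputs imply, and the
  one-way and probabilistic machinery quantifies how far the decision is
  from the threshold.

## A minimal session

```{r}
res <- run_cea(base_deck())
res
```

```{r, eval = FALSE}
torn <- one_way_sensitivity(base_deck())
head(torn)
psa <- run_psa(base_deck(), iterations = 10000, seed = 1)
psa
run_all(base_deck(), seed = 1, out_dir = "cea-outputs")
```
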