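---
title: "Modeling the health economics of PRS-guided CAD prevention in children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the health economics of PRS-guided CAD prevention in children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prscea)
```

## The problem

Coronary artery disease (CAD) begins in childhood, but candidates for
primordial prevention are hard to identify early. A polygenic risk score
(PRS) is available from birth and stable over life, so it can stratify
children by lifetime CAD risk decades before clinical disease. `prscea`
implements a decision-analytic evaluation of a PRS-guided prevention
program: a hypothetical cohort of 10,000 children is genotyped at age 10,
the top 20% of the PRS distribution ($n = 2000$) receives intensive
lifestyle intervention, and the top 2% ($n = 200$) additionally receives
statin therapy, against a standard-care comparator.

The package has four computational layers, each with a tabular (tibble)
surface:

1. a **parameter registry** (`parameter_set()`, `default_parameters()`)
   carrying every model input with its units and a per-parameter
   probability distribution for uncertainty analysis;
2. a **Markov cohort engine** (`build_transition_table()`,
   `run_cohort_trace()`, `summarize_trace()`) that propagates the cohort
   through four mutually exclusive health states in annual cycles;
3. a **societal cost-benefit ledger** (`benefit_ledger()`) that turns
   prevented events into monetized benefits, ROI, and an ICER;
4. a **probabilistic sensitivity analysis** (`run_psa()`, `ceac_curve()`)
   propagating parameter uncertainty by Monte Carlo, with country-level
   localization (`localize_ledger()`) on top.

## The cohort model

The Markov model has four states: alive and event-free, alive post
nonfatal cardiovascular event (MI or stroke), cardiovascular death, and
non-cardiovascular death. Cycles are annual from entry at age 10 to age 80
(70 cycles); both death states are absorbing and there are no recurrent
events.

Cardiovascular events begin at age 40. The 10-year incidence of 12% in the
top PRS quintile (applied equally to CAD and stroke, which share all
parameters for lack of harmonized stroke-specific inputs) is converted to a
constant annual hazard by

$$p_{\text{annual}} = 1 - (1 - p_{\text{10y}})^{1/10},$$

so that compounding over ten cycles recovers the cumulative risk exactly
(`annualize_risk()`, tested to $10^{-12}$). CAD and stroke hazards are
combined as independent competing risks,
$p_\text{event} = 1-(1-p_\text{CAD})(1-p_\text{stroke})$. A uniform 30%
relative risk reduction multiplies the event hazards of intervened strata;
20% of events are acutely fatal.

Numerical conventions, chosen where the published description is silent:

* **Cycle convention.** Transitions occur at cycle end; rewards are
  credited to the state occupied during the cycle, with no half-cycle
  correction. The convention is simple, exactly mass-conserving, and makes
  the zero-mortality limit come out in whole years (70 years lived from
  age 10 to 80).
* **Non-CV mortality.** Zero before age 40 (none is modeled there), and
  zero by default afterwards so that base-case traces are self-contained;
  `build_transition_table(background_mortality = ...)` accepts a scalar or
  a per-age life-table column when competing mortality is wanted.
* **Bottom 80% stratum.** No incidence is published for it; its event
  hazard defaults to zero. All economic results derive from the high-risk
  strata, so this choice does not touch the ledger.
* **Post-event utility.** The post-event state keeps its age-band utility
  by default (a configurable multiplier exists), because per-case QALY
  impacts enter the economic ledger through fixed per-case quantities
  (13.3 QALYs gained per prevented case) rather than through a state
  utility decrement.

Utilities are age-banded: 0.95 (ages 10–40), 0.92 (40–60), 0.85 (over 60),
each a per-year weight in [0, 1]. QALYs are discounted at the fixed 3%
annual rate, first cycle undiscounted.

The three clinical scenario profiles shipped by `scenario_fixtures()`
(low PRS; high PRS without prevention; high PRS with prevention) are
illustrative inputs, not engine outputs: their absolute life-expectancy and
QALY levels are not derivable from the utility schedule above under any
simple cycle convention, and they are documented as illustrative by their
source. The package therefore asserts only their *differences* — 7 years of
life expectancy and 13.3 QALYs restored by prevention, and the fivefold
fatal-MI gradient between risk strata.

```{r scenarios}
sc <- scenario_fixtures()
project_scenario_delta(sc[sc$name == "high_prs_no_prevention", ],
                       sc[sc$name == "high_prs_with_prevention", ])
```

## The cost-benefit ledger

The deterministic ledger reproduces a societal-perspective accounting per
10,000 children. With $n_\text{high} = 2000$, 10-year incidence $p = 0.12$,
and relative risk reduction $r = 0.30$:

$$\text{events prevented} = n_\text{high} \, p \, r = 72, \qquad
  \text{ARR} = p\,r = 3.6\%.$$

Benefit lines: direct healthcare savings (events × $421,487 lifetime cost
per case), QALY value (events × 13.3 QALYs × $100,000), productivity
(events × $200,000), screening-stratification savings, and a 15%
co-benefit multiplier applied to the sum of the first four lines.

* **Rounding convention.** Each line is rounded to the printed precision
  ($0.1M; QALYs to an integer) *before* summation, so the reported total
  equals the sum of its reported lines; unrounded values are kept in
  `_raw` fields.
* **Screening reconstruction.** The underlying screening schedule is not
  published in full; the unique simple parameterization that reproduces
  both printed totals simultaneously is $250 per screen to age 70, with
  uniform screening starting at 40 for everyone ($75M undiscounted) versus
  stratified starts at 40 (top 20%) and 50 (rest) ($55M), saving $20M.
* **Program cost.** One-time testing ($400 × 10,000 = $4.0M) plus the
  discounted present value of statin therapy for the treated 200 children.
  The published PV is $970,000; an exact ordinary annuity at 3% over 30
  years gives $200 \times 250 \times 19.6004 = \$980{,}022$ (a 1.1%
  discrepancy whose derivation is unpublished). The default
  `medication_pv = "printed"` carries the published value through its
  implied annuity factor (19.4 per $1 of annual cost), which keeps headline
  reproduction exact while still letting sampled statin costs propagate in
  the PSA; `"annuity"` selects the computed annuity.
* **ICER numerator.** Gross program cost over QALYs gained
  ($4.97M / 958 = \$5188$/QALY). Netting downstream savings would make the
  intervention dominant and the published ratio undefined, so gross cost is
  the only convention consistent with the printed value.
* **Break-even.** Reported both ways: per-case benefit from the full ledger
  (total benefit / events, giving 2 cases) and from the direct per-case
  bundle (lifetime cost + QALY value + productivity, giving 3) — hence
  "2–3 cases".
* **Adjusted NPV/ROI.** Benefits are compounded jointly by 5% medical
  inflation and 3% discounting over 30 years:
  $NPV = B \times (1.05/1.03)^{30}$.

```{r ledger}
led <- benefit_ledger(default_parameters())
led
```

## Parameter uncertainty

Each parameter carries one of five distribution kinds, following standard
PSA practice: beta for proportions (incidences, case fatality), gamma for
costs (parameterized by mean and coefficient of variation:
shape $= 1/cv^2$, scale $= \bar{x}\,cv^2$), normal for utilities and QALY
losses, lognormal for the relative risk, and fixed for structural constants
(discount rate, cohort size, valuation constants).

Distribution choices that required a decision:

* **Relative risk.** The RR is lognormal with median 0.70 and
  $\sigma = \ln(0.80/0.60)/(2 \times 1.96)$ from the stated 95% interval
  (0.60–0.80). The printed interval is not multiplicatively symmetric about
  0.70, so the distribution is anchored on the median. The *parameter*
  drawn is the risk reduction $1 - RR$, whose median is then exactly the
  base value 0.30.
* **Truncation.** Normal utility draws are truncated to [0, 1] and QALY
  losses to [0, ∞) by resampling until valid rather than clipping, which
  preserves the distribution's shape near the boundary; resampling consumes
  extra RNG variates, which is why seeds are only portable across identical
  parameter sets.
* **Adherence.** Listed among beta-distributed probability parameters by
  the source but given no value; it is folded into the single uniform 30%
  relative risk reduction rather than invented as a separate parameter.
* **What varies per draw.** All non-fixed entries: incidences, RR, costs,
  fatality, utilities, QALY losses. The per-case QALY gain (13.3), the
  valuation constants, and the screening schedule stay fixed, consistent
  with the published QALY interval being ≈ 13.3 × the events interval.

`run_psa()` seeds one RNG stream and draws parameters in fixed row order,
so a `(parameters, n, seed)` triple reproduces the result bit for bit; with
every distribution collapsed to a point mass the PSA equals the
deterministic ledger exactly (a tested identity). The cost-effectiveness
acceptability curve evaluates, on a $0–$100,000 grid in $1,000 steps
(covering the conventional $50,000–$100,000 willingness-to-pay range), the
fraction of draws with positive net monetary benefit
$\text{WTP} \times \Delta QALY - \Delta C$. Intervals are empirical
2.5/97.5 percentiles, not normal approximations. The published events
interval (58–86) is somewhat narrower than Beta(120, 880) × lognormal-RR
propagation produces, and the published RR sampling scheme is not fully
specified; the package documents its own propagation and compares the
published intervals only in magnitude.

```{r psa}
psa <- run_psa(default_parameters(), n = 200, seed = 1)
glance(psa)
```

## Country localization

Country-level ICER and ROI use two positive factors per country: a
`cost_factor` scaling program costs and a `benefit_factor` scaling
monetized benefits,

$$\text{ICER}_c = \frac{f^{\text{cost}}_c \, C}{\Delta QALY}, \qquad
  \text{ROI}_c = 100 \cdot
  \frac{f^{\text{ben}}_c B - f^{\text{cost}}_c C}{f^{\text{cost}}_c C}.$$

The published country table prints results but not factors; the shipped
`country_profiles()` table is a back-derived reconstruction (each country's
ICER divided by the USA ICER; the benefit factor solved from its ROI) and
is labelled as such. Whether the original analysis scaled QALYs, QALY
price, or both is unknowable from the results alone; the two-factor form
reproduces every published cell and is adopted as the reconstruction.

```{r country}
localize_ledger(led)
```

## What the packaged inputs do and do not emulate

The packaged base case *is* the study condition set: all inputs are
published point values and distributions, and there is no patient-level
data anywhere — the analysis is cohort-level and parameter-driven, so the
"synthetic data" of this package is its parameter fixtures
(`default_parameters()`, `scenario_fixtures()`, `country_profiles()`) plus
`perturbed_parameters()`, which applies seeded multiplicative jitter
(default ±10%) to non-fixed base values while re-centering each
distribution so every invariant still holds; property tests sweep it over
many seeds. Passing tests therefore demonstrate arithmetic fidelity to the
published model under its own assumptions — not calibration to any real
cohort: real pediatric PRS-guided prevention data do not yet exist, the
incidence and treatment-effect inputs are adult-derived, adherence is
optimistic, and non-CAD mortality before 40 is ignored.

Problem sizes used by the test-suite and reproduction script — 70-cycle
traces, 1000-draw PSA (the published count), 10,000-draw law-of-large-
numbers checks — were chosen as the smallest sizes at which the respective
statistical assertions are stable.

## Known limitations

* No recurrent events, recurrence costs, or post-event utility decrement
  in the base case; modeling them would change (likely increase) projected
  benefit.
* Stroke duplicates every CAD parameter by assumption.
* The bottom-80% stratum carries no event hazard, so the engine understates
  total population burden (irrelevant to incremental results).
* The Markov engine and the economic ledger are linked by design through
  per-case constants, mirroring the published arithmetic, rather than by
  feeding engine QALY deltas into the ledger.
* Country factors are reconstructions, not published inputs.
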