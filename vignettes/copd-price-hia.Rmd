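---
title: "Projecting COPD burden under tobacco price increases: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting COPD burden under tobacco price increases: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdhia)
```

## The question the model answers

Raising the price of tobacco is one of the most effective population-level
levers against smoking, the dominant risk factor for chronic obstructive
pulmonary disease (COPD). `copdhia` implements a health impact assessment
(HIA) for this lever: a deterministic, discrete-time Markov multi-state
projection of a national population in which a one-time price increase
shifts smoking behaviour, and the downstream consequences for COPD burden,
mortality and life expectancy are followed for decades. A reference
("business-as-usual") projection with no price change is always run
alongside, and every result is a contrast against it.

## State space and annual cycle

Each person occupies a joint state
(sex, age $a \in \{0,\dots,95\}$, smoking state $s \in$ {never, current,
former}, COPD state $c \in$ {no, yes}). The projection is an expected-value
cohort-component model: cell counts are real numbers, not simulated
individuals, so runs are exactly reproducible and regression-testable.

Within each annual cycle the engine applies, in a fixed order:

1. **Smoking transitions** — initiation $\iota(a)$ (never $\to$ current,
   possible from age 11), cessation $\kappa(a)$ (current $\to$ former, from
   age 16) and restart $\rho(a)$ (former $\to$ current, from age 22);
2. **COPD incidence** — among the COPD-free aged 40+, at state-specific
   probabilities $i_s(a)$ (using post-transition smoking states); COPD is
   absorbing, with no remission;
3. **Mortality** — at state-specific probabilities $m_s(a)$, identical for
   the COPD yes/no strata;
4. **Ageing** — everyone advances one year; survivors of age 95 leave the
   modelled range; projected newborns enter at age 0 as never-smokers
   without COPD.

The cycle order is a modelling convention: published descriptions of
comparable HIA tools do not pin it down, and alternative orders differ only
at second order in the annual rates. We fix and document it because the
dense-matrix test oracle must reproduce it exactly.

Smoking transitions apply equally to COPD and COPD-free individuals
(smoking behaviour is taken as independent of disease status), and the
initial COPD occupancy at year 0 is split across smoking states in
proportion to the smoking prevalences — no coupling at initialisation is
assumed because none is specified for the data this emulates.

## From population rates to state-specific rates

Inputs provide *population-average* COPD incidence $I(a,\mathrm{sex})$ and
all-cause mortality $M(a,\mathrm{sex})$, plus relative risks of smoking:
on COPD by sex and age band (within the published range 8.13–19.83), and on
total mortality by sex (2.07 for males, 1.74 for females). State-specific
rates come from the standard attributable-risk decomposition,

$$ i_\text{never} = \frac{I}{p_n + p_f \cdot RR_f + p_c \cdot RR_c},
\qquad i_\text{former} = RR_f \, i_\text{never}, \qquad
i_\text{current} = RR_c \, i_\text{never}, $$

so that the smoking-distribution-weighted average reproduces the input rate
exactly (`build_state_rates()` is tested to 1e-12). Two conventions matter:

* Relative risks are interpreted as **current-vs-never** (and
  former-vs-never) contrasts. Former-smoker RRs are rarely published
  alongside; where the user does not supply them the synthetic generator
  defaults to $1 + 0.5\,(RR - 1)$, placing former smokers halfway between
  never and current smokers — an explicit, visible choice, not a hidden one.
* The state-specific rates are **frozen from the reference bundle** and
  reused unchanged in intervention runs. An intervention therefore acts
  purely through smoking-state occupancy, which is the stated mechanism of
  a price rise; re-deriving rates from intervention prevalences would
  double-count the effect.

COPD confers no mortality beyond the smoking pathway in this
implementation; the life-expectancy gains of an intervention arise from
reduced overall mortality via reduced smoking. One visible consequence is
that simulated COPD prevalence drifts upward over long horizons (absorbing
disease, no excess mortality), so prevalence *contrasts* between scenarios
are meaningful while the level itself rises above its ~1% starting value.

## The intervention: price elasticities

The price elasticity of demand $\varepsilon$ (percentage change in
consumption per 1% price increase) is age-banded: $-1.5$ below 19, $-0.75$
at 19–29, $-0.5$ from 30 (`default_schedule()`); a uniform $-0.5$
(`sensitivity_schedule()`) supports sensitivity analyses. For a one-time
price increase of $P$% the multiplier $f = |\varepsilon(a)|\,P/100$ is
applied **relatively**, once, at the beginning of the simulation:

* never- and former-smoking prevalences are multiplied by $1 + f$;
* current smoking is recomputed as the complement,
  $p_c' = 1 - p_n' - p_f'$;
* initiation and restart probabilities are multiplied by $1 - f$, cessation
  by $1 + f$, clamped to $[0, 1]$.

The relative reading follows directly from the definition of elasticity as
a percentage change. For large $f$ the scaled never + former prevalences
can exceed 1; they are then rescaled proportionally (preserving the
never:former ratio) and current smoking is set to 0. This cap is this
package's documented convention — it matters only for combinations such as
$|\varepsilon| = 1.5$ with price increases near 50%.

## Life expectancy

`cohort_life_expectancy()` follows a closed single-sex cohort of baseline
age $a_0$ (no newborns, no other ages) through $95 - a_0$ annual cycles.
Person-years use a half-cycle correction (deaths within a cycle contribute
half a year), with COPD status for weighting taken as the within-cycle
(post-transition, post-incidence) status. Survivors reaching age 95 receive
a terminal tail of $1 / M(95, \mathrm{sex})$ further expected years — the
constant-hazard remaining lifetime at the top modelled age. Without that
tail, the life expectancy of a 20-year-old truncates visibly below
plausible national values (~80 years); with it, the zero-mortality limit
still returns exactly 95 years, which the tests pin down. Three modes share
one loop and differ only in the weight given to COPD person-years: 1
(overall), 0 (COPD-free), $1 - DW$ (COPD-disability-adjusted).

The disability weight $DW$ has no published value in the analyses this
package emulates; it is a required configuration parameter, default 0.2, on
the scale of published COPD severity weights. Gains reported by `le_gain()`
are differences against the 0% reference and are exactly zero for the
reference itself.

## The synthetic-data generator

No national input datasets ship with the package; `generate_bundle()`
produces country-like bundles with the structure the analysis assumes:

* **Demographics** — a stationary-population pyramid $l(a)\,(1+r)^{-a}$
  from the bundle's own survival curve, with birth-cohort growth rate $r$
  (`pyramid_shape`, negative = ageing population) and 2% log-normal noise;
  newborn projections continue the trend.
* **Smoking** — uptake concentrated at ages 11–20 (a normal-CDF ramp
  centred on `initiation_peak_age` = 16) plus a small residual component
  through mid-adulthood; the fraction of ever-smokers who have quit ramps
  in from 16 and rises steeply around age 70. Curves are rescaled so
  current smoking peaks at `peak_current_prevalence` (default 0.20;
  males +25%, females −25%) in middle age, where national surveys place it.
* **Consistency** — initiation and cessation probabilities are *derived*
  from the prevalence curves through the closed cohort recursion (with an
  assumed exponentially declining relapse curve), so prevalences are the
  stationary age profile of the transition rates, exactly up to
  smoking-differential mortality. Reference-scenario prevalence drift then
  reflects demography, not internally contradictory inputs; a test bounds
  the 40-year adult-profile drift at two percentage points.
* **COPD and mortality** — incidence and prevalence are zero before 40 and
  exponential in age (defaults chosen to give overall prevalence near 1%
  and incidence near 1.5 per 1000 person-years, the published order of
  magnitude); mortality is Gompertz with a small infant component, giving
  life expectancy at birth of about 79 (males) and 86 (females) years.

Defaults give an overall current-smoking prevalence of ~13%, inside the
10.6–17.5% range of the European countries this emulates. Three presets
(`synthetic_profile()`: `"italy-like"`, `"england-like"`, `"sweden-like"`)
contrast a populous, ageing, high-smoking southern country with smaller and
lower-smoking northern ones; they are illustrative, not calibrated.

What the generator does **not** emulate: birth-cohort effects in smoking
uptake, migration, smoking intensity, and the disease-specific excess
mortality a calibrated national dataset would embed. Tests passing on
synthetic bundles therefore demonstrate correctness of the machinery and
the directional behaviour of interventions, not agreement with any
particular country's published trajectories — reproducing those would
require the original national inputs.

## Numerical choices and degenerate inputs

* Ages are integer single years 0–95; age-banded inputs (relative risks)
  are expanded at load time, the same value applied to all ages in a band.
* Transition inputs are annual probabilities in $[0,1]$, not instantaneous
  rates; prevalence files store proportions, converted to percent only at
  reporting time.
* Bundle CSVs serialise doubles as `%.17g`, so a write/load round trip is
  exact and repeated writes are byte-identical.
* Smoking proportions must sum to 1 within 1e-9 at every (sex, age);
  `validate_bundle()` reports every violation with its table, sex and age.
* An empty population cell yields zero state-specific rates (not NaN); an
  empty population at reporting time is an error, not a silent zero.
* COPD incidence rates use mid-year person-years (start-of-year alive minus
  half the year's deaths) and are undefined for the final simulated year,
  matching the convention of the tool family this emulates.
* A 0% price (or all-zero elasticity) returns the input bundle *bit
  identically*, so reference comparisons are exact, not merely close.

## Verification strategy and problem sizes

The test suite cross-checks the engine against an independently constructed
dense one-year transition matrix over the full
(age × smoking × COPD) + death state space, powered over 40 years
(agreement to 1e-10); enforces population bookkeeping
($\mathrm{alive}(t+1,a+1) = \mathrm{alive}(t,a) - \mathrm{deaths}(t,a)$) and
smoking-share normalisation across 100 random synthetic bundles; verifies
monotonicity of smoking reductions, cases saved and life-expectancy gains
across prices 0–50%; and pins limiting cases (zero price, zero elasticity,
unit relative risks, zero mortality) to exact reference behaviour. Default
problem sizes — 1e6 (tests) and 1e5 (property sweeps) persons, 40-year
horizon — keep the whole suite around a minute on one core while exercising
every code path at full age resolution.

## Known limitations

* No COPD excess mortality by default (an explicit hook in the design);
  long-horizon prevalence levels drift upward as a result.
* One-time price increases only; annual repeated rises, income dynamics,
  illicit trade and cross-border purchasing are out of scope.
* Elasticities are shared across sexes and regions; real responsiveness
  varies with income and socioeconomic position.
* The terminal 1/M(95) tail assumes a constant hazard beyond the top
  modelled age; it is a small, documented approximation affecting all
  scenarios alike, and differences between scenarios are insensitive to it.
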