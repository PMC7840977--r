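# copdhia

Health impact assessment (HIA) of tobacco price increases on the burden of
chronic obstructive pulmonary disease (COPD).

`copdhia` is for epidemiologists and public-health modellers who want to ask:
*if the price of tobacco rose once by X%, what would happen to smoking
prevalence, COPD incidence and life expectancy over the next decades?* It
implements a deterministic, discrete-time Markov multi-state projection of a
whole national population, a tobacco-price intervention module driven by
age-banded price elasticities of demand, aggregation into the standard HIA
outcome set, and a synthetic-data generator so the entire pipeline runs and
is testable without any external data.

## The model in brief

The population is distributed over joint states
(sex, age 0–95, smoking ∈ {never, current, former}, COPD ∈ {no, yes}) and
advanced in annual cycles: smoking transitions (initiation ι(a), cessation
κ(a), restart ρ(a), with uptake possible from age 11, quitting from 16,
relapse from 22), COPD incidence from age 40 (absorbing), mortality, then
ageing with newborn entry.

Population-average COPD incidence *I(a)* and all-cause mortality *M(a)* are
split into smoking-state-specific rates with relative risks *RR* via the
attributable-risk decomposition

```
i_never = I / (p_never + p_former·RR_former + p_current·RR_current)
i_former = RR_former · i_never        i_current = RR_current · i_never
```

so the weighted average reproduces the inputs exactly. These rates are
frozen from the reference scenario; a price increase of *P*% acts only by
shifting smoking: never- and former-smoking prevalences (and cessation) are
scaled by `1 + |ε(a)|·P/100`, current smoking becomes the complement, and
initiation/restart scale by `1 − |ε(a)|·P/100`, with the elasticity schedule
ε(a) = −1.5 (ages 11–18), −0.75 (19–29), −0.5 (30+) by default and a uniform
−0.5 for sensitivity analyses.

Outcomes: smoking-state prevalences, COPD prevalence (%) and incidence
(cases/1000 person-years), cumulative incident cases saved vs the reference,
cohort life expectancy (overall, COPD-free, COPD-disability-adjusted; with
half-cycle correction and a 1/M(95) terminal tail) and cost savings from
prevented cases. See the methods vignette
(`vignettes/copd-price-hia.Rmd`) for every modelling convention and its
rationale.

## Worked example

```r
library(copdhia)

bundle <- generate_bundle(synthetic_params(seed = 1))
bundle
#> <copd_bundle>
#>   region: north   base year: 2018   horizon: 40 years
#>   population: 1,000,000 persons (192 sex x age cells)
#>   overall current smoking: 13.1%   overall COPD prevalence: 0.87%

cmp <- simulate_scenarios(bundle, prices = c(5, 10, 20))
cases_saved_table(cmp)
#> # A tibble: 4 × 3
#>   scenario  price_increase_percent cases_saved
#>   <chr>                      <dbl>       <dbl>
#> 1 reference                      0          0
#> 2 price+5%                       5       2651.
#> 3 price+10%                     10       5172.
#> 4 price+20%                     20       9622.

le_gain(bundle, price_scenario(20), age = 20, sex = "male", mode = "overall")
#> [1] 0.752625

cost_savings(124364, annual_cost = 5700, duration = 10)
#> [1] 7088748000
```

Read: on a synthetic 1-million-person country smoking at 13.1%, a one-time
20% price rise prevents ~9,600 incident COPD cases over 40 years (and
roughly twice / four times the 10% / 5% effects — gains scale
near-linearly), and a 20-year-old male gains 0.75 years of life expectancy.
The last line is the published cost arithmetic: 124,364 prevented cases at
5,700 €/year for 10 years of disease is ≈ 7.09 billion €.

Tidy/ggplot2 accessors: `tidy()` and `glance()` on bundles, trajectories
and comparisons; `autoplot(cmp)`, `plot_smoking_prevalence(cmp)`,
`plot_copd_burden(cmp)`.

A thin command-line wrapper ships at `inst/cli/copdhia.R`:

```sh
Rscript inst/cli/copdhia.R generate-data --profile italy-like --seed 1 --out bundle/
Rscript inst/cli/copdhia.R simulate --bundle bundle/ --prices 5,10,20 --out results/
Rscript inst/cli/copdhia.R life-expectancy --seed 1 --ages 20,40,60 --out results/
```

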