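# epiquake

Integrated earthquake casualty estimation: HAZUS damage-state casualty
rates augmented with four human-related risk factors — age over 65, female
gender, physical disability and low socioeconomic status — through
logistic equations whose coefficients come from a random-effects
meta-analysis of published odds ratios.

Engineering loss models map building damage states to fixed casualty
rates per injury severity (1 light, 2 moderate, 3 severe, 4 fatal) and so
predict the same outcome for every demographic mix. `epiquake` is for
emergency-preparedness analysts and disaster epidemiologists who want
casualty projections that respond to *who* lives in each census tract,
not just what the buildings are made of.

## The model

Each resident carries dichotomous indicators `X1..X4` for the four risk
factors. The probability of a casualty outcome is

```
p = 1 / (1 + exp(-(b0 + b1*X1 + b2*X2 + b3*X3 + b4*X4)))
```

where `b0 = logit(rate)` for the (damage state, severity) casualty rate —
e.g. the 10% collapse fatality rate gives `b0 = ln(1/9) = -2.197` — and
`b1..b4` are pooled log odds ratios (DerSimonian–Laird random-effects
pooling of published studies; the canonical death set is
`(1.073, 0.182, 0.609, 0.788)`). Severities are then assigned by a
hierarchical cascade, most severe first: at each step the expected count
`E[X] = sum(p)` is computed over the remaining residents, the
highest-probability residents are assigned to that severity, and the
remainder passes to the next step. Zero-rate cells are structural zeros
(`-Inf` on the logit scale): probability 0 for everyone, always.

Populations are realised from census-tract marginals either as a seeded
Bernoulli sample of individuals or as the 16 exact expected-count cells
under independence. The twelve tract profiles of Tiberias, Israel
(42,079 residents) ship with the package, along with the study table and
the reinforced-concrete casualty-rate table.

## Worked example

The worst-case scenario: every structure in Tiberias collapses.

```r
library(epiquake)

est <- estimate_casualties(tiberias_tracts(), scenario_config())
est
#> Integrated earthquake casualty estimate
#>   12 tract(s), 42079 residents; population = cells, ses_mode = all_one, seed = 1
#> City summary (resident-weighted):
#> # A tibble: 5 x 4
#>   severity  count   pct hazus_pct
#>   <chr>     <int> <dbl>     <dbl>
#> 1 fatal     10595  25.2        10
#> 2 severe     4196  10           5
#> 3 moderate  11101  26.4        20
#> 4 light      9668  23          40
#> 5 uninjured  6519  15.5        25
```

Integrating the human-related factors more than doubles the expected
fatality share (25% of residents vs the 10% engineering baseline) and
doubles the severe share, while the light-injury share drops by almost
half — accumulated risk factors push individuals up the severity scale.
Per-tract results are in `tidy(est)`; tract 11, for example, gets 1,482
expected fatalities among its 5,926 residents (25%). `compare_to_hazus(est)`
gives the percentage-point deltas and `autoplot(est)` draws the severity
composition per tract.

The pooled effects behind the coefficients:

```r
pool_effects(study_effects())
#   female/injury pools to OR 1.72 (95% CI 1.27, 2.33) across three studies
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/epiquake estimate \
  --profiles inst/extdata/tiberias_tracts.csv \
  --out tally.csv --report report.json --seed 1
Rscript inst/cli/epiquake compare --report report.json
```

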