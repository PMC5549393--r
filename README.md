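# lqascamp

Lot Quality Assurance Sampling (LQAS) for assessing service coverage in
refugee camps.

Humanitarian agencies need rapid assessments that say more than "average
camp coverage is X%": they need to know *which part* of the camp is
under-served. LQAS answers both questions from a small stratified
sample. The camp is divided into supervision areas (SAs); a fixed small
sample (here 19 respondents per SA per respondent group, six SAs, 114
in total) classifies each SA against coverage benchmarks with an exact
binomial decision rule, and the pooled data give a camp-level coverage
estimate with a 95% confidence interval — with no cluster design effect
to compute. This package is for epidemiologists and M&E staff designing
or analysing such surveys, and for methodologists studying their
operating characteristics.

## The model

An SA with true coverage *p* yields *X* ~ Binomial(*n*, *p*) positive
respondents. Given an upper threshold *p*<sub>U</sub> and lower
threshold *p*<sub>L</sub> (30 percentage points apart in the standard
design), the decision rule *d* classifies the SA as having met the
benchmark when *X* ≥ *d*, with exact misclassification errors

- α(d) = P(X < d | p = p_U)   — a well-served SA classified low,
- β(d) = P(X ≥ d | p = p_L)   — an under-served SA classified high.

`lqas_rule()` selects *d* by exhaustive minimax over max(α, β); at
*n* = 19 this reproduces the standard published rules (95% → 16,
80% → 13, 75% → 12, 60% → 9), all with errors ≤ 0.10. Each indicator is
classified twice: against its programme target, and against the camp
average rounded up to the next 5% band — LQAS used as a homogeneity test
to find outlier SAs. Camp coverage is estimated three ways (crude,
SA-population-weighted, and survey-design with finite population
correction), with a sensitivity table comparing them. A survey
simulator (systematic PPS village allocation, segmentation sampling
with random-walk fallback, parallel sampling of two respondent groups)
and a synthetic camp generator with known ground truth let every stage
be validated end to end.

## Worked example

The packaged fixture is the SA count table of a WASH assessment of
Batil refugee camp (South Sudan): six SAs, 19 respondents per group per
SA, eleven indicators.

```r
library(lqascamp)
bp <- batil_preset()
fit <- lqas(bp$counts, bp$indicators)
fit
#> LQAS camp assessment: 6 supervision areas x 11 indicators (n = 19 per SA)
#>
#>  indicator           SA1 SA2  SA3  SA4  SA5   SA6  avg_dr     ci95  target_dr
#>  improved_water      19  19   19   16   19    19   97.3% (NA) ±3.0% 95% (16)
#>  continuous_water    16  9*b  8*ab 9*b  14    8*ab 57.0% (9)  ±9.1% 80% (13)
#>  ibrik               16  4*ab 3*ab 10   10    8*b  45.2% (7)  ±9.2% 60% (9)
#>  soap                18  9*b  2*ab 13   8*b   6*ab 51.1% (8)  ±9.2% 75% (12)
#>  handwash_area       18  5*b  0*ab 0*ab 1*ab  5*b  27.2% (3)  ±8.0% 60% (9)
#>  health_promoter     19  18   19   19   15*ab 16   93.5% (16) ±4.7% 95% (16)
#>  four_moments        18  7*b  1*ab 11*b 0*ab  2*ab 37.0% (5)  ±8.7% 75% (12)
#>  handwash_adjacent   9   9    1*ab 1*ab 3*b   8*b  27.9% (3)  ±8.2% 60% (9)
#>  improved_sanitation 19  18   18   19   19    17   96.8% (NA) ±3.4%
#>  no_open_defecation  19  18   18   19   19    17   96.8% (NA) ±3.4%
#>  diarrhoea           4   5    7    6    7     3               ±8.3%
#>
#> Flags: a = below camp-average decision rule, b = below programme-target decision rule
```

Each SA cell shows the observed count of 19; `*b` marks an SA below the
decision rule for its programme target (26 such cells), `*a` an SA
below the rule for the camp-average benchmark (15 cells) — the
homogeneity outliers. The `avg_dr` column is the camp average with the
decision rule of its 5% band in parentheses (`NA` above the 95% band,
where every SA passes trivially); `ci95` is the 95% confidence
half-width of the camp estimate.

```r
print(fit$ranking, row.names = FALSE)
#>   sa_id n_average_failures n_target_failures n_dual_failures
#>     SA3                  6                 6               6
#>     SA6                  3                 6               3
#>     SA5                  3                 5               3
#>     SA4                  2                 4               2
#>     SA2                  1                 5               1
#>     SA1                  0                 0               0
```

SA-3 is the "worst of the worst" — flagged on both rules for six
indicators — while SA-1 (closest to the camp's clinics, road and
market) is never flagged; this is the sub-camp information a cluster
survey of the same size cannot provide.

Design-side questions use the same machinery:

```r
lqas_rule(10, 0.80, 0.50)
#> LQAS decision rule: n = 10, thresholds 0.8 / 0.5 -> d = 7
#>   alpha = 0.1209, beta = 0.1719
```

so halving the SA sample (e.g. for gender-stratified classification)
inflates the errors from ≤ 0.10 to 0.12/0.17.

Simulation against known truth:

```r
camp <- generate_camp(camp_config(seed = 1))       # 6 SAs, ~38,000 people
tab  <- tabulate_survey(run_survey(camp, survey_design(), seed = 1))
fit2 <- lqas(tab, data.frame(id = camp$indicators$id,
                             target = camp$indicators$target))
recovery_experiment(camp, n_replicates = 1000, seed = 1)  # bias, RMSE, CI coverage
```

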