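---
title: "LQAS camp assessment: models, decision rules, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LQAS camp assessment: models, decision rules, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lqascamp)
```

## The problem

Humanitarian agencies running water, sanitation and hygiene (WASH)
programmes in refugee camps need rapid, statistically defensible
assessments that work at two levels at once: a coverage estimate for the
whole camp, and a classification of each sub-camp management unit — the
*supervision area* (SA) — as adequately or inadequately served, so that
scarce resources can be directed to the worst-served areas. Lot Quality
Assurance Sampling (LQAS) delivers both from a small stratified sample:
a fixed number of respondents per SA (here 19, in six SAs, for 114 per
respondent group) is classified against benchmark coverages by an exact
binomial decision rule, and the same data aggregate into a stratified
coverage estimate with no cluster design effect.

This package implements that entire workflow: decision-rule design,
SA classification, stratified estimation, a simulator of the field
sampling pipeline, and a synthetic camp generator so that every stage
can be validated against known ground truth without any external data.
The shipped fixture is the SA count table of a real camp assessment
(Batil camp, South Sudan; six SAs; eleven indicators).

## The classification model

An SA with true indicator coverage $p$ yields $X \sim \mathrm{Bin}(n, p)$
positive respondents among $n$. Given an upper threshold $p_U$
(acceptable coverage) and a lower threshold $p_L$ (clearly inadequate
coverage), a decision rule $d$ classifies the SA as *met* when
$X \ge d$. Its two operating errors are exact binomial tails:

$$\alpha(d) = P(X < d \mid p = p_U), \qquad
  \beta(d) = P(X \ge d \mid p = p_L).$$

$\alpha$ is the risk of condemning a genuinely well-served area,
$\beta$ the risk of passing a genuinely under-served one. No normal
approximation is used anywhere: $n$ is small (10–50) and the method was
designed for hand tabulation.

**Rule selection.** `lqas_rule()` chooses $d^\* = \arg\min_d
\max(\alpha(d), \beta(d))$ by exhaustive search over $d \in \{0, \dots,
n\}$, breaking ties toward the smaller $d$. With $n = 19$ and
thresholds 30 points apart this reproduces the standard published
rules — benchmarks 95/80/75/60 per cent give $d$ = 16/13/12/9 — each with
both errors below 0.10; at $n = 10$ the same criterion gives $d = 7$
with errors 0.12 and 0.17, which is why halving the sample (for, say,
gender-stratified reporting) is not recommended at the SA level.

**Degenerate lower threshold.** Benchmarks of 30 per cent and below
make $p_L = \max(p - 0.30,\, 0)$ collapse to zero, where
$\beta(d) \equiv 0$ for every $d \ge 1$ and minimax degenerates to
$d = 1$. The published hand-tabulation tables nevertheless carry
non-trivial rules there (30 per cent → 3 at $n = 19$). We reproduce
them by switching, in this branch only, to the largest $d$ whose
$\alpha$ does not exceed the error cap (default 0.10): the selection
then still controls the only error that remains defined. This is a
deliberate design choice; the minimax and the $\alpha$-cap branches
agree on every benchmark from 35 per cent upward.

**The homogeneity rule.** Beyond programme targets, LQAS doubles as a
test of homogeneity: the camp-wide average coverage for an indicator is
rounded **up** to the next 5 per cent band (`band_ceiling()`) and the
band's decision rule flags SAs well below the camp's own average.
Ceiling rounding is adopted because it is the unique convention
consistent with all published average-coverage rules of the fixture
(57.0% → 60% band, rule 9; 45.2% → 50%, rule 7; 51.1% → 55%, rule 8;
27.2% and 27.9% → 30%, rule 3; 93.5% → 95%, rule 16; 37.0% → 40%,
rule 5). Averages above the 95 per cent band (97.3%, 96.8% in the
fixture) have no defined rule and classify as `NA`; so do averages
below the 20 per cent band, where the lower threshold would fall below
−10 per cent.

**Priority ranking.** SAs are ordered by failures against the average
rule (primary), then failures against targets, then `sa_id`. The
average rule is primary because it identifies the outliers — the "worst
of the worst" — even when targets are globally missed or unset; dual
failures are reported alongside. The fixture ranks SA-3 first (six dual
failures) and SA-1 last (none of either kind), matching the published
assessment. No multiplicity adjustment is applied across the 6 × 8 flag
grid; the flags are descriptive management signals, not hypothesis
tests.

## Estimation

Aggregating the SA samples as strata gives three estimators of camp
coverage (`estimate_coverage()`):

* **crude**: $\hat p = \sum_h x_h / N$, $\mathrm{se} = \sqrt{\hat p (1 -
  \hat p)/(N - 1)}$ with $N = \sum_h n_h$;
* **weighted**: $\hat p = \sum_h W_h \hat p_h$ with $W_h = N_h / \sum
  N_h$ population weights and $\mathrm{se} = \sqrt{\sum_h W_h^2 \hat
  p_h (1 - \hat p_h)/(n_h - 1)}$;
* **design**: the weighted estimator with each stratum's variance term
  multiplied by the finite population correction $1 - n_h/N_h$.

The $N - 1$ and $n_h - 1$ denominators were chosen because they
reconcile exactly with the published crude standard errors of the
fixture (e.g. 0.047 for continuous water at 64/114). Confidence
intervals use $z = 1.96$ throughout (configurable); interval bounds are
clipped to $[0, 1]$ for reporting while half-widths are kept unclipped.
`sensitivity_table()` tabulates the pairwise differences between the
three estimators (convention: crude minus alternative) with standard
deviation, maximum, mean and median summaries over indicators — with
equal stratum populations the three point estimates coincide and only
the variance formulas differ. SA populations for the fixture camp were
never published, so weighting is exercised on synthetic camps; the
fixture's homogeneity rules instead consume the published weighted
averages directly.

`cluster_equivalent_n()` converts the stratified sample size into the
cluster-survey equivalent under an assumed design effect
(`ceiling(deff * n)`, default deff 1.5): the 114-respondent stratified
design corresponds to a 171-respondent cluster sample.

## The sampling simulator

`run_survey()` reproduces the field selection pipeline:

1. **PPS allocation** (`pps_allocate()`): the 19 interview locations of
   an SA are allocated to its Sheik villages by systematic
   probability-proportional-to-size sampling (cumulative totals, one
   uniform random start). Systematic PPS was chosen over independent
   multinomial draws as the standard field practice with lower
   allocation variance; with $k$ equal villages it guarantees exactly
   one location each.
2. **Household selection**: villages with at least `landmark_threshold`
   households (default 12) use **segmentation sampling**
   (`segmentation_select()`): the household range is recursively split
   into at most 4 near-equal segments, one chosen with probability
   proportional to size, until 10 or fewer households remain, then one
   is drawn uniformly — exactly uniform overall by construction.
   Smaller villages fall back to the **random walk**
   (`random_walk_select()`): uniform entry household, random direction,
   geometric number of doors (step probability 0.6), reflecting at the
   ends of the household list. The reflection makes the walk
   deliberately *not* exactly uniform, mirroring the documented bias of
   the field technique; exact enumeration of the chain shows the
   total-variation distance from uniform stays below 0.1 for villages
   of up to 20 households at the default step probability (worst case
   0.095 at 3 households).
3. **Parallel sampling** (`parallel_sample()`): from the selected
   household the two respondent groups — heads of household and
   caregivers of children 0–59 months — are filled by moving to the
   next nearest door (index distance, lower index on ties) until each
   group has one respondent. Household adjacency is modelled as
   position in the village household list; no coordinates exist in the
   frame. A village lacking a respondent type escalates the location to
   the next village of the SA.

Responses are Bernoulli draws at the SA's true coverage. A fixed seed
makes the complete survey byte-reproducible.

## The synthetic camp generator

`generate_camp()` builds Batil-like frames: six SAs at equally spaced
amenity distances, each with a uniform 8–12 Sheik villages; village
populations are lognormal (sdlog 0.5) rescaled to an exact camp total
of 38,000; households are population over a mean household size of 6.
True SA coverage follows a logit-linear distance gradient,

$$\operatorname{logit} p_s = \operatorname{logit} p_0 - \gamma\, d_s,$$

the minimal model producing the observed "periphery is worse served"
pattern while keeping truths inside $(0,1)$; sanitation-type indicators
get $\gamma = 0$, mirroring the uniformly high sanitation coverage of
the fixture camp. The default indicator panel's baselines and gradients
are plausibility choices anchored to the fixture's observed range, not
published values. Caregiver presence per household defaults to 0.6 and
head-of-household presence to 0.9 — field-plausible occupancy rates; the
paper these data come from reports neither.

What the generator deliberately does **not** model: spatial household
geometry, overlapping village boundaries, interviewer effects, refusal
and item nonresponse, or within-household selection. Passing tests on
synthetic camps therefore validate the statistical machinery
(unbiasedness, error rates, CI coverage) under clean binomial response
behaviour, not robustness to the messiness of real field data.

`batil_preset()` pins the generator to the fixture: truths equal the
observed per-SA proportions, SA populations are equal (the real ones
are unpublished), and village structure is a fixed ten near-equal
villages per SA so the preset consumes no randomness.

## Validation summary

`recovery_experiment()` closes the loop: replicate surveys are
simulated from a camp with known truth and the pipeline's estimates and
classifications are compared against it. Because responses are
Bernoulli at SA truth regardless of which village or household was
visited, per-SA counts are exactly $\mathrm{Bin}(19, p_s)$; the default
`method = "binomial"` draws them directly (distributionally identical
to the full pipeline and fast enough for $10^4$ replicates), while
`method = "full"` exercises the complete selection machinery. The test
suite runs the experiment at 1,000–10,000 replicates: weighted-estimator
bias stays below 0.01, 95% CI empirical coverage lies in [0.90, 0.97]
for mid-range truths, and observed classification error rates match the
exact $\alpha/\beta$ within Monte-Carlo error (with a Bonferroni-style
simultaneous bound across the 48 SA-indicator cells). Problem sizes in
the suite (replicate counts of $10^3$–$10^5$ per property) were chosen
to make Monte-Carlo error a small fraction of each tested margin.

## Numerical conventions and edge cases

* Probabilities are carried at full double precision; rounding (1 dp
  for percentages, 3 dp for proportions) happens only in rendering.
* Band arithmetic rounds `coverage / 0.05` to 9 decimals before taking
  the ceiling so that representation noise (e.g. `0.60/0.05` landing a
  hair above 12) cannot shift a boundary coverage into the next band.
* `d` ranges over the full `0:n`; `d = 0` classifies everything as met
  ($\alpha = 0, \beta = 1$) and is admissible input to `lqas_errors()`
  but never selected for non-degenerate thresholds.
* Counts above `n`, duplicate SA ids, and non-integer cells are hard
  errors naming the offending SA and indicator.
* Known limitations: the average-coverage rule inherits whatever bias
  the supplied average has (weighted vs crude); the random walk is
  intentionally biased; and ranking ties below the top positions depend
  on the lexicographic tie-break.

## A worked run

```{r worked}
bp <- batil_preset()
fit <- lqas(bp$counts, bp$indicators)
fit
summary(fit)$ranking
```

```{r sim}
camp <- generate_camp(camp_config(seed = 1))
rec <- tabulate_survey(run_survey(camp, survey_design(), seed = 1))
head(rec)
```
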