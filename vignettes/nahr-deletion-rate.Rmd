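---
title: "Estimating sperm NAHR deletion rates, their heritability and the absence of a paternal-age effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sperm NAHR deletion rates, their heritability and the absence of a paternal-age effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nahrtwin)
```

## The problem

Nonallelic homologous recombination (NAHR) between the paralogous
*CMT1A-REP* segmental duplications on 17p12 deletes a 1.4 Mb interval
containing *PMP22*; the deletion causes HNPP and the reciprocal
duplication CMT1A. The deletion arises during male meiosis at a rate of
roughly 1 in 30,000 sperm, which is measurable directly: sperm DNA is
diluted across many small-pool PCR reactions and deletion-specific
breakpoint products are amplified well by well. `nahrtwin` implements
the quantitative side of such a study on a twin cohort: per-donor rate
estimation from well counts, the heritability of that rate in
monozygotic (MZ) co-twins, the question of whether the rate rises with
the donor's age, and screens of candidate covariates.

## Limiting-dilution assay model

Each plate distributes a diluted DNA mass across $N$ wells. If $m$
amplifiable molecules land independently and uniformly, the number of
occupied (positive) wells $R$ follows a binomial with success
probability $1 - e^{-m/N}$, so the natural estimator inverts occupancy:

$$\hat m = -N \log\!\left(\frac{N - R}{N}\right).$$

`poisson_occupancy()` implements this inversion. Two constraints follow
directly from the formula:

* A **saturated plate** ($R = N$) has no finite estimate. We treat it as
  a hard error — "increase dilution" — rather than clamping, because any
  clamp would bias rates downward silently.
* The correction always **exceeds the raw positive count** (a convexity
  consequence), with equality only at $R = 0$; it vanishes in the dilute
  limit $R/N \to 0$.

`calibrate_dilution()` chains this over a calibration series to express
the sample's DNA mass per amplifiable haploid genome, which converts
screen input mass into molecules screened. `corrected_deletion_count()`
applies the same inversion to deletion-positive wells, per plate then
summed. Per-plate correction (rather than pooling all wells) is the
default because plates may differ in input mass; `pool = TRUE` is
available when they do not.

The deletion rate is the corrected count divided by molecules screened.
Its confidence interval is the **exact Poisson interval on the count**,
obtained by chi-square inversion,

$$\left[\tfrac12\chi^2_{\alpha/2}(2c),\;
  \tfrac12\chi^2_{1-\alpha/2}(2c+2)\right] / M,$$

extended continuously to the non-integer counts that occupancy
correction produces. The interval is placed on the count only;
uncertainty in the calibration denominator is not propagated, matching
the convention of reporting intervals on Poisson-corrected counts. The
test suite verifies the bounds against a brute-force tail-probability
search to four significant figures on counts 0–50, and verifies
per-donor interval coverage of a known generating rate at the nominal
level.

```{r}
plates <- data.frame(n_wells = 96, n_positive = 48,
                     input_mass_pg_per_well = 5)
calibrate_dilution(plates)
estimate_rate(corrected_count = 10, total_molecules = 1e6)
```

## Heritability: one-way ICC and the re-pairing null

With 8 MZ twin pairs, heritability (in the broad sense of "shared by
co-twins", genetics plus shared environment) is quantified by the
intraclass correlation of deletion rate within pairs. We use the
**one-way random-effects, single-measure, consistency ICC** (the
Shrout–Fleiss ICC(1,1)) because co-twins are interchangeable — there is
no meaningful "first" and "second" twin — which makes the one-way model
the right ANOVA. For pairs,

$$\widehat{ICC} = \frac{MS_B - MS_W}{MS_B + MS_W},$$

with a one-sided p-value from $F = MS_B/MS_W$ on $(n-1,\,n)$ degrees of
freedom and an F-inversion confidence interval. The implementation is a
closed-form computation checked in the tests against `stats::aov` mean
squares to ten significant figures.

A significant ICC alone does not show co-twins are *more* alike than
arbitrary men of the same cohort, so `resample_unrelated_null()`
implements a bespoke null: repeatedly re-pair the same 16 MZ
individuals into 8 "unrelated" pairs by drawing a uniform random perfect
matching that contains no true co-twin pair, compute the ICC and its
p-value for each re-pairing, and report the fraction that beats the
observed co-twin result. Design choices here, made once:

* **Matching without reuse** (each donor appears exactly once per
  iteration) rather than sampling pairs with replacement — re-pairing
  the same 16 men is the natural reading of "unrelated pairs drawn from
  the co-twins", and it preserves the marginal rate distribution
  exactly. The sampler's uniformity over admissible matchings is tested
  by enumeration (all 105 matchings of 8 items) with a chi-square
  goodness-of-fit check.
* **Joint exceedance** (resampled ICC larger *and* p smaller than
  observed) is the default criterion; `criterion = "icc_only"` is
  available for sensitivity analysis.
* **Degenerate resampled sets** (zero variance) are counted as
  non-exceeding, with a warning — the conservative direction.
* Each iteration draws from its own deterministic substream of the
  master seed, so results are bit-reproducible and independent of
  iteration order.

With only 3 DZ pairs, an MZ/DZ variance-component decomposition (ACE)
is out of scope by design: it would not be estimable.

## The paternal-age question

Germline point-mutation rates rise with father's age, consistent with
accumulating mitotic replications of spermatogonial stem cells. The
replication-counting model implemented in `genome_replications()` is:
30 replications before puberty, 23 per year after puberty (taken to
occur at age 15), plus 5 during sperm maturation. A sperm from a
24-year-old has undergone $30 + 23\times9 + 5 = 242$ replications; from
a 67-year-old, $1231$ — a 5.1-fold linear increase across that age
span. If NAHR deletions were replication-driven, their rate should
track this.

Whether a cohort *could have seen* such an effect is a power question,
answered by simulation (`simulate_linear_age_power()`): set each
donor's expected rate on a linear ramp from youngest to oldest age with
a given fold change, rescaled so the cohort mean equals the observed
mean rate (both constraints — the fold across the age span and the
preserved mean — are honoured simultaneously by the rescaling); draw
each donor's deletion count as Poisson with mean rate × molecules
assayed, the only natural exposure scale; regress observed rate on age;
and count the fraction of replicates with slope p below α. At fold 1
the procedure is a null calibration and the power estimate must sit at
α, which the tests check against the 99% binomial band at 10,000
replicates. A sigmoidal alternative (`simulate_logit_logistic_power()`)
covers a threshold-like age dependence of the kind described for
maternal-age effects: a four-parameter logistic in age with the
midpoint rate pinned to the observed mean, asymptote ratio and
steepness left as configuration (defaults: ratio 5, midpoint at the
median cohort age, steepness 0.2/year), tested by Spearman rank
correlation since the alternative is monotone but non-linear. No
printed power value is claimed for the sigmoidal model; its
parameterisation is not pinned down by any published number.

## Covariate screens

`group_rate_test()` is a two-sided Mann–Whitney U comparison (PRDM9
A-homozygotes versus A-heterozygotes; smokers versus non-smokers). The
exact null is used up to combined n = 20 without ties — the tests match
it against full enumeration of rank assignments — and the tie-corrected
normal approximation beyond, which is the regime of a 29-versus-5
comparison. Smoking is dichotomised both ways (ex-smokers as smokers
and as non-smokers) and both p-values reported. `snp_association()`
regresses rate on additive dosage per SNP with Bonferroni adjustment
over the SNPs tested, refusing related donors (one per family);
additive coding is assumed, the usual default for a quantitative-trait
single-marker screen. `paralog_identity()` scores pre-aligned
proximal/distal hotspot sequences; gap-versus-base columns count as
mismatches by default (`count_gaps = FALSE` excludes them), columns
gapped in both sequences are ignored, and the metric is symmetric and
case-insensitive.

## The synthetic cohort generator

No per-donor dataset is distributed, so every stage is exercised
against `generate_cohort()`, which emulates the structure of such a
study. Its defaults are the study conditions, chosen once:

| parameter | default | why |
|---|---|---|
| composition | 8 MZ pairs, 3 DZ pairs, 12 unrelated (n = 34) | the cohort design |
| ages | 24–67 years, co-twins sharing an age | the sampled age span |
| `mean_rate` | 3.54e-5 per molecule | the observed cohort mean |
| `between_donor_cv` | 0.5 | gives a max/min fold-range of order seven across 34 donors |
| `pair_icc` | 0.78 | the observed MZ intraclass correlation |
| `age_fold` | 1 | no age effect observed |
| `molecules_per_donor` | 1e6 | assay depth giving tens of deletion molecules per donor at the mean rate |

True log-rates follow a variance-components model: a pair effect
carrying fraction `pair_icc` of the log-rate variance (shared fully
within MZ pairs; with weight 1/2 within DZ pairs, the additive-genetics
analogy) plus an individual effect, around a log-normal baseline
calibrated so the expected rate equals `mean_rate`. The log-normal
choice reflects positive rates with multiplicative variation.
Observation is Poisson at the per-donor molecule depth
(`molecules_per_donor = Inf` switches measurement noise off, for
estimator-recovery studies). Plate files are generated by binomial well
occupancy so the assay chain can be exercised from raw wells.

What the generator does *not* emulate: PCR failure and contamination,
plate-to-plate efficiency drift, uncertainty in the calibration itself,
age-structured cohort recruitment, and any real linkage between
covariates and rate (covariates are drawn independently). Passing tests
therefore demonstrate correctness of the estimators and their
calibration under the model's assumptions, not robustness to assay
artefacts.

One subtlety: `pair_icc` is defined on the log-rate scale, where the
variance partition lives. The ICC computed on raw rates is attenuated
by the log-normal nonlinearity (about 0.78 observed at a generating
value of 0.8 with CV 0.5) on top of the usual small-sample downward
bias of the ANOVA estimator at 8 pairs, so parameter-recovery tests
assert recovery of `pair_icc` on log rates, while the analysis
functions operate on raw rates as a real workflow would.

## Numerical and reproducibility choices

* Non-integer corrected counts use the continuous chi-square extension
  for their CIs; count 0 has lower bound exactly 0.
* A zero-variance response in any regression returns slope 0,
  R² = 0, p = 1 rather than `NaN` — a flat screen is evidence of
  nothing, not an error. Zero-variance rank sets in the Mann–Whitney
  test likewise return p = 1.
* Power simulations use a vectorised closed-form OLS / Spearman-t
  computation across replicates; the closed form is tested against
  `lm()` to ten significant figures.
* All pipeline randomness fans out from one master seed by a
  deterministic integer hash per stage (and per iteration inside the
  resampling null), so reports are byte-identical across re-runs.
* Default problem sizes: 10,000 resampling iterations and 10,000 power
  replicates in the acceptance script; the test suite uses 200–4,000
  replicates per property, with 1,000 cohorts for the ICC-recovery
  study, sizes at which every Monte-Carlo tolerance asserted has
  comfortable margin.

## A worked run

```{r}
co <- generate_cohort(cohort_spec(seed = 7))
cohort_summary(co$donors$deletion_rate)[c("mean_rate", "fold_range")]

mz <- co$donors[co$donors$zygosity == "MZ", ]
mz <- mz[order(mz$pair_id, mz$twin_index), ]
icc_oneway(matrix(mz$deletion_rate, ncol = 2, byrow = TRUE))

resample_unrelated_null(mz$deletion_rate, mz$pair_id,
                        n_iterations = 2000, seed = 3)

rate_age_regression(co$donors$age_years, co$donors$deletion_rate)

simulate_linear_age_power(co$donors$age_years, co$donors$total_molecules,
                          mean(co$donors$deletion_rate), fold = 5.1,
                          n_replicates = 2000, seed = 5)
```

## Known limitations

* The resampling null conditions on the observed rates; it tests
  exchangeability of pairings, not any generative model.
* Calibration uncertainty is not propagated into rate CIs.
* The sigmoidal power model's steepness and asymptote ratio are user
  configuration, not estimated quantities.
* With 3 DZ pairs the package deliberately offers no genetics-versus-
  shared-environment decomposition.
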