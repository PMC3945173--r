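# nahrtwin

Estimation of nonallelic homologous recombination (NAHR) deletion rates
in sperm from limiting-dilution small-pool PCR data, and the downstream
population questions such rates raise: how variable is the rate between
men, is it heritable, and does it rise with paternal age?

The package is aimed at groups running single-molecule sperm-typing
assays at NAHR hotspots such as *CMT1A-REP* (whose deletion causes HNPP
and whose reciprocal duplication causes CMT1A), and at methodologists
who want a tested reference implementation of the statistics involved.

## What it computes

**Assay model.** Molecules distributed across $N$ PCR wells leave $R$
positive wells; the Poisson-occupancy inversion
$\hat m = -N\ln\!\big((N-R)/N\big)$ estimates the molecules on the
plate. `calibrate_dilution()` converts a calibration series into pg of
DNA per amplifiable haploid genome; `corrected_deletion_count()`
applies the same inversion to deletion-positive wells. The deletion
rate is corrected count / molecules screened, with an exact Poisson
confidence interval by chi-square inversion,
$\big[\tfrac12\chi^2_{\alpha/2}(2c),\ \tfrac12\chi^2_{1-\alpha/2}(2c+2)\big]/M$,
extended continuously to the non-integer counts the correction yields.

**Heritability.** `icc_oneway()` gives the one-way random-effects,
single-measure intraclass correlation (Shrout–Fleiss ICC(1,1)) for MZ
co-twin pairs, with an F-based one-sided p and confidence interval.
`resample_unrelated_null()` asks whether co-twins are more alike than
arbitrary pairings of the same men: it re-pairs the 2n donors into n
pairs by uniform random perfect matchings that avoid true co-twin
pairs, and reports the fraction of pairings whose ICC is larger *and*
p smaller than observed.

**Paternal age.** `genome_replications()` implements the germline
replication-counting model (30 replications before puberty at 15, 23
per year after, 5 at maturation): 242 replications at age 24, 1231 at
age 67, a 5.1-fold span. `simulate_linear_age_power()` and
`simulate_logit_logistic_power()` estimate, by Poisson simulation at
the cohort's assay depth, the power to detect linear and sigmoidal
rate–age relationships.

**Covariate screens.** Mann–Whitney group comparisons (PRDM9 genotype
classes, smoking under both ex-smoker codings), OLS screens (BMI,
alcohol), a per-SNP dosage regression with Bonferroni correction, and
percent identity of pre-aligned proximal/distal hotspot sequences.

**Synthetic cohorts.** `generate_cohort()` produces donor, plate and
covariate tables with tunable heritability, age effect, between-donor
variation and assay depth; `run_pipeline()` drives the whole analysis
from files (or a YAML config) to a machine-readable JSON report. A thin
CLI wrapper lives at `inst/scripts/run-pipeline.R`.

## A worked example

```r
library(nahrtwin)

co <- generate_cohort(cohort_spec(seed = 7))   # 34 men, 8 MZ pairs
s <- cohort_summary(co$donors$deletion_rate)
# mean 3.96e-05, s.e.m. 2.9e-06, range 1.1e-05 to 8.2e-05 (7.5-fold)

mz <- co$donors[co$donors$zygosity == "MZ", ]
mz <- mz[order(mz$pair_id, mz$twin_index), ]
icc_oneway(matrix(mz$deletion_rate, ncol = 2, byrow = TRUE))
#> One-way single-measure ICC, 8 pairs
#>   ICC = 0.894, 95% CI 0.596-0.977, one-sided p = 0.0002697

resample_unrelated_null(mz$deletion_rate, mz$pair_id,
                        n_iterations = 10000, seed = 3)
#> Unrelated-pair resampling null (joint criterion)
#>   observed ICC = 0.894 (p = 0.0002697)
#>   2 / 10000 resampled pairings exceed (0.02%)

rate_age_regression(co$donors$age_years, co$donors$deletion_rate)
#> OLS (n = 34): slope = 2.124e-07, R^2 = 0.02575, p = 0.3646

simulate_linear_age_power(co$donors$age_years, co$donors$total_molecules,
                          mean(co$donors$deletion_rate), fold = 5.1,
                          n_replicates = 10000, seed = 5)
#> [1] 1

estimate_rate(10, 1e6)
#>   corrected_count total_molecules  rate       ci_low      ci_high ci_level
#> 1              10           1e+06 1e-05 4.795389e-06 1.839036e-05     0.95
```

Read in sequence: this cohort's deletion rate varies several-fold
between donors; MZ co-twins are strongly correlated (ICC 0.894) and
almost no random re-pairing of the same men does better (0.02%); the
rate shows no age trend even though a replication-driven 5.1-fold
increase would have been detected in essentially every simulated
replicate; and a donor with 10 corrected deletion molecules in a
million screened has a rate of 1e-5 with 95% CI (4.8e-6, 1.8e-5).

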