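#' Germline genome-replication model parameters
#'
#' The spermatogenesis replication-counting model: a fixed number of
#' genome replications before puberty, a constant number of spermatogonial
#' stem-cell replications per year after puberty, and a fixed number
#' during sperm maturation.
#'
#' @param pre_puberty_replications Replications before puberty (default 30).
#' @param replications_per_year Stem-cell replications per year after
#'   puberty (default 23).
#' @param maturation_replications Replications during sperm maturation
#'   (default 5).
#' @param puberty_age Age at puberty in years (default 15).
#' @return A list of class `replication_params`.
#' @export
replication_params <- function(pre_puberty_replications = 30,
                               replications_per_year = 23,
                               maturation_replications = 5,
                               puberty_age = 15) {
  vals <- c(pre_puberty_replications, replications_per_year,
            maturation_replications, puberty_age)
  if (any(!is.finite(vals)) || any(vals < 0) || puberty_age <= 0) {
    stop("replication parameters must be non-negative, puberty_age > 0")
  }
  structure(
    list(pre_puberty_replications = pre_puberty_replications,
         replications_per_year = replications_per_year,
         maturation_replications = maturation_replications,
         puberty_age = puberty_age),
    class = "replication_params"
  )
}

#' Number of genome replications behind a sperm from a man of a given age
#'
#' @param age Age in years (vectorised); must be at least `puberty_age`.
#' @param params A [replication_params()] object.
#' @return Replication count(s): `pre_puberty + per_year * (age - puberty)
#'   + maturation`. 242 at age 24 and 1231 at age 67 under the defaults.
#' @examples
#' genome_replications(24)  # 242
#' genome_replications(67)  # 1231
#' @export
genome_replications <- function(age, params = replication_params()) {
  if (any(!is.finite(age)) || any(age < params$puberty_age)) {
    stop("'age' must be finite and at least puberty_age (",
         params$puberty_age, ")")
  }
  params$pre_puberty_replications +
    params$replications_per_year * (age - params$puberty_age) +
    params$maturation_replications
}

#' Fold change in germline replications between two ages
#'
#' @param age_a,age_b Ages in years, both at least puberty age.
#' @param params A [replication_params()] object.
#' @return `genome_replications(age_b) / genome_replications(age_a)`;
#'   about 5.1 between ages 24 and 67 under the defaults.
#' @export
replication_fold_change <- function(age_a, age_b,
                                    params = replication_params()) {
  genome_replications(age_b, params) / genome_replications(age_a, params)
}

#' Linear regression of deletion rate on donor age
#'
#' @param age Donor ages in years (>= 3 donors, >= 2 distinct ages).
#' @param rate Per-donor deletion rates.
#' @return A [ols_regression()] `regression_result`.
#' @export
rate_age_regression <- function(age, rate) {
  ols_regression(rate, age)
}

# Expected per-donor rates under a linear fold ramp anchored at the
# cohort's age extremes, rescaled so the cohort mean equals mean_rate.
.linear_ramp_rates <- function(age, mean_rate, fold) {
  ramp <- 1 + (fold - 1) * (age - min(age)) / (max(age) - min(age))
  ramp / mean(ramp) * mean_rate
}

#' Power to detect a linear paternal-age effect by Monte-Carlo simulation
#'
#' Simulates a linear fold change in deletion rate across the cohort's age
#' span: each donor's expected rate rises linearly from the youngest to
#' the oldest age by the given fold, with the cohort mean pinned to
#' `mean_rate`. Observed deletion-molecule counts are drawn Poisson with
#' mean (expected rate x molecules assayed), converted back to rates, and
#' regressed on age; power is the fraction of replicates whose slope
#' p-value falls below `alpha`.
#'
#' @param age Donor ages in years.
#' @param molecules Molecules assayed per donor (scalar or per-donor).
#' @param mean_rate Cohort mean deletion rate for the simulated data.
#' @param fold Linear fold change between youngest and oldest (>= 1;
#'   `fold = 1` is the null and yields power approximately `alpha`).
#' @param n_replicates Monte-Carlo replicates, default `10000`.
#' @param alpha Significance threshold, default `0.05`.
#' @param seed Integer seed.
#' @return Estimated power (fraction in \[0, 1\]).
#' @export
simulate_linear_age_power <- function(age, molecules, mean_rate, fold,
                                      n_replicates = 10000L, alpha = 0.05,
                                      seed = 1L) {
  if (!is.finite(fold) || fold < 1) stop("'fold' must be >= 1")
  if (any(!is.finite(molecules)) || any(molecules <= 0)) {
    stop("'molecules' must be positive")
  }
  if (length(unique(age)) < 2L) stop("ages must not all be equal")
  n <- length(age)
  molecules <- rep_len(molecules, n)
  r <- .linear_ramp_rates(age, mean_rate, fold)
  mu <- r * molecules
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(n * n_replicates, mu), nrow = n)
  rates <- counts / molecules
  p <- .ols_pvalues(rates, age)
  mean(p < alpha)
}

#' Power curve over a grid of linear fold changes
#'
#' @inheritParams simulate_linear_age_power
#' @param folds Ordered vector of fold changes (each >= 1).
#' @return A data frame of class `power_curve` with columns `fold`,
#'   `power`, `n_replicates`, `alpha`, `seed`.
#' @export
power_curve <- function(age, molecules, mean_rate, folds,
                        n_replicates = 10000L, alpha = 0.05, seed = 1L) {
  power <- vapply(seq_along(folds), function(i) {
    simulate_linear_age_power(age, molecules, mean_rate, folds[i],
                              n_replicates = n_replicates, alpha = alpha,
                              seed = .iter_seed(seed, i))
  }, numeric(1))
  out <- data.frame(fold = folds, power = power,
                    n_replicates = as.integer(n_replicates),
                    alpha = alpha, seed = as.integer(seed))
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Power to detect a logit-logistic (sigmoidal) paternal-age effect
#'
#' Simulates a four-parameter logistic dependence of deletion rate on age,
#' the shape proposed for the maternal-age dependence of Down-syndrome
#' prevalence: rate rises from a lower to an upper asymptote with midpoint
#' at `midpoint_age`. The asymptotes are placed symmetrically around
#' `mean_rate` with ratio `asymptote_fold`, so the curve passes through
#' `mean_rate` at the midpoint. Counts are drawn Poisson as in
#' [simulate_linear_age_power()]; significance is assessed by Spearman's
#' rank correlation between age and simulated rate.
#'
#' @inheritParams simulate_linear_age_power
#' @param asymptote_fold Ratio of upper to lower asymptote (>= 1; 1 gives
#'   a flat curve and power approximately `alpha`). Default 5.
#' @param midpoint_age Age at the curve midpoint; default the median age.
#' @param steepness Logistic steepness per year (>= 0; 0 gives a flat
#'   curve). Default 0.2.
#' @return Estimated power (fraction in \[0, 1\]).
#' @export
simulate_logit_logistic_power <- function(age, molecules, mean_rate,
                                          asymptote_fold = 5,
                                          midpoint_age = stats::median(age),
                                          steepness = 0.2,
                                          n_replicates = 10000L,
                                          alpha = 0.05, seed = 1L) {
  if (!is.finite(asymptote_fold) || asymptote_fold < 1) {
    stop("'asymptote_fold' must be >= 1 (upper asymptote above lower)")
  }
  if (!is.finite(steepness) || steepness < 0) {
    stop("'steepness' must be non-negative")
  }
  if (any(!is.finite(molecules)) || any(molecules <= 0)) {
    stop("'molecules' must be positive")
  }
  n <- length(age)
  molecules <- rep_len(molecules, n)
  low <- 2 * mean_rate / (1 + asymptote_fold)
  high <- asymptote_fold * low
  r <- low + (high - low) / (1 + exp(-steepness * (age - midpoint_age)))
  mu <- r * molecules
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(n * n_replicates, mu), nrow = n)
  rates <- counts / molecules
  p <- .spearman_pvalues(rates, age)
  mean(p < alpha)
}
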