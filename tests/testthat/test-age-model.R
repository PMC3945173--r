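test_that("replication counting model is exact and linear above puberty", {
  expect_identical(genome_replications(24), 242)
  expect_identical(genome_replications(67), 1231)
  expect_identical(genome_replications(15), 35)
  # exactly linear in age above puberty
  ages <- 15:70
  reps <- genome_replications(ages)
  expect_true(all(diff(reps) == 23))
  expect_true(all(reps == round(reps)))
  expect_error(genome_replications(14), "puberty")
  custom <- replication_params(puberty_age = 13)
  expect_equal(genome_replications(13, custom), 35)
  expect_error(replication_params(replications_per_year = -1),
               "non-negative")
})

test_that("replication fold change between cohort age extremes rounds to 5.1", {
  expect_equal(replication_fold_change(24, 67), 1231 / 242)
  expect_equal(round(replication_fold_change(24, 67), 1), 5.1)
  expect_equal(replication_fold_change(40, 40), 1)
  expect_equal(replication_fold_change(15, 16), 58 / 35)
})

test_that("rate-age regression follows the OLS closed form", {
  set.seed(3)
  age <- sample(24:67, 20, replace = TRUE)
  rate <- 3e-5 + 1e-7 * age + rnorm(20, 0, 5e-6)
  res <- rate_age_regression(age, rate)
  # two-pass closed-form oracle
  xc <- age - mean(age)
  yc <- rate - mean(rate)
  slope <- sum(xc * yc) / sum(xc^2)
  intercept <- mean(rate) - slope * mean(age)
  r2 <- slope^2 * sum(xc^2) / sum(yc^2)
  se <- sqrt(sum((rate - intercept - slope * age)^2) / 18 / sum(xc^2))
  p <- 2 * pt(-abs(slope / se), 18)
  expect_equal(res$slope, slope, tolerance = 1e-10)
  expect_equal(res$intercept, intercept, tolerance = 1e-10)
  expect_equal(res$r_squared, r2, tolerance = 1e-10)
  expect_equal(res$p_value, p, tolerance = 1e-10)
})

test_that("rate-age regression handles exact and degenerate relationships", {
  age <- c(24, 30, 45, 60, 67)
  expect_equal(suppressWarnings(
    rate_age_regression(age, 1e-6 * age))$r_squared, 1)
  flat <- rate_age_regression(age, rep(3e-5, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_value, 1)
  expect_error(rate_age_regression(rep(30, 5), rnorm(5)), "constant")
  expect_error(rate_age_regression(c(24, 30), c(1, 2) * 1e-5),
               "at least three")
})

test_that("linear age-effect power is calibrated at the null and monotone", {
  age <- round(seq(24, 67, length.out = 34))
  mols <- 1e6
  p_null <- simulate_linear_age_power(age, mols, 3.54e-5, fold = 1,
                                      n_replicates = 2000, seed = 21)
  expect_lt(abs(p_null - 0.05), 0.025)

  folds <- c(1.2, 2, 5.1)
  pw <- vapply(folds, function(f)
    simulate_linear_age_power(age, mols, 3.54e-5, fold = f,
                              n_replicates = 2000, seed = 22),
    numeric(1))
  expect_true(all(diff(pw) >= -2 * sqrt(0.25 / 2000)))
  expect_gt(pw[3], 0.99)

  # more molecules assayed means more power
  pw_lo <- simulate_linear_age_power(age, 2e4, 3.54e-5, fold = 2,
                                     n_replicates = 2000, seed = 23)
  pw_hi <- simulate_linear_age_power(age, 1e6, 3.54e-5, fold = 2,
                                     n_replicates = 2000, seed = 23)
  expect_gt(pw_hi, pw_lo - 2 * sqrt(0.25 / 2000))

  expect_error(simulate_linear_age_power(age, mols, 3.54e-5, fold = 0.5),
               ">= 1")
  expect_error(simulate_linear_age_power(age, 0, 3.54e-5, fold = 2),
               "positive")
})

test_that("power curve tabulates the fold grid deterministically", {
  age <- round(seq(24, 67, length.out = 34))
  pc1 <- power_curve(age, 1e6, 3.54e-5, folds = c(1, 2, 5.1),
                     n_replicates = 500, seed = 9)
  pc2 <- power_curve(age, 1e6, 3.54e-5, folds = c(1, 2, 5.1),
                     n_replicates = 500, seed = 9)
  expect_identical(pc1, pc2)
  expect_equal(pc1$fold, c(1, 2, 5.1))
  expect_true(all(pc1$power >= 0 & pc1$power <= 1))
})

test_that("logit-logistic power is alpha for flat curves and high for steep", {
  age <- round(seq(24, 67, length.out = 34))
  flat_s <- simulate_logit_logistic_power(age, 1e6, 3.54e-5,
                                          steepness = 0,
                                          n_replicates = 2000, seed = 31)
  expect_lt(abs(flat_s - 0.05), 0.03)
  flat_a <- simulate_logit_logistic_power(age, 1e6, 3.54e-5,
                                          asymptote_fold = 1,
                                          steepness = 0.5,
                                          n_replicates = 2000, seed = 32)
  expect_lt(abs(flat_a - 0.05), 0.03)
  steep <- simulate_logit_logistic_power(age, 1e6, 3.54e-5,
                                         asymptote_fold = 5,
                                         steepness = 0.5,
                                         n_replicates = 2000, seed = 33)
  expect_gt(steep, 0.9)
  expect_error(
    simulate_logit_logistic_power(age, 1e6, 3.54e-5,
                                  asymptote_fold = 0.5),
    ">= 1")
})
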