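test_that("poisson occupancy matches the closed form and guards its domain", {
  expect_equal(poisson_occupancy(96, 0), 0)
  expect_equal(poisson_occupancy(96, 48), 96 * log(2))
  expect_equal(poisson_occupancy(88, 3), -88 * log(85 / 88))
  # vectorised over plates
  expect_equal(poisson_occupancy(c(96, 88), c(48, 3)),
               c(96 * log(2), -88 * log(85 / 88)))
  expect_error(poisson_occupancy(96, 96), "saturated")
  expect_error(poisson_occupancy(96, 97), "exceed")
  expect_error(poisson_occupancy(0, 0), "positive integer")
  expect_error(poisson_occupancy(96, -1), "non-negative")
  expect_error(poisson_occupancy(96, 3.5), "integer")
})

test_that("occupancy inverts molecule-dropping simulation within 2%", {
  set.seed(41)
  n_wells <- 96L
  for (m in c(30L, 66L, 90L)) {
    est <- replicate(4000, {
      occupied <- length(unique(sample.int(n_wells, m, replace = TRUE)))
      -n_wells * log((n_wells - occupied) / n_wells)
    })
    expect_lt(abs(mean(est) - m) / m, 0.02)
    # and the package estimator computes the same inversion
    expect_equal(poisson_occupancy(n_wells, 48), -96 * log(48 / 96))
  }
})

test_that("dilution calibration chains occupancy into pg per haploid genome", {
  one <- data.frame(n_wells = 96, n_positive = 48,
                    input_mass_pg_per_well = 5)
  cal <- calibrate_dilution(one)
  expect_equal(cal$amplifiable_molecules_total, 96 * log(2))
  expect_equal(cal$pg_per_haploid_genome, 480 / (96 * log(2)))
  expect_equal(cal$pg_per_haploid_genome, 7.2135, tolerance = 1e-4)

  two <- rbind(one, one)
  cal2 <- calibrate_dilution(two)
  expect_equal(cal2$amplifiable_molecules_total,
               2 * cal$amplifiable_molecules_total)
  expect_equal(cal2$pg_per_haploid_genome, cal$pg_per_haploid_genome)

  none <- data.frame(n_wells = 96, n_positive = 0,
                     input_mass_pg_per_well = 5)
  expect_error(calibrate_dilution(none), "undefined")
  # role filtering: deletion_screen rows are ignored
  mixed <- rbind(cbind(one, role = "calibration"),
                 cbind(one, role = "deletion_screen"))
  expect_equal(calibrate_dilution(mixed)$amplifiable_molecules_total,
               96 * log(2))
})

test_that("corrected deletion count corrects per plate and never shrinks", {
  plates <- data.frame(n_wells = c(88, 88), n_positive = c(3, 0),
                       input_mass_pg_per_well = 2)
  expect_equal(corrected_deletion_count(plates), -88 * log(85 / 88))
  expect_equal(round(corrected_deletion_count(plates), 3), 3.052)

  zero <- data.frame(n_wells = 96, n_positive = 0,
                     input_mass_pg_per_well = 2)
  expect_equal(corrected_deletion_count(zero), 0)

  # correction >= raw positives (convexity), equality only at R = 0
  for (r in c(1, 10, 40, 90)) {
    expect_gt(corrected_deletion_count(
      data.frame(n_wells = 96, n_positive = r,
                 input_mass_pg_per_well = 2)), r)
  }

  # pooling collapses all wells into a single (N, R)
  expect_equal(
    corrected_deletion_count(plates, pool = TRUE),
    -176 * log(173 / 176))
})

test_that("correction vanishes in the dilute limit", {
  ratios <- vapply(c(0.2, 0.05, 0.01, 0.001), function(frac) {
    n <- 10000L
    r <- round(frac * n)
    poisson_occupancy(n, r) / r
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_lt(abs(ratios[length(ratios)] - 1), 1e-3)
})

test_that("rate estimates carry exact Poisson intervals on the count", {
  e0 <- estimate_rate(0, 1e6)
  expect_equal(e0$rate, 0)
  expect_equal(e0$ci_low, 0)
  expect_equal(e0$ci_high, qchisq(0.975, 2) / 2 / 1e6)
  expect_equal(e0$ci_high, 3.68888e-6, tolerance = 1e-5)

  e10 <- estimate_rate(10, 1e6)
  expect_equal(e10$rate, 1e-5)
  expect_equal(e10$ci_low, 4.795389e-6, tolerance = 1e-6)
  expect_equal(e10$ci_high, 1.839036e-5, tolerance = 1e-6)

  # Poisson scaling: doubling count and molecules fixes the rate and
  # narrows the relative CI
  e20 <- estimate_rate(20, 2e6)
  expect_equal(e20$rate, e10$rate)
  expect_lt(e20$ci_high / e20$rate, e10$ci_high / e10$rate)
  expect_gt(e20$ci_low / e20$rate, e10$ci_low / e10$rate)

  # non-integer corrected counts extend continuously
  e_frac <- estimate_rate(3.052, 1e5)
  expect_true(e_frac$ci_low < e_frac$rate &&
                e_frac$rate < e_frac$ci_high)
  expect_error(estimate_rate(-1, 1e6), "non-negative")
  expect_error(estimate_rate(3, 0), "positive")
})

test_that("per-donor CIs achieve near-nominal coverage on synthetic donors", {
  set.seed(77)
  n <- 1000L
  true_rate <- 3.54e-5
  molecules <- 1e6
  counts <- rpois(n, true_rate * molecules)
  est <- estimate_rate(counts, molecules)
  covered <- mean(est$ci_low <= true_rate & true_rate <= est$ci_high)
  expect_gte(covered, 0.93)
})

test_that("cohort summary reports mean, sem and fold range", {
  s <- cohort_summary(c(1e-5, 3e-5))
  expect_equal(s$mean_rate, 2e-5)
  expect_equal(s$fold_range, 3)

  s_eq <- cohort_summary(rep(2e-5, 5))
  expect_equal(s_eq$sem, 0)
  expect_equal(s_eq$fold_range, 1)

  expect_error(cohort_summary(1e-5), "at least two")
  expect_error(cohort_summary(data.frame(x = 1)), "deletion_rate")
})
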