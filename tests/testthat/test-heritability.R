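test_that("one-way ICC matches the independent ANOVA computation", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- matrix(rnorm(2 * n, mean = 5), ncol = 2)
    res <- icc_oneway(x)
    # oracle: mean squares straight from the one-way ANOVA fit
    y <- as.vector(t(x))
    g <- factor(rep(seq_len(n), each = 2))
    tab <- summary(stats::aov(y ~ g))[[1]]
    msb <- tab["g", "Mean Sq"]
    msw <- tab["Residuals", "Mean Sq"]
    icc_oracle <- (msb - msw) / (msb + msw)
    expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
    expect_equal(res$ms_between, msb, tolerance = 1e-10)
    expect_equal(res$ms_within, msw, tolerance = 1e-10)
    expect_equal(res$p_value,
                 pf(msb / msw, n - 1, n, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_lte(res$ci_low, res$icc)
    expect_lte(res$icc, res$ci_high)
  }
})

test_that("ICC handles perfect agreement and degenerate input", {
  perfect <- cbind(c(1, 2, 3), c(1, 2, 3))
  res <- icc_oneway(perfect)
  expect_equal(res$icc, 1)
  expect_equal(res$p_value, 0)
  expect_error(icc_oneway(cbind(c(1, 1), c(1, 1))), "degenerate")
  expect_error(icc_oneway(cbind(1, 2)), "at least two pairs")
})

test_that("ICC is near zero when pairing carries no information", {
  set.seed(5)
  iccs <- replicate(400, icc_oneway(matrix(rnorm(16), ncol = 2))$icc)
  expect_lt(abs(mean(iccs)), 0.05)
})

test_that("matching sampler covers all allowed matchings uniformly", {
  ids <- letters[1:8]
  true_pairs <- cbind(ids[c(1, 3, 5, 7)], ids[c(2, 4, 6, 8)])
  all_m <- enumerate_matchings(ids)
  expect_length(all_m, 105)  # 7!! matchings of 8 items into 4 pairs
  forbidden_keys <- apply(true_pairs, 1L, function(r)
    paste(sort(r), collapse = "-"))
  allowed <- Filter(function(m) {
    rows <- apply(m, 1L, function(r) paste(sort(r), collapse = "-"))
    !any(rows %in% forbidden_keys)
  }, all_m)
  allowed_keys <- vapply(allowed, matching_key, character(1))

  set.seed(99)
  n_draws <- 20000L
  drawn <- vapply(seq_len(n_draws), function(i)
    matching_key(sample_unrelated_matching(ids, true_pairs)),
    character(1))
  expect_true(all(drawn %in% allowed_keys))
  counts <- table(factor(drawn, levels = allowed_keys))
  gof <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(gof$p.value, 0.01)
})

test_that("matching sampler validates its inputs", {
  expect_error(sample_unrelated_matching(letters[1:3]), "even number")
  # infeasible: the only matching of two items is forbidden
  expect_error(
    sample_unrelated_matching(c("a", "b"), cbind("a", "b"),
                              max_tries = 50L),
    "forbidden")
})

test_that("resampling null is reproducible and respects its contract", {
  set.seed(2)
  rates <- exp(rnorm(16, log(3.5e-5), 0.4))
  pid <- rep(1:8, each = 2)
  r1 <- resample_unrelated_null(rates, pid, n_iterations = 500, seed = 42)
  r2 <- resample_unrelated_null(rates, pid, n_iterations = 500, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$proportion, r1$n_exceeding / r1$n_iterations)
  expect_true(r1$proportion >= 0 && r1$proportion <= 1)
  # observed statistics agree with the direct ICC on the true pairs
  obs <- icc_oneway(matrix(rates[order(pid)], ncol = 2, byrow = TRUE))
  expect_equal(r1$observed_icc, obs$icc)
  expect_equal(r1$observed_p, obs$p_value)
})

test_that("degenerate resampled sets are flagged, not counted as exceeding", {
  rates <- rep(3e-5, 16)
  pid <- rep(1:8, each = 2)
  # warns for the degenerate observed set and for the resampled sets
  expect_warning(expect_warning(
    res <- resample_unrelated_null(rates, pid, n_iterations = 20,
                                   seed = 1),
    "degenerate"), "degenerate")
  expect_equal(res$proportion, 0)
  expect_equal(res$n_degenerate, 20L)
})

test_that("resampling null inputs are validated", {
  rates <- rnorm(16)
  expect_error(resample_unrelated_null(rates, rep(1:4, each = 4)),
               "exactly twice")
  expect_error(resample_unrelated_null(rates[1:3], rep(1, 3)),
               "same length|exactly twice")
})

test_that("strong co-twin correlation is rarely exceeded by re-pairings", {
  props <- vapply(1:10, function(i) {
    co <- generate_cohort(cohort_spec(n_mz_pairs = 8, n_dz_pairs = 0,
                                      n_unrelated = 0, pair_icc = 0.9,
                                      seed = 8 + i))
    mz <- co$donors
    resample_unrelated_null(mz$deletion_rate, mz$pair_id,
                            n_iterations = 300, seed = 10 + i)$proportion
  }, numeric(1))
  expect_lt(mean(props), 0.1)
})

test_that("generated pair ICC is recovered across true values", {
  # log scale: the generator's pair_icc is a log-rate variance fraction
  for (rho in c(0, 0.8)) {
    est <- vapply(1:300, function(i) {
      co <- generate_cohort(cohort_spec(
        n_mz_pairs = 8, n_dz_pairs = 0, n_unrelated = 0,
        pair_icc = rho, molecules_per_donor = Inf, seed = 5000 + i))
      icc_oneway(mz_pair_matrix(co$donors, log_scale = TRUE))$icc
    }, numeric(1))
    expect_lt(abs(mean(est) - rho), 0.07)
  }
})
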