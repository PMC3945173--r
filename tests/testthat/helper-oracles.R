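# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact Poisson CI by brute-force tail inversion: smallest/largest mean
# whose tail probability of the observed count is >= alpha/2.
poisson_ci_oracle <- function(count, level = 0.95) {
  alpha <- 1 - level
  upper <- stats::uniroot(
    function(mu) stats::ppois(count, mu) - alpha / 2,
    lower = 1e-12, upper = 10 * count + 50, tol = 1e-12)$root
  lower <- if (count == 0) 0 else stats::uniroot(
    function(mu) stats::ppois(count - 1, mu, lower.tail = FALSE) - alpha / 2,
    lower = 1e-12, upper = 10 * count + 50, tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# All perfect matchings of an even set of ids, as a list of two-column
# matrices with rows sorted canonically.
enumerate_matchings <- function(ids) {
  if (length(ids) == 0L) return(list(matrix(character(0), ncol = 2)))
  first <- ids[1L]
  rest <- ids[-1L]
  out <- list()
  for (j in seq_along(rest)) {
    partner <- rest[j]
    sub <- enumerate_matchings(rest[-j])
    for (m in sub) {
      out[[length(out) + 1L]] <- rbind(
        sort(c(first, partner)),
        m, deparse.level = 0)
    }
  }
  out
}

matching_key <- function(m) {
  rows <- apply(m, 1L, function(r) paste(sort(as.character(r)),
                                         collapse = "-"))
  paste(sort(rows), collapse = "|")
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (untied data only).
mw_exact_oracle <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  n_tot <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  combs <- utils::combn(n_tot, m)
  u_all <- apply(combs, 2L, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  })
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# MZ pair matrix (rows = pairs) from a donor table.
mz_pair_matrix <- function(donors, log_scale = FALSE) {
  mz <- donors[donors$zygosity == "MZ" & !is.na(donors$pair_id), ,
               drop = FALSE]
  mz <- mz[order(mz$pair_id, mz$twin_index), ]
  v <- if (log_scale) log(mz$deletion_rate) else mz$deletion_rate
  matrix(v, ncol = 2L, byrow = TRUE)
}
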