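#' Mann-Whitney (Wilcoxon rank-sum) test for a two-group rate difference
#'
#' Two-sided Mann-Whitney U test of deletion rates between two donor
#' groups (e.g. PRDM9 A/A homozygotes versus A-heterozygotes). The exact
#' null distribution is used for small samples without ties (combined n up
#' to `exact_threshold`); larger or tied samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param rates_a,rates_b Numeric rate vectors for the two groups, both
#'   non-empty.
#' @param exact_threshold Combined sample size at or below which the exact
#'   null is used (default 20).
#' @return List with `u_statistic`, `p_value`, `method`, `n_a`, `n_b`.
#' @export
group_rate_test <- function(rates_a, rates_b, exact_threshold = 20L) {
  if (length(rates_a) == 0L || length(rates_b) == 0L) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(rates_a, rates_b)) > 0L
  exact <- (length(rates_a) + length(rates_b)) <= exact_threshold && !ties
  wt <- stats::wilcox.test(rates_a, rates_b, exact = exact,
                           correct = !exact)
  p <- wt$p.value
  # all ranks tied: the test carries no evidence against the null
  if (is.nan(p)) p <- 1
  list(u_statistic = unname(wt$statistic),
       p_value = p,
       method = if (exact) "exact" else "normal approximation",
       n_a = length(rates_a),
       n_b = length(rates_b))
}

#' Linear screen of deletion rate against a continuous covariate
#'
#' OLS of rate on the covariate (BMI, alcohol intake, ...); shares the
#' [ols_regression()] result contract with [rate_age_regression()].
#'
#' @param rates Per-donor deletion rates.
#' @param covariate Paired covariate values; non-constant, >= 3 complete
#'   pairs (missing values are dropped pairwise).
#' @return A `regression_result`.
#' @export
covariate_regression <- function(rates, covariate) {
  ols_regression(rates, covariate)
}

#' Smoking-status screen under both ex-smoker classifications
#'
#' Dichotomises smoking status both ways — ex-smokers grouped with current
#' smokers, and ex-smokers grouped with never-smokers — and runs the
#' Mann-Whitney rate comparison for each.
#'
#' @param rates Per-donor deletion rates.
#' @param smoking Character/factor vector with levels `never`, `ex`,
#'   `current` (missing values dropped).
#' @return List with elements `ex_as_smoker` and `ex_as_nonsmoker`, each a
#'   [group_rate_test()] result (or `NULL` if a grouping is empty).
#' @export
smoking_rate_test <- function(rates, smoking) {
  smoking <- as.character(smoking)
  keep <- !is.na(smoking) & is.finite(rates)
  rates <- rates[keep]
  smoking <- smoking[keep]
  bad <- setdiff(unique(smoking), c("never", "ex", "current"))
  if (length(bad) > 0L) {
    stop("unknown smoking level(s): ", paste(bad, collapse = ", "))
  }
  test_split <- function(is_smoker) {
    if (!any(is_smoker) || all(is_smoker)) return(NULL)
    group_rate_test(rates[is_smoker], rates[!is_smoker])
  }
  list(ex_as_smoker = test_split(smoking %in% c("current", "ex")),
       ex_as_nonsmoker = test_split(smoking == "current"))
}

#' Single-SNP association screen with Bonferroni correction
#'
#' Per-SNP OLS of deletion rate on additive genotype dosage (0/1/2), with
#' Bonferroni adjustment over the number of SNPs tested. Only one donor
#' per family may be included (related donors inflate the test); supply
#' `pair_id` to enforce this. Monomorphic SNPs are excluded with a
#' warning.
#'
#' @param rates Per-donor deletion rates (unrelated donors).
#' @param dosages Data frame or matrix, one column per SNP, dosages in
#'   {0, 1, 2} (NA allowed).
#' @param n_snps_tested Multiplicity for the Bonferroni correction;
#'   defaults to the number of SNP columns supplied.
#' @param pair_id Optional family/pair identifier per donor; any id
#'   occurring more than once is an error.
#' @return Data frame with one row per tested SNP: `snp`, `n`, `slope`,
#'   `p_value`, `p_bonferroni`.
#' @export
snp_association <- function(rates, dosages, n_snps_tested = NULL,
                            pair_id = NULL) {
  dosages <- as.data.frame(dosages)
  if (ncol(dosages) == 0L) stop("no SNP columns supplied")
  if (!is.null(pair_id)) {
    pid <- pair_id[!is.na(pair_id)]
    if (anyDuplicated(pid) > 0L) {
      stop("related donors detected: include only one donor per family")
    }
  }
  if (is.null(n_snps_tested)) n_snps_tested <- ncol(dosages)
  ok_dosage <- vapply(dosages, function(d)
    all(is.na(d) | d %in% c(0, 1, 2)), logical(1))
  if (!all(ok_dosage)) {
    stop("dosages must be 0, 1 or 2 (or NA): ",
         paste(names(dosages)[!ok_dosage], collapse = ", "))
  }
  rows <- lapply(names(dosages), function(snp) {
    d <- dosages[[snp]]
    keep <- !is.na(d) & is.finite(rates)
    if (length(unique(d[keep])) < 2L) {
      warning("SNP ", snp, " is monomorphic in the tested donors; excluded")
      return(NULL)
    }
    fit <- ols_regression(rates[keep], d[keep])
    data.frame(snp = snp, n = fit$n, slope = fit$slope,
               p_value = fit$p_value,
               p_bonferroni = min(1, fit$p_value * n_snps_tested))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(snp = character(0), n = integer(0),
                      slope = numeric(0), p_value = numeric(0),
                      p_bonferroni = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Percent identity between aligned paralogous hotspot sequences
#'
#' Column-wise identity of a pre-aligned proximal/distal hotspot pair.
#' By default gap columns count as mismatches (columns gapped in both
#' sequences are ignored); with `count_gaps = FALSE` only columns with a
#' base in both sequences enter the denominator. Case-insensitive;
#' symmetric in its two arguments.
#'
#' @param proximal,distal Aligned sequences of equal length, as single
#'   strings over {A, C, G, T, N, -}.
#' @param count_gaps Whether gap-vs-base columns count as mismatches
#'   (default `TRUE`).
#' @return Percent identity in \[0, 100\].
#' @examples
#' paralog_identity("ACGTA", "ACGTA")          # 100
#' paralog_identity("ACGTACGTA-", "ACGTACGTAT") # 90
#' @export
paralog_identity <- function(proximal, distal, count_gaps = TRUE) {
  a <- strsplit(toupper(as.character(proximal)), "")[[1L]]
  b <- strsplit(toupper(as.character(distal)), "")[[1L]]
  if (length(a) != length(b)) {
    stop("aligned sequences must have equal length")
  }
  if (length(a) == 0L) stop("empty sequences")
  ok <- c("A", "C", "G", "T", "N", "-")
  if (!all(a %in% ok) || !all(b %in% ok)) {
    stop("sequences must be over the alphabet A, C, G, T, N, -")
  }
  both_gap <- a == "-" & b == "-"
  a <- a[!both_gap]
  b <- b[!both_gap]
  if (count_gaps) {
    columns <- length(a)
  } else {
    keep <- a != "-" & b != "-"
    a <- a[keep]
    b <- b[keep]
    columns <- length(a)
  }
  if (columns == 0L) stop("no alignment columns to compare")
  matches <- sum(a == b & a != "-")
  100 * matches / columns
}
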