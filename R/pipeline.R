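#' Run the full deletion-rate analysis pipeline
#'
#' Orchestrates the analysis end to end: per-donor rates (from a plate
#' table when supplied, else from the donor table's precomputed columns),
#' cohort summary, MZ co-twin heritability with the resampling null,
#' age regression and paternal-age power simulations, and the covariate
#' screens (BMI, alcohol, smoking, SNPs, paralog identity) where data are
#' available. Stages whose inputs are absent are skipped with a logged
#' notice, as partial covariate availability is the norm for registry
#' cohorts. All randomness is fanned out deterministically from the one
#' `seed`, so re-running a config reproduces the report exactly.
#'
#' @param config A list, or path to a YAML file, with elements: `donors`
#'   (path to donor TSV, required unless `plates` given), `plates`,
#'   `covariates`, `aligned_fasta` (optional paths), `ci_level` (0.95),
#'   `resample_iterations` (10000), `power_folds` (numeric vector),
#'   `power_replicates` (1000), `alpha` (0.05), `seed` (1), `out_dir`
#'   (optional; report and tables are written there), `figures` (FALSE).
#' @return The report as a nested list (invisibly written as
#'   `report.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(ci_level = 0.95, resample_iterations = 10000L,
                   power_folds = c(1, 1.7, 2, 3, 5.1, 10),
                   power_replicates = 1000L, alpha = 0.05, seed = 1L,
                   figures = FALSE)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  seed <- as.integer(config$seed)
  notice <- function(...) message("[nahrtwin] ", ...)

  input_hashes <- list()
  for (nm in c("donors", "plates", "covariates", "aligned_fasta")) {
    if (!is.null(config[[nm]]) && is.character(config[[nm]])) {
      if (!file.exists(config[[nm]])) {
        stop("input file for '", nm, "' not found: ", config[[nm]])
      }
      input_hashes[[nm]] <- unname(tools::md5sum(config[[nm]]))
    }
  }

  report <- list(seed = seed, inputs = input_hashes)

  # --- rates ----------------------------------------------------------
  donors <- NULL
  if (!is.null(config$donors)) {
    donors <- if (is.data.frame(config$donors)) config$donors
              else read_donors(config$donors)
  }
  if (!is.null(config$plates)) {
    plates <- if (is.data.frame(config$plates)) config$plates
              else read_plates(config$plates)
    est <- estimate_donor_rates(plates, ci_level = config$ci_level)
    if (is.null(donors)) {
      donors <- est
      donors$age_years <- NA_real_
      donors$zygosity <- "U"
    } else {
      keep <- setdiff(names(donors),
                      c("corrected_deletion_count", "total_molecules",
                        "deletion_rate"))
      donors <- merge(donors[keep], est, by = "donor_id", sort = TRUE)
    }
  }
  if (is.null(donors)) stop("config must provide 'donors' and/or 'plates'")
  report$cohort <- cohort_summary(donors$deletion_rate)
  if (!"ci_low" %in% names(donors) &&
      all(is.finite(donors$corrected_deletion_count)) &&
      all(is.finite(donors$total_molecules))) {
    est <- estimate_rate(donors$corrected_deletion_count,
                         donors$total_molecules,
                         ci_level = config$ci_level)
    donors$ci_low <- est$ci_low
    donors$ci_high <- est$ci_high
  }

  # --- heritability ---------------------------------------------------
  mz <- donors[donors$zygosity == "MZ" & !is.na(donors$pair_id), ,
               drop = FALSE]
  complete_pairs <- names(which(table(mz$pair_id) == 2L))
  mz <- mz[mz$pair_id %in% complete_pairs, , drop = FALSE]
  if (length(complete_pairs) >= 2L) {
    ord <- order(mz$pair_id, mz$twin_index)
    mzo <- mz[ord, ]
    pair_mat <- matrix(mzo$deletion_rate, ncol = 2L, byrow = TRUE)
    icc <- icc_oneway(pair_mat, ci_level = config$ci_level)
    null <- resample_unrelated_null(
      mzo$deletion_rate, mzo$pair_id,
      n_iterations = config$resample_iterations,
      seed = .iter_seed(seed, 1L))
    report$heritability <- list(
      icc = unclass(icc),
      resampling_null = unclass(null))
  } else {
    notice("fewer than 2 complete MZ pairs: heritability stage skipped")
    report$heritability <- list(skipped = "fewer than 2 complete MZ pairs")
  }

  # --- age ------------------------------------------------------------
  ages_known <- is.finite(donors$age_years)
  if (sum(ages_known) >= 3L &&
      length(unique(donors$age_years[ages_known])) >= 2L) {
    reg <- rate_age_regression(donors$age_years[ages_known],
                               donors$deletion_rate[ages_known])
    mols <- donors$total_molecules[ages_known]
    if (any(!is.finite(mols))) mols <- rep(1e6, sum(ages_known))
    pc <- power_curve(donors$age_years[ages_known], mols,
                      mean(donors$deletion_rate[ages_known]),
                      folds = config$power_folds,
                      n_replicates = config$power_replicates,
                      alpha = config$alpha, seed = .iter_seed(seed, 2L))
    logit_power <- simulate_logit_logistic_power(
      donors$age_years[ages_known], mols,
      mean(donors$deletion_rate[ages_known]),
      n_replicates = config$power_replicates, alpha = config$alpha,
      seed = .iter_seed(seed, 3L))
    report$age <- list(
      regression = unclass(reg),
      replication_model = list(
        replications_youngest = genome_replications(
          min(donors$age_years[ages_known])),
        replications_oldest = genome_replications(
          max(donors$age_years[ages_known])),
        fold_change = replication_fold_change(
          min(donors$age_years[ages_known]),
          max(donors$age_years[ages_known]))),
      power_curve = as.data.frame(pc),
      logit_logistic_power = logit_power)
  } else {
    notice("insufficient age data: age stage skipped")
    report$age <- list(skipped = "insufficient age data")
  }

  # --- covariates -----------------------------------------------------
  report$covariates <- list()
  aa <- donors$prdm9_genotype == "A/A"
  if (!is.null(donors$prdm9_genotype) && any(aa) && any(!aa)) {
    gt <- group_rate_test(donors$deletion_rate[aa],
                          donors$deletion_rate[!aa])
    report$covariates$prdm9 <- gt
  }
  if (!is.null(config$covariates)) {
    cv <- if (is.data.frame(config$covariates)) config$covariates
          else read_covariates(config$covariates)
    m <- merge(donors[c("donor_id", "pair_id", "deletion_rate")], cv,
               by = "donor_id")
    screen_lm <- function(col) {
      if (!col %in% names(m)) return(NULL)
      ok <- is.finite(m[[col]])
      if (sum(ok) < 3L || length(unique(m[[col]][ok])) < 2L) {
        notice("covariate '", col, "': insufficient data, skipped")
        return(NULL)
      }
      unclass(covariate_regression(m$deletion_rate[ok], m[[col]][ok]))
    }
    report$covariates$bmi <- screen_lm("bmi")
    report$covariates$alcohol <- screen_lm("alcohol_units_per_week")
    if ("smoking" %in% names(m) && sum(!is.na(m$smoking)) >= 4L) {
      report$covariates$smoking <- smoking_rate_test(m$deletion_rate,
                                                     m$smoking)
    } else {
      notice("smoking status: insufficient data, skipped")
    }
    snp_cols <- grep("^rs", names(m), value = TRUE)
    if (length(snp_cols) > 0L) {
      has_snp <- rowSums(!is.na(m[, snp_cols, drop = FALSE])) > 0
      mu <- m[has_snp, , drop = FALSE]
      if (nrow(mu) >= 3L) {
        report$covariates$snps <- withCallingHandlers(
          snp_association(mu$deletion_rate, mu[snp_cols],
                          pair_id = mu$pair_id),
          warning = function(w) {
            notice(conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      }
    }
  } else {
    notice("no covariate table supplied: covariate screens skipped")
  }

  if (!is.null(config$aligned_fasta)) {
    al <- read_aligned_fasta(config$aligned_fasta)
    al$identity <- vapply(seq_len(nrow(al)), function(i)
      paralog_identity(al$proximal[i], al$distal[i]), numeric(1))
    m <- merge(al[c("donor_id", "identity")],
               donors[c("donor_id", "deletion_rate")], by = "donor_id")
    if (nrow(m) >= 3L && length(unique(m$identity)) >= 2L) {
      report$covariates$paralog_identity <- list(
        per_donor = m,
        regression = unclass(covariate_regression(m$deletion_rate,
                                                  m$identity)))
    } else {
      notice("paralog identity: insufficient variation, regression skipped")
      report$covariates$paralog_identity <- list(per_donor = m)
    }
  }

  # --- outputs --------------------------------------------------------
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE)
    }
    utils::write.table(donors, file.path(config$out_dir, "donors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$age$power_curve)) {
      utils::write.table(report$age$power_curve,
                         file.path(config$out_dir, "power.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (isTRUE(config$figures)) {
      grDevices::pdf(file.path(config$out_dir, "figures.pdf"),
                     width = 6, height = 5)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot_rate_by_age(donors)
      if (length(complete_pairs) >= 2L) plot_twin_scatter(donors)
      if (!is.null(report$age$power_curve)) {
        plot_power_curve(report$age$power_curve)
      }
    }
  }
  invisible(report)
}
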