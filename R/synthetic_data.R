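#' Specification of a synthetic sperm-typing cohort
#'
#' Defaults describe the study conditions the analysis is designed for:
#' 34 men (8 MZ twin pairs, 3 DZ pairs, 12 unrelated) aged 24-67, a mean
#' deletion rate of 3.54e-5 per molecule, multiplicative between-donor
#' variation of CV 0.5 (giving a max/min fold-range of order seven across
#' 34 donors), a within-MZ-pair log-rate correlation of 0.78, no age
#' effect, and about 1e6 molecules screened per donor.
#'
#' @param n_mz_pairs,n_dz_pairs,n_unrelated Cohort composition.
#' @param age_range Sampling range of donor ages in years; co-twins share
#'   an age.
#' @param mean_rate Mean true deletion rate per molecule.
#' @param between_donor_cv Coefficient of variation of true rates across
#'   donors (log-normal).
#' @param pair_icc Fraction of log-rate variance shared within a twin
#'   pair, in \[0, 1); MZ pairs share it fully, DZ pairs with weight 1/2.
#' @param age_fold Linear fold change in true rate from youngest to oldest
#'   (>= 1; 1 = no age effect).
#' @param molecules_per_donor Molecules screened per donor (scalar or one
#'   per donor); `Inf` turns observation noise off (rates observed
#'   exactly, no plates generated).
#' @param wells_per_plate Wells per plate for the generated plate files.
#' @param n_screen_plates Deletion-screen plates per donor.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mz_pairs = 8L, n_dz_pairs = 3L, n_unrelated = 12L,
                        age_range = c(24, 67), mean_rate = 3.54e-5,
                        between_donor_cv = 0.5, pair_icc = 0.78,
                        age_fold = 1, molecules_per_donor = 1e6,
                        wells_per_plate = 96L, n_screen_plates = 10L,
                        seed = 1L) {
  if (mean_rate <= 0) stop("'mean_rate' must be positive")
  if (pair_icc < 0 || pair_icc >= 1) stop("'pair_icc' must be in [0, 1)")
  if (age_fold < 1) stop("'age_fold' must be >= 1")
  if (between_donor_cv < 0) stop("'between_donor_cv' must be >= 0")
  if (length(age_range) != 2L || age_range[1L] >= age_range[2L]) {
    stop("'age_range' must be (min, max) with min < max")
  }
  n <- 2L * n_mz_pairs + 2L * n_dz_pairs + n_unrelated
  if (n < 2L) stop("cohort must contain at least two donors")
  structure(
    list(n_mz_pairs = as.integer(n_mz_pairs),
         n_dz_pairs = as.integer(n_dz_pairs),
         n_unrelated = as.integer(n_unrelated),
         age_range = as.numeric(age_range),
         mean_rate = mean_rate,
         between_donor_cv = between_donor_cv,
         pair_icc = pair_icc,
         age_fold = age_fold,
         molecules_per_donor = molecules_per_donor,
         wells_per_plate = as.integer(wells_per_plate),
         n_screen_plates = as.integer(n_screen_plates),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort (donor table, plates, covariates)
#'
#' True per-donor log-rates are drawn from a variance-components model:
#' a pair effect carrying fraction `pair_icc` of the log-rate variance
#' (shared fully within MZ pairs, with weight 1/2 within DZ pairs) plus an
#' individual effect, around a log-normal baseline calibrated so the
#' expected rate equals `mean_rate`. An optional linear age ramp
#' multiplies rates by `age_fold` from youngest to oldest (mean
#' preserved). Observed deletion counts are Poisson at depth
#' `molecules_per_donor`; limiting-dilution calibration plates and
#' deletion-screen plates are generated by binomial well occupancy.
#' Covariates (BMI, smoking, alcohol, four SNP dosages) are drawn
#' independently of rate, with the partial availability typical of
#' registry data.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with data frames `donors`,
#'   `plates`, `covariates`, plus `true_rates` and the `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)

  n_mz <- 2L * spec$n_mz_pairs
  n_dz <- 2L * spec$n_dz_pairs
  n <- n_mz + n_dz + spec$n_unrelated
  zyg <- c(rep("MZ", n_mz), rep("DZ", n_dz), rep("U", spec$n_unrelated))
  pair_of <- c(rep(seq_len(spec$n_mz_pairs), each = 2L),
               rep(spec$n_mz_pairs + seq_len(spec$n_dz_pairs), each = 2L),
               rep(NA_integer_, spec$n_unrelated))
  twin_index <- c(rep(1:2, spec$n_mz_pairs + spec$n_dz_pairs),
                  rep(NA_integer_, spec$n_unrelated))
  pair_label <- ifelse(is.na(pair_of), NA_character_,
                       sprintf("P%02d", pair_of))
  donor_id <- sprintf("D%02d", seq_len(n))

  # co-twins share an age; span the full range so the ramp is anchored
  n_groups <- spec$n_mz_pairs + spec$n_dz_pairs + spec$n_unrelated
  group_ages <- round(seq(spec$age_range[1L], spec$age_range[2L],
                          length.out = max(n_groups, 2L)))
  group_ages <- sample(group_ages)
  grp <- pair_of
  # unrelated donors each get their own age group
  grp[is.na(pair_of)] <- spec$n_mz_pairs + spec$n_dz_pairs +
    seq_len(spec$n_unrelated)
  age <- group_ages[grp]

  sigma2 <- log(1 + spec$between_donor_cv^2)
  mu0 <- log(spec$mean_rate) - sigma2 / 2
  sd_pair <- sqrt(spec$pair_icc * sigma2)
  sd_ind <- sqrt((1 - spec$pair_icc) * sigma2)

  pair_effect <- stats::rnorm(spec$n_mz_pairs + spec$n_dz_pairs,
                              0, sd_pair)
  shared <- numeric(n)
  is_dz <- zyg == "DZ"
  shared[!is.na(pair_of)] <- pair_effect[pair_of[!is.na(pair_of)]]
  # DZ co-twins share the pair component with weight 1/2 (additive
  # genetics analogy): half the pair variance shared, half private
  shared[is_dz] <- sqrt(0.5) * shared[is_dz] +
    sqrt(0.5) * stats::rnorm(sum(is_dz), 0, sd_pair)
  shared[is.na(pair_of)] <- stats::rnorm(spec$n_unrelated, 0, sd_pair)

  log_rate <- mu0 + shared + stats::rnorm(n, 0, sd_ind)
  true_rate <- exp(log_rate)
  if (spec$age_fold > 1) {
    ramp <- 1 + (spec$age_fold - 1) *
      (age - min(age)) / (max(age) - min(age))
    true_rate <- true_rate * ramp / mean(ramp)
  }

  molecules <- rep_len(spec$molecules_per_donor, n)
  noise_free <- any(!is.finite(molecules))
  if (noise_free) {
    corrected <- rep(NA_real_, n)  # rates observed exactly
    obs_rate <- true_rate
    molecules_out <- rep(NA_real_, n)
  } else {
    corrected <- stats::rpois(n, true_rate * molecules)
    obs_rate <- corrected / molecules
    molecules_out <- molecules
  }

  prdm9 <- sample(c(rep("A/A", 29), rep("A/B", 4), "A/L20"), n,
                  replace = n > 34L)
  motif_class <- ifelse(prdm9 == "A/L20", "canonical/non-canonical",
                        "canonical")

  donors <- data.frame(
    donor_id = donor_id,
    pair_id = pair_label,
    twin_index = twin_index,
    age_years = age,
    zygosity = zyg,
    prdm9_genotype = prdm9,
    prdm9_motif_class = motif_class,
    corrected_deletion_count = corrected,
    total_molecules = molecules_out,
    deletion_rate = obs_rate,
    stringsAsFactors = FALSE
  )

  plates <- if (noise_free) {
    data.frame(plate_id = character(0), donor_id = character(0),
               role = character(0), n_wells = integer(0),
               n_positive = integer(0),
               input_mass_pg_per_well = numeric(0))
  } else {
    .generate_cohort_plates(donors, spec)
  }

  covariates <- .generate_covariates(donors)

  structure(list(donors = donors, plates = plates,
                 covariates = covariates, true_rates = true_rate,
                 spec = spec),
            class = "synthetic_cohort")
}

# Calibration plates at ~1.5 molecules/well plus deletion-screen plates
# whose positive wells follow the donor's true rate.
.generate_cohort_plates <- function(donors, spec) {
  wells <- spec$wells_per_plate
  pg_per_genome <- 6.6  # diploid genomic DNA, ~3.3 pg per haploid copy
  input_pg <- 5
  rows <- lapply(seq_len(nrow(donors)), function(i) {
    m_per_well_cal <- input_pg / (pg_per_genome / 2)
    r_cal <- stats::rbinom(1L, wells, 1 - exp(-m_per_well_cal))
    cal <- data.frame(
      plate_id = sprintf("%s_CAL1", donors$donor_id[i]),
      donor_id = donors$donor_id[i],
      role = "calibration",
      n_wells = wells,
      n_positive = r_cal,
      input_mass_pg_per_well = input_pg
    )
    n_plates <- spec$n_screen_plates
    mol_per_well <- donors$total_molecules[i] / (n_plates * wells)
    p_pos <- 1 - exp(-donors$deletion_rate[i] * mol_per_well)
    r_scr <- stats::rbinom(n_plates, wells, p_pos)
    scr <- data.frame(
      plate_id = sprintf("%s_DEL%02d", donors$donor_id[i],
                         seq_len(n_plates)),
      donor_id = donors$donor_id[i],
      role = "deletion_screen",
      n_wells = wells,
      n_positive = r_scr,
      input_mass_pg_per_well = mol_per_well * pg_per_genome / 2
    )
    rbind(cal, scr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Registry-style covariates, independent of rate; BMI available for most
# donors, smoking/alcohol for a small subset, SNP dosages for unrelated
# donors only (one per family).
.generate_covariates <- function(donors) {
  n <- nrow(donors)
  bmi <- round(stats::rnorm(n, 26, 3.5), 1)
  bmi[sample.int(n, size = min(7L, max(0L, n - 3L)))] <- NA
  lifestyle <- sample.int(n, size = min(10L, n))
  smoking <- rep(NA_character_, n)
  smoking[lifestyle] <- sample(c("never", "ex", "current"),
                               length(lifestyle), replace = TRUE,
                               prob = c(0.5, 0.3, 0.2))
  alcohol <- rep(NA_real_, n)
  alcohol[lifestyle] <- round(stats::rgamma(length(lifestyle),
                                            shape = 2, scale = 5), 1)
  snps <- c("rs1670533", "rs3796619", "rs17542943", "rs7863596")
  unrel <- donors$zygosity == "U"
  dos <- sapply(snps, function(s) {
    d <- rep(NA_integer_, n)
    d[unrel] <- stats::rbinom(sum(unrel), 2L, 0.35)
    d
  })
  out <- data.frame(donor_id = donors$donor_id, bmi = bmi,
                    smoking = smoking, alcohol_units_per_week = alcohol,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(dos))
}

#' Simulate a limiting-dilution plate series by molecule dropping
#'
#' Distributes `true_molecule_count` molecules per plate across `wells`
#' wells: each well is positive with probability
#' `1 - exp(-m/wells)`. Inverting with [poisson_occupancy()] recovers `m`
#' up to Monte-Carlo error, which makes this the round-trip companion of
#' the occupancy estimator.
#'
#' @param true_molecule_count Molecules per plate (non-negative real).
#' @param wells Wells per plate (>= 1), default 96.
#' @param n_plates Number of plates to simulate, default 1.
#' @param input_mass_pg_per_well DNA input per well in pg, default 5.
#' @param seed Optional integer seed.
#' @return A plate data frame (columns as consumed by the assay module).
#' @export
generate_plate_series <- function(true_molecule_count, wells = 96L,
                                  n_plates = 1L,
                                  input_mass_pg_per_well = 5,
                                  seed = NULL) {
  if (true_molecule_count < 0) stop("'true_molecule_count' must be >= 0")
  if (wells < 1L) stop("'wells' must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- 1 - exp(-true_molecule_count / wells)
  r <- stats::rbinom(n_plates, as.integer(wells), p)
  data.frame(
    plate_id = sprintf("SIM%04d", seq_len(n_plates)),
    donor_id = "SIM",
    role = "calibration",
    n_wells = as.integer(wells),
    n_positive = r,
    input_mass_pg_per_well = input_mass_pg_per_well
  )
}

#' Write a synthetic cohort to disk
#'
#' Writes `donors.tsv`, `plates.csv` and `covariates.tsv` in the dialects
#' the readers consume. Output is byte-identical for a fixed spec seed.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(donors = file.path(dir, "donors.tsv"),
             plates = file.path(dir, "plates.csv"),
             covariates = file.path(dir, "covariates.tsv"))
  utils::write.table(cohort$donors, paths["donors"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$plates, paths["plates"], quote = FALSE,
                   row.names = FALSE)
  utils::write.table(cohort$covariates, paths["covariates"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
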