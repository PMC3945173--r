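#' Read a per-donor summary table (TSV)
#'
#' Columns: `donor_id`, `pair_id`, `twin_index`, `age_years`, `zygosity`
#' (`MZ`/`DZ`/`U`), `prdm9_genotype`, `prdm9_motif_class`,
#' `corrected_deletion_count`, `total_molecules`, `deletion_rate`.
#'
#' @param path Path to the tab-separated donor table.
#' @return Data frame of donors.
#' @export
read_donors <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("donor_id", "age_years", "zygosity", "deletion_rate")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols) > 0L) {
    stop("donor table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(d$deletion_rate) | d$deletion_rate < 0)
  if (length(bad) > 0L) {
    stop("donor table ", path, ": non-finite or negative deletion_rate ",
         "at data line(s) ", paste(bad, collapse = ", "))
  }
  d
}

#' Read a plate table (CSV)
#'
#' Columns: `plate_id`, `donor_id`, `role` (`calibration` or
#' `deletion_screen`), `n_wells`, `n_positive`, `input_mass_pg_per_well`.
#'
#' @param path Path to the CSV.
#' @return Data frame of plates.
#' @export
read_plates <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plate_id", "donor_id", "role", "n_wells", "n_positive",
           "input_mass_pg_per_well")
  missing_cols <- setdiff(req, names(p))
  if (length(missing_cols) > 0L) {
    stop("plate table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_role <- which(!p$role %in% c("calibration", "deletion_screen"))
  if (length(bad_role) > 0L) {
    stop("plate table ", path, ": unknown role at data line(s) ",
         paste(bad_role, collapse = ", "))
  }
  p
}

#' Read a covariate table (TSV)
#'
#' Keyed by `donor_id`; optional columns `bmi`, `smoking`,
#' `alcohol_units_per_week` and any number of SNP dosage columns (names
#' starting `rs`).
#'
#' @param path Path to the tab-separated covariate table.
#' @return Data frame of covariates.
#' @export
read_covariates <- function(path) {
  cv <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"donor_id" %in% names(cv)) {
    stop("covariate table ", path, " lacks a 'donor_id' column")
  }
  cv
}

#' Read aligned paralog hotspot pairs from FASTA
#'
#' Expects, per donor, two aligned records named
#' `<donor_id> proximal` and `<donor_id> distal` (first token donor id,
#' second token the repeat). Gap characters `-` are allowed.
#'
#' @param path Path to the aligned FASTA.
#' @return Data frame with columns `donor_id`, `proximal`, `distal`.
#' @export
read_aligned_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readBStringSet(path)
  toks <- strsplit(trimws(names(seqs)), "\\s+")
  donor <- vapply(toks, `[`, character(1), 1L)
  role <- vapply(toks, `[`, character(1), 2L)
  if (any(is.na(role)) || !all(role %in% c("proximal", "distal"))) {
    stop("each FASTA record must be named '<donor_id> proximal|distal'")
  }
  ids <- unique(donor)
  rows <- lapply(ids, function(id) {
    pr <- which(donor == id & role == "proximal")
    di <- which(donor == id & role == "distal")
    if (length(pr) != 1L || length(di) != 1L) {
      stop("donor ", id, " must have exactly one proximal and one ",
           "distal record")
    }
    data.frame(donor_id = id,
               proximal = as.character(seqs[[pr]]),
               distal = as.character(seqs[[di]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-donor rate estimation from a plate table
#'
#' For each donor: calibrate the limiting-dilution series, convert the
#' deletion-screen DNA input into total molecules screened using the
#' per-sample pg-per-haploid-genome, Poisson-correct the positive wells
#' and attach the exact CI.
#'
#' @param plates Plate data frame (see [read_plates()]).
#' @param ci_level Confidence level, default 0.95.
#' @return Data frame, one row per donor: `donor_id`,
#'   `pg_per_haploid_genome`, `corrected_deletion_count`,
#'   `total_molecules`, `deletion_rate`, `ci_low`, `ci_high`.
#' @export
estimate_donor_rates <- function(plates, ci_level = 0.95) {
  rows <- lapply(split(plates, plates$donor_id), function(pl) {
    cal <- calibrate_dilution(pl[pl$role == "calibration", , drop = FALSE])
    scr <- pl[pl$role == "deletion_screen", , drop = FALSE]
    if (nrow(scr) == 0L) stop("donor ", pl$donor_id[1L],
                              " has no deletion_screen plates")
    count <- corrected_deletion_count(scr)
    total <- sum(scr$n_wells * scr$input_mass_pg_per_well) /
      cal$pg_per_haploid_genome
    est <- estimate_rate(count, total, ci_level = ci_level)
    data.frame(donor_id = pl$donor_id[1L],
               pg_per_haploid_genome = cal$pg_per_haploid_genome,
               corrected_deletion_count = est$corrected_count,
               total_molecules = est$total_molecules,
               deletion_rate = est$rate,
               ci_low = est$ci_low,
               ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
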