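#' Poisson occupancy estimate of amplifiable molecules on a plate
#'
#' Inverts the Poisson occupancy of a limiting-dilution PCR plate: if
#' molecules are distributed independently across `N` wells and `R` wells
#' score positive, the estimated number of molecules on the plate is
#' \eqn{-N \log((N - R)/N)}.
#'
#' @param n_wells Number of reactions (wells) on the plate; positive integer.
#' @param n_positive Number of positive reactions observed; `0 <= R < N`.
#'   A saturated plate (`R == N`) is an error, not a clamped value: the
#'   estimator diverges and the sample must be assayed at higher dilution.
#' @return Estimated number of amplifiable molecules (non-negative numeric,
#'   vectorised over plates). `0` when `n_positive` is `0`.
#' @examples
#' poisson_occupancy(96, 48)   # 96 * log(2)
#' poisson_occupancy(88, 3)
#' @export
poisson_occupancy <- function(n_wells, n_positive) {
  if (length(n_wells) != length(n_positive)) {
    n <- max(length(n_wells), length(n_positive))
    n_wells <- rep_len(n_wells, n)
    n_positive <- rep_len(n_positive, n)
  }
  if (any(!is.finite(n_wells)) || any(n_wells <= 0) ||
      any(n_wells != round(n_wells))) {
    stop("'n_wells' must be a positive integer count of reactions")
  }
  if (any(!is.finite(n_positive)) || any(n_positive < 0) ||
      any(n_positive != round(n_positive))) {
    stop("'n_positive' must be a non-negative integer count")
  }
  if (any(n_positive > n_wells)) {
    stop("'n_positive' cannot exceed 'n_wells'")
  }
  if (any(n_positive == n_wells)) {
    stop("saturated plate (all wells positive): the occupancy estimate ",
         "diverges; increase dilution and re-assay")
  }
  -n_wells * log((n_wells - n_positive) / n_wells)
}

.validate_plates <- function(plates, role = NULL) {
  req <- c("n_wells", "n_positive", "input_mass_pg_per_well")
  if (!is.data.frame(plates) || !all(req %in% names(plates))) {
    stop("'plates' must be a data frame with columns ",
         paste(req, collapse = ", "))
  }
  if (!is.null(role) && "role" %in% names(plates)) {
    plates <- plates[plates$role == role, , drop = FALSE]
  }
  if (nrow(plates) == 0L) stop("no plates supplied")
  if (any(!is.finite(plates$input_mass_pg_per_well)) ||
      any(plates$input_mass_pg_per_well <= 0)) {
    stop("'input_mass_pg_per_well' must be positive and finite")
  }
  plates
}

#' Calibrate a limiting-dilution series
#'
#' Sums Poisson-occupancy estimates over calibration plates for one sample
#' and converts total DNA input mass into the mass of one amplifiable
#' haploid genome, the per-sample calibration used to translate DNA input
#' into molecules screened.
#'
#' @param plates Data frame of calibration plates with columns `n_wells`,
#'   `n_positive` and `input_mass_pg_per_well` (picograms per well). If a
#'   `role` column is present only rows with `role == "calibration"` are
#'   used.
#' @return An object of class `dilution_calibration`: a list with
#'   `amplifiable_molecules_total`, `total_input_mass_pg` and
#'   `pg_per_haploid_genome`.
#' @examples
#' plates <- data.frame(n_wells = 96, n_positive = 48,
#'                      input_mass_pg_per_well = 5)
#' calibrate_dilution(plates)
#' @export
calibrate_dilution <- function(plates) {
  plates <- .validate_plates(plates, role = "calibration")
  molecules <- sum(poisson_occupancy(plates$n_wells, plates$n_positive))
  mass <- sum(plates$n_wells * plates$input_mass_pg_per_well)
  if (molecules <= 0) {
    stop("zero occupancy across calibration plates: the mass per ",
         "amplifiable genome is undefined")
  }
  structure(
    list(amplifiable_molecules_total = molecules,
         total_input_mass_pg = mass,
         pg_per_haploid_genome = mass / molecules),
    class = "dilution_calibration"
  )
}

#' @export
print.dilution_calibration <- function(x, ...) {
  cat("Limiting-dilution calibration\n")
  cat(sprintf("  amplifiable molecules: %.3f\n",
              x$amplifiable_molecules_total))
  cat(sprintf("  total input mass:      %.1f pg\n", x$total_input_mass_pg))
  cat(sprintf("  pg per haploid genome: %.4f\n", x$pg_per_haploid_genome))
  invisible(x)
}

#' Poisson-corrected deletion-molecule count over screen plates
#'
#' Applies the occupancy correction to deletion-positive wells, plate by
#' plate, and sums. The correction accounts for wells that received more
#' than one deletion molecule, so the corrected count is always at least
#' the raw positive count (equal only when no wells are positive).
#'
#' @param plates Data frame of deletion-screen plates (columns as in
#'   [calibrate_dilution()]; rows with `role == "deletion_screen"` are used
#'   when a `role` column is present).
#' @param pool If `TRUE`, pool all wells into a single (N, R) pair before
#'   correcting instead of correcting per plate. Pooling is only
#'   appropriate when all plates received the same input mass per well.
#' @return Non-negative numeric corrected count of deletion molecules.
#' @export
corrected_deletion_count <- function(plates, pool = FALSE) {
  plates <- .validate_plates(plates, role = "deletion_screen")
  if (pool) {
    poisson_occupancy(sum(plates$n_wells), sum(plates$n_positive))
  } else {
    sum(poisson_occupancy(plates$n_wells, plates$n_positive))
  }
}

#' Exact Poisson confidence interval on a (possibly non-integer) count
#'
#' Chi-square inversion of the exact Poisson tail: lower bound
#' \eqn{\chi^2(\alpha/2, 2c)/2}, upper bound
#' \eqn{\chi^2(1-\alpha/2, 2c+2)/2}. Occupancy correction produces
#' real-valued counts; the chi-square form extends continuously to
#' non-integer `count` (degrees of freedom `2c` and `2c + 2` with real
#' `c`), which is how intervals are drawn on corrected counts.
#'
#' @param count Non-negative count (vectorised; need not be an integer).
#' @param level Confidence level, default `0.95`.
#' @return A two-column matrix with columns `lower` and `upper`.
#' @examples
#' poisson_ci(0)    # upper ~ 3.689
#' poisson_ci(10)
#' @export
poisson_ci <- function(count, level = 0.95) {
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("'count' must be non-negative and finite")
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("'level' must be a single value in (0, 1)")
  }
  alpha <- 1 - level
  lower <- ifelse(count == 0, 0, 0.5 * stats::qchisq(alpha / 2, 2 * count))
  upper <- 0.5 * stats::qchisq(1 - alpha / 2, 2 * count + 2)
  cbind(lower = lower, upper = upper)
}

#' Deletion-rate estimate with exact Poisson confidence interval
#'
#' Converts a Poisson-corrected deletion-molecule count and the total
#' number of molecules screened into a per-molecule deletion rate. The
#' confidence interval is the exact Poisson interval on the count
#' ([poisson_ci()]) divided by the total molecules; calibration
#' uncertainty is not propagated.
#'
#' @param corrected_count Poisson-corrected count(s) of deletion molecules.
#' @param total_molecules Total amplifiable molecules screened; positive.
#' @param ci_level Confidence level, default `0.95`.
#' @return A data frame of class `rate_estimate` with columns
#'   `corrected_count`, `total_molecules`, `rate`, `ci_low`, `ci_high`,
#'   `ci_level`; one row per input element.
#' @examples
#' estimate_rate(10, 1e6)
#' @export
estimate_rate <- function(corrected_count, total_molecules, ci_level = 0.95) {
  if (any(!is.finite(total_molecules)) || any(total_molecules <= 0)) {
    stop("'total_molecules' must be positive and finite")
  }
  if (any(!is.finite(corrected_count)) || any(corrected_count < 0)) {
    stop("'corrected_count' must be non-negative and finite")
  }
  ci <- poisson_ci(corrected_count, level = ci_level)
  out <- data.frame(
    corrected_count = corrected_count,
    total_molecules = total_molecules,
    rate = corrected_count / total_molecules,
    ci_low = ci[, "lower"] / total_molecules,
    ci_high = ci[, "upper"] / total_molecules,
    ci_level = ci_level
  )
  rownames(out) <- NULL
  class(out) <- c("rate_estimate", "data.frame")
  out
}

#' Cohort-level summary of deletion rates
#'
#' @param rates Numeric vector of per-donor deletion rates (or a donor
#'   data frame with a `deletion_rate` column); at least two finite rates.
#' @return A list with `n`, `mean_rate`, `sem`, `min_rate`, `max_rate` and
#'   `fold_range` (max/min).
#' @export
cohort_summary <- function(rates) {
  if (is.data.frame(rates)) {
    if (!"deletion_rate" %in% names(rates)) {
      stop("donor data frame must contain a 'deletion_rate' column")
    }
    rates <- rates$deletion_rate
  }
  rates <- rates[is.finite(rates)]
  if (length(rates) < 2L) {
    stop("at least two donors with finite rates are required")
  }
  list(
    n = length(rates),
    mean_rate = mean(rates),
    sem = stats::sd(rates) / sqrt(length(rates)),
    min_rate = min(rates),
    max_rate = max(rates),
    fold_range = if (min(rates) > 0) max(rates) / min(rates) else Inf
  )
}
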