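#' Plot deletion rate against donor age
#'
#' Scatter of per-donor deletion rate versus age at sampling, with 95%
#' CI whiskers when `ci_low`/`ci_high` columns are present.
#'
#' @param donors Donor data frame with `age_years`, `deletion_rate` and
#'   optionally `ci_low`, `ci_high`.
#' @return Invisibly, `NULL`; draws on the current device.
#' @export
plot_rate_by_age <- function(donors) {
  ok <- is.finite(donors$age_years) & is.finite(donors$deletion_rate)
  d <- donors[ok, , drop = FALSE]
  ylim <- range(c(d$deletion_rate, d$ci_low, d$ci_high), na.rm = TRUE)
  plot(d$age_years, d$deletion_rate, pch = 19, ylim = ylim,
       xlab = "Age at sampling (years)",
       ylab = "Deletion rate per molecule",
       main = "Deletion rate vs donor age")
  if (all(c("ci_low", "ci_high") %in% names(d))) {
    graphics::segments(d$age_years, d$ci_low, d$age_years, d$ci_high,
                       col = "grey50")
  }
  invisible(NULL)
}

#' Plot MZ co-twin deletion rates against one another
#'
#' @param donors Donor data frame with `zygosity`, `pair_id`,
#'   `twin_index` and `deletion_rate`.
#' @return Invisibly, `NULL`.
#' @export
plot_twin_scatter <- function(donors) {
  mz <- donors[donors$zygosity == "MZ" & !is.na(donors$pair_id), ,
               drop = FALSE]
  mz <- mz[order(mz$pair_id, mz$twin_index), ]
  m <- matrix(mz$deletion_rate, ncol = 2L, byrow = TRUE)
  lim <- range(m)
  plot(m[, 1L], m[, 2L], pch = 19, xlim = lim, ylim = lim,
       xlab = "Co-twin 1 deletion rate", ylab = "Co-twin 2 deletion rate",
       main = "MZ co-twin deletion rates")
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(NULL)
}

#' Plot a paternal-age power curve
#'
#' @param pc A [power_curve()] data frame.
#' @return Invisibly, `NULL`.
#' @export
plot_power_curve <- function(pc) {
  plot(pc$fold, 100 * pc$power, type = "b", pch = 19, ylim = c(0, 100),
       xlab = "Linear fold change in rate across the age span",
       ylab = "Power (%)",
       main = sprintf("Power to detect a linear age effect (alpha = %g)",
                      pc$alpha[1L]))
  graphics::abline(h = 100 * pc$alpha[1L], lty = 3, col = "grey50")
  invisible(NULL)
}
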