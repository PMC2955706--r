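#' Model constants for one cell cycle
#'
#' Collects every constant of the cell-cycle control model in one object.
#' The three decision rules are parameterised as follows.
#'
#' * **Interdivision timer** (`timer_threshold`): the cell enters the
#'   division phase when its accrued growth-rate-times-time signal reaches
#'   this dimensionless constant. Before commitment the signal accrues at
#'   the instantaneous growth rate, so it equals `log(V/V0)`; after
#'   commitment it accrues at the growth rate memorised at commitment,
#'   continuing even in darkness. The default `log(4.1)` (about 1.411)
#'   makes an uninterrupted cell divide at 4.1 times its initial volume
#'   and its rate-duration product equal to about 1.4.
#' * **Commitment sizer** (`commitment_ratio`): a cell passes the primary
#'   arrest point only once its volume reaches this multiple of its
#'   initial volume while growing; default 2. Uncommitted cells arrest in
#'   darkness indefinitely.
#' * **Mitotic sizer** (`mitotic_cutpoint_low`, `mitotic_cutpoint_high`):
#'   the final-to-initial volume ratio maps to the number of daughters —
#'   below the low cutpoint no division (tied to the commitment ratio, 2),
#'   between the cutpoints binary fission (2 daughters), at or above the
#'   high cutpoint (default 2.9) two rounds of fission (4 daughters).
#'   With `stochastic_bands = TRUE`, seeded runs draw each cell's
#'   cutpoints uniformly from the observed indeterminate bands
#'   (1.8--2.2 and 2.7--3.1) instead of using the deterministic values.
#'
#' Division-phase subphases (shrinkage, rotation, one or two rounds of
#' mitosis, mitosis completion) have fixed durations independent of light;
#' the defaults are plausible placeholders on the order of fractions of an
#' hour — their light-independence, not their magnitude, is the modelled
#' property.
#'
#' Noise terms are between-cell lognormal coefficients of variation applied
#' in seeded simulations: `cv_mu` on the growth rate, `cv_threshold` on the
#' timer threshold, `cv_measurement` on each sampled volume. `v0_mean` and
#' `v0_cv` describe the initial-volume distribution (79.7 +/- 12.6 um^3).
#'
#' @param timer_threshold Dimensionless timer threshold; default `log(4.1)`.
#' @param commitment_ratio Volume-doubling gate for commitment; default 2.
#' @param mitotic_cutpoint_low Ratio below which no division occurs;
#'   defaults to `commitment_ratio`.
#' @param mitotic_cutpoint_high Ratio at which 4 daughters replace 2;
#'   default 2.9.
#' @param calib A [growth_calibration()].
#' @param subphase_durations Named numeric vector of division subphase
#'   durations in hours: `shrinkage`, `rotation`, `first_mitosis`,
#'   `second_mitosis`, `mitosis_completion`.
#' @param cv_mu,cv_threshold,cv_measurement Between-cell and measurement
#'   coefficients of variation (dimensionless, >= 0).
#' @param v0_mean,v0_cv Mean (um^3) and CV of the initial-volume
#'   distribution.
#' @param stochastic_bands If `TRUE`, seeded simulations draw per-cell
#'   mitotic cutpoints from the indeterminate bands.
#' @param shrinkage_fraction Fraction of the final volume lost during the
#'   shrinkage subphase (rendering convention used by the synthetic-data
#'   generator and the division-entry detector).
#' @return An object of class `cycle_params`.
#' @export
cycle_params <- function(timer_threshold = log(4.1),
                         commitment_ratio = 2,
                         mitotic_cutpoint_low = commitment_ratio,
                         mitotic_cutpoint_high = 2.9,
                         calib = default_growth_calibration(),
                         subphase_durations = c(shrinkage = 0.3,
                                                rotation = 0.3,
                                                first_mitosis = 0.5,
                                                second_mitosis = 0.5,
                                                mitosis_completion = 0.4),
                         cv_mu = 0.25,
                         cv_threshold = 0.1,
                         cv_measurement = 0.03,
                         v0_mean = 79.7,
                         v0_cv = 12.6 / 79.7,
                         stochastic_bands = FALSE,
                         shrinkage_fraction = 0.1) {
  stopifnot(inherits(calib, "growth_calibration"))
  need <- c("shrinkage", "rotation", "first_mitosis", "second_mitosis",
            "mitosis_completion")
  if (!all(need %in% names(subphase_durations)))
    stop("subphase_durations must name: ",
         paste(need, collapse = ", "), call. = FALSE)
  subphase_durations <- subphase_durations[need]
  if (any(subphase_durations < 0))
    stop("subphase durations must be non-negative", call. = FALSE)
  if (commitment_ratio <= 1)
    stop("commitment_ratio must exceed 1", call. = FALSE)
  if (timer_threshold <= log(commitment_ratio))
    stop("timer_threshold must exceed log(commitment_ratio); ",
         "otherwise cells would divide before committing", call. = FALSE)
  if (mitotic_cutpoint_high <= mitotic_cutpoint_low ||
      mitotic_cutpoint_high >= exp(timer_threshold) + 1e-9)
    stop("mitotic_cutpoint_high must lie between mitotic_cutpoint_low ",
         "and exp(timer_threshold)", call. = FALSE)
  cvs <- c(cv_mu, cv_threshold, cv_measurement, v0_cv)
  if (any(!is.finite(cvs)) || any(cvs < 0))
    stop("all CVs must be finite and non-negative", call. = FALSE)
  if (v0_mean <= 0) stop("v0_mean must be positive", call. = FALSE)
  if (shrinkage_fraction < 0 || shrinkage_fraction >= 1)
    stop("shrinkage_fraction must be in [0, 1)", call. = FALSE)
  structure(list(timer_threshold = timer_threshold,
                 commitment_ratio = commitment_ratio,
                 mitotic_cutpoint_low = mitotic_cutpoint_low,
                 mitotic_cutpoint_high = mitotic_cutpoint_high,
                 calib = calib,
                 subphase_durations = subphase_durations,
                 cv_mu = cv_mu,
                 cv_threshold = cv_threshold,
                 cv_measurement = cv_measurement,
                 v0_mean = v0_mean,
                 v0_cv = v0_cv,
                 stochastic_bands = stochastic_bands,
                 shrinkage_fraction = shrinkage_fraction),
            class = "cycle_params")
}

#' @export
print.cycle_params <- function(x, ...) {
  cat("Cell-cycle model constants\n")
  cat(sprintf("  timer threshold        : %.4f (= log(%.3f))\n",
              x$timer_threshold, exp(x$timer_threshold)))
  cat(sprintf("  commitment ratio       : %.2f\n", x$commitment_ratio))
  cat(sprintf("  mitotic cutpoints      : %.2f / %.2f\n",
              x$mitotic_cutpoint_low, x$mitotic_cutpoint_high))
  cat(sprintf("  division phase total   : %.2f h\n",
              sum(x$subphase_durations)))
  cat(sprintf("  noise CVs (mu/thr/meas): %.2f / %.2f / %.2f\n",
              x$cv_mu, x$cv_threshold, x$cv_measurement))
  cat(sprintf("  initial volume         : %.1f um^3 (CV %.2f)\n",
              x$v0_mean, x$v0_cv))
  invisible(x)
}
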