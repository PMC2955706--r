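#' Single-cell volume trajectory
#'
#' A sampled (time, volume) series for one cell, tied to the light
#' schedule it was recorded under. Trajectories are assumed to start at
#' the completion of the mother's mitosis, so the first sample defines the
#' cycle start.
#'
#' @param cell_id Identifier (coerced to character).
#' @param time_h Sample times (h), strictly increasing; sampling may be
#'   irregular.
#' @param volume_um3 Volumes (um^3), positive.
#' @param schedule The [light_schedule()] the cell experienced.
#' @param annotations Optional list of ground-truth annotations (as
#'   attached by [generate_cohort()]).
#' @return An object of class `volume_trajectory`: a data frame with
#'   columns `time_h`, `volume_um3` and attributes `cell_id`, `schedule`,
#'   `annotations`.
#' @export
volume_trajectory <- function(cell_id, time_h, volume_um3, schedule,
                              annotations = NULL) {
  stopifnot(inherits(schedule, "light_schedule"),
            is.numeric(time_h), is.numeric(volume_um3),
            length(time_h) == length(volume_um3))
  if (length(time_h) == 0L)
    stop("trajectory must contain at least one sample", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0))
    stop("volumes must be positive and finite", call. = FALSE)
  out <- data.frame(time_h = time_h, volume_um3 = volume_um3)
  attr(out, "cell_id") <- as.character(cell_id)[1L]
  attr(out, "schedule") <- schedule
  attr(out, "annotations") <- annotations
  class(out) <- c("volume_trajectory", "data.frame")
  out
}

#' @export
print.volume_trajectory <- function(x, ...) {
  cat(sprintf("Volume trajectory '%s': %d samples over %.2f h (%s)\n",
              attr(x, "cell_id"), nrow(x),
              diff(range(x$time_h)),
              schedule_condition(attr(x, "schedule"))))
  invisible(x)
}

#' Detect division-phase entry in a volume trajectory
#'
#' Division-phase entry is marked morphologically by the cell detaching
#' its membrane from the wall and shrinking; in a volume series the only
#' available signature is a sustained drop. The detector first suppresses
#' measurement noise with a running median (window `smooth_h` hours; a
#' raw running maximum over thousands of noisy samples would be biased
#' upward and trigger false drops), then finds the first stretch of
#' consecutive smoothed samples lying below `(1 - drop_fraction)` times
#' the smoothed running maximum that is at least `min_samples` long and
#' spans at least the smoothing window in time (a real division drop
#' persists from shrinkage to hatching, while noise excursions decay on
#' the smoothing timescale). The entry
#' time reported is the onset of the decline: from the first
#' below-threshold sample the detector walks back while the smoothed
#' series is strictly declining, which lands on the true entry sample for
#' noiseless data (a dark plateau before entry does not strictly decline,
#' so the walk stops at shrinkage onset, not at light-off). Returns `NA`
#' if the cell never divided.
#'
#' @param traj A [volume_trajectory()].
#' @param drop_fraction Relative drop from the running maximum that
#'   qualifies as shrinkage (default 0.05, i.e. 5%).
#' @param min_samples Number of consecutive below-threshold samples
#'   required to call the drop sustained (default 5).
#' @param smooth_h Running-median window in hours (default 0.5); windows
#'   wider than the record are clipped.
#' @return Entry time in hours, or `NA_real_`.
#' @export
detect_division_entry <- function(traj, drop_fraction = 0.05,
                                  min_samples = 5L, smooth_h = 0.5) {
  stopifnot(inherits(traj, "volume_trajectory"),
            drop_fraction > 0, drop_fraction < 1, min_samples >= 1L,
            smooth_h >= 0)
  v <- traj$volume_um3
  n <- length(v)
  if (n < min_samples) return(NA_real_)
  sm <- smooth_series(v, traj$time_h, smooth_h)
  vs <- sm$values
  below <- vs < (1 - drop_fraction) * cummax(vs)
  run <- rle(below)
  ends <- cumsum(run$lengths)
  # a genuine drop persists from shrinkage to hatching; noise excursions
  # decorrelate after one smoothing window
  need <- max(min_samples, sm$k)
  hit <- which(run$values & run$lengths >= need)
  if (length(hit) == 0L) return(NA_real_)
  i <- ends[hit[1L]] - run$lengths[hit[1L]] + 1L
  # walk back to the onset of the decline; running-median ties are broken
  # on the raw series, which still declines strictly during shrinkage but
  # is flat on a pre-entry dark plateau
  while (i > 1L &&
         (vs[i - 1L] > vs[i] ||
          (vs[i - 1L] == vs[i] && v[i - 1L] > v[i]))) i <- i - 1L
  traj$time_h[i]
}

# Running median over a window of smooth_h hours, but never narrower than
# 15 samples (a too-narrow window leaves the running maximum biased by
# noise); degrades gracefully on short records. Returns the smoothed
# series and the window actually used.
smooth_series <- function(v, time_h, smooth_h) {
  n <- length(v)
  if (smooth_h <= 0 || n < 3L) return(list(values = v, k = 1L))
  dt <- stats::median(diff(time_h))
  k <- max(floor(smooth_h / dt), 15L)
  k <- min(k, n - 1L)
  if (k %% 2L == 0L) k <- k - 1L
  if (k < 3L) return(list(values = v, k = 1L))
  # constant end rule: raw edge values would leak noise into the running
  # maximum and fake an early drop
  list(values = as.numeric(stats::runmed(v, k, endrule = "constant")),
       k = k)
}

#' Segment a trajectory into interdivision and division phases
#'
#' The cycle starts at the first sample; the division phase starts at the
#' detected sustained volume drop.
#'
#' @inheritParams detect_division_entry
#' @return An object of class `phase_segmentation`: a list with
#'   `t_cycle_start`, `t_division_entry` (`NA` if none) and
#'   `interdivision_duration`.
#' @export
segment_phases <- function(traj, drop_fraction = 0.05, min_samples = 5L,
                           smooth_h = 0.5) {
  t0 <- traj$time_h[1L]
  t_entry <- detect_division_entry(traj, drop_fraction, min_samples,
                                   smooth_h)
  structure(list(t_cycle_start = t0,
                 t_division_entry = t_entry,
                 interdivision_duration = t_entry - t0),
            class = "phase_segmentation")
}

# Light periods of a schedule: rows with par above dark_par, labelled
# L1, L2, ... in time order.
light_periods <- function(schedule, dark_par = 0) {
  seg <- as.data.frame(schedule)
  lit <- seg[seg$par > dark_par, , drop = FALSE]
  if (nrow(lit)) lit$label <- paste0("L", seq_len(nrow(lit)))
  lit
}

#' Estimate the growth rate within each light period
#'
#' Fits the exponential growth model (log-linear least squares, see
#' [fit_exponential()]) separately within every illuminated interval of
#' the schedule, clipped to the interdivision phase. Dark intervals are
#' excluded: cells neither grow nor shrink in darkness, so including them
#' would bias the rate downward. A light period with fewer than
#' `min_points` usable samples is reported as `NA`, not an error.
#'
#' @param traj A [volume_trajectory()].
#' @param seg A [segment_phases()] result.
#' @param min_points Minimum samples needed to fit one period.
#' @return Named numeric vector of rates (per hour), one per light period
#'   (`L1`, `L2`, ...).
#' @export
estimate_mu_per_light_period <- function(traj, seg, min_points = 3L) {
  stopifnot(inherits(traj, "volume_trajectory"),
            inherits(seg, "phase_segmentation"))
  schedule <- attr(traj, "schedule")
  lit <- light_periods(schedule)
  t_stop <- if (is.na(seg$t_division_entry)) Inf else seg$t_division_entry
  mus <- stats::setNames(rep(NA_real_, nrow(lit)), lit$label)
  for (i in seq_len(nrow(lit))) {
    sel <- traj$time_h >= lit$t_start[i] &
      traj$time_h < min(lit$t_end[i], t_stop)
    if (sum(sel) >= min_points) {
      fit <- fit_exponential(traj$time_h[sel], traj$volume_um3[sel])
      mus[i] <- fit$mu
    }
  }
  mus
}

# Noise-robust volume level near a time point: median of the last
# (or first) k samples at or before (after) t. k is kept small so that
# the growth over the window stays well below the measurement noise.
local_volume <- function(traj, t, k = 3L, side = c("before", "after")) {
  side <- match.arg(side)
  idx <- if (side == "before") which(traj$time_h <= t)
         else which(traj$time_h >= t)
  if (length(idx) == 0L) return(NA_real_)
  idx <- if (side == "before") utils::tail(idx, k) else utils::head(idx, k)
  stats::median(traj$volume_um3[idx])
}

#' Timer products and volume ratios for one analysed cell
#'
#' Computes the quantities used to characterise interdivision control:
#' the product of the first-light-period growth rate and the full
#' interdivision duration (`muT`); the dark-adjusted product
#' `mu_L1 * (T - T_dark)` which discounts time spent arrested in darkness
#' before commitment; and, for schedules with two light periods, the
#' additive accrual `sum_i mu_i * T_i` over illuminated time. When the
#' schedule contains no darkness the dark-adjusted product equals the raw
#' product.
#'
#' @param traj A [volume_trajectory()].
#' @param seg A [segment_phases()] result with a division entry.
#' @param mus Per-light-period rates from
#'   [estimate_mu_per_light_period()].
#' @return A one-row data frame: `condition`, `T`, `mu_L1`, `mu_L2`,
#'   `muT`, `muT_dark_adjusted`, `accrual_sum`, `ratio_final`,
#'   `ratio_at_light_off`.
#' @export
compute_products <- function(traj, seg, mus) {
  stopifnot(inherits(traj, "volume_trajectory"),
            inherits(seg, "phase_segmentation"))
  if (is.na(seg$t_division_entry))
    stop("trajectory has no division entry; nothing to compute",
         call. = FALSE)
  if (length(mus) < 1L || is.na(mus[1L]))
    stop("growth rate of the first light period is missing", call. = FALSE)
  schedule <- attr(traj, "schedule")
  condition <- schedule_condition(schedule)
  T_total <- seg$interdivision_duration
  t_entry <- seg$t_division_entry
  seg_df <- as.data.frame(schedule)
  # darkness experienced before entry
  dark <- seg_df[seg_df$par <= 0, , drop = FALSE]
  t_dark <- if (nrow(dark))
    sum(pmax(pmin(dark$t_end, t_entry) - pmin(dark$t_start, t_entry), 0))
  else 0
  # additive accrual over illuminated time, when every period was fitted
  lit <- light_periods(schedule)
  accrual <- NA_real_
  if (nrow(lit) >= 2L && !anyNA(mus[lit$label])) {
    durs <- pmax(pmin(lit$t_end, t_entry) - pmin(lit$t_start, t_entry), 0)
    accrual <- sum(mus[lit$label] * durs)
  }
  v0_meas <- local_volume(traj, traj$time_h[1L], side = "after")
  v_final <- local_volume(traj, t_entry + 1e-9, side = "before")
  ratio_light_off <- NA_real_
  if (nrow(dark) && dark$t_start[1L] < t_entry)
    ratio_light_off <- local_volume(traj, dark$t_start[1L],
                                    side = "before") / v0_meas
  data.frame(condition = condition,
             T = T_total,
             mu_L1 = unname(mus[1L]),
             mu_L2 = if (length(mus) >= 2L) unname(mus[2L]) else NA_real_,
             muT = unname(mus[1L]) * T_total,
             muT_dark_adjusted = unname(mus[1L]) * (T_total - t_dark),
             accrual_sum = accrual,
             ratio_final = v_final / v0_meas,
             ratio_at_light_off = ratio_light_off)
}

#' Classify the number of daughter cells
#'
#' If the trajectory carries generator annotations, the daughter count is
#' recovered from the annotated volume partition; otherwise the mitotic
#' sizer is applied to the measured final-to-initial volume ratio. A
#' trajectory without division entry is classified as 0.
#'
#' @param traj A [volume_trajectory()].
#' @param seg A [segment_phases()] result.
#' @param params A [cycle_params()] (for the sizer cutpoints).
#' @param use_annotation Recover the count from ground-truth annotations
#'   when present (default `TRUE`).
#' @return Integer in `{0, 2, 4}`.
#' @export
classify_division_number <- function(traj, seg, params = cycle_params(),
                                     use_annotation = TRUE) {
  stopifnot(inherits(traj, "volume_trajectory"),
            inherits(seg, "phase_segmentation"))
  if (is.na(seg$t_division_entry)) return(0L)
  ann <- attr(traj, "annotations")
  if (use_annotation && !is.null(ann$daughter_volumes))
    return(length(ann$daughter_volumes))
  v0_meas <- local_volume(traj, traj$time_h[1L], side = "after")
  v_final <- local_volume(traj, seg$t_division_entry + 1e-9,
                          side = "before")
  as.integer(mitotic_sizer(v_final / v0_meas, params))
}

#' Analyse one trajectory end to end
#'
#' Convenience driver: segments the trajectory, estimates per-light-period
#' growth rates, computes the timer products and classifies the division
#' number. Cells without a division entry yield `NA` products and
#' `division_number = 0`.
#'
#' @inheritParams detect_division_entry
#' @param params A [cycle_params()].
#' @param use_annotation Passed to [classify_division_number()].
#' @return A one-row data frame (cell_id, condition, entry time, duration,
#'   rates, products, ratios, division number).
#' @export
analyse_trajectory <- function(traj, params = cycle_params(),
                               drop_fraction = 0.05, min_samples = 5L,
                               smooth_h = 0.5, use_annotation = TRUE) {
  seg <- segment_phases(traj, drop_fraction, min_samples, smooth_h)
  base <- data.frame(cell_id = attr(traj, "cell_id"),
                     condition = schedule_condition(attr(traj, "schedule")),
                     t_division_entry = seg$t_division_entry,
                     T = seg$interdivision_duration,
                     mu_L1 = NA_real_, mu_L2 = NA_real_, muT = NA_real_,
                     muT_dark_adjusted = NA_real_, accrual_sum = NA_real_,
                     ratio_final = NA_real_, ratio_at_light_off = NA_real_,
                     division_number = 0L)
  if (is.na(seg$t_division_entry)) return(base)
  mus <- estimate_mu_per_light_period(traj, seg)
  if (length(mus) >= 1L && !is.na(mus[1L])) {
    rec <- compute_products(traj, seg, mus)
    base[names(rec)] <- rec
  }
  base$division_number <- classify_division_number(traj, seg, params,
                                                   use_annotation)
  base
}

#' Analyse a cohort of trajectories
#'
#' @param trajs List of [volume_trajectory()] objects.
#' @inheritParams analyse_trajectory
#' @return A data frame with one row per cell (see
#'   [analyse_trajectory()]).
#' @export
analyse_cohort <- function(trajs, params = cycle_params(),
                           drop_fraction = 0.05, min_samples = 5L,
                           smooth_h = 0.5, use_annotation = TRUE) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  do.call(rbind, lapply(trajs, analyse_trajectory, params = params,
                        drop_fraction = drop_fraction,
                        min_samples = min_samples, smooth_h = smooth_h,
                        use_annotation = use_annotation))
}

#' Summarise a cohort of per-cell records
#'
#' Sample statistics (n - 1 denominator) of the interdivision duration,
#' the rate-duration product and the final volume ratio, plus the
#' coefficient of variation of the duration in percent and the tally of
#' division numbers. Cells without a division entry contribute only to
#' the division-number tally.
#'
#' @param records Data frame as returned by [analyse_cohort()] (needs
#'   columns `T`, `muT`, `ratio_final`, `division_number`).
#' @return An object of class `cohort_summary` (a list).
#' @export
summarise_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L)
    stop("need at least 2 records to summarise a cohort", call. = FALSE)
  need <- c("T", "muT", "ratio_final", "division_number")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ok <- !is.na(records$T)
  mT <- mean(records$T[ok]); sT <- stats::sd(records$T[ok])
  structure(list(
    n = nrow(records),
    n_divided = sum(records$division_number > 0L),
    mean_T = mT, sd_T = sT, cv_T = 100 * sT / mT,
    mean_muT = mean(records$muT[ok]),
    sd_muT = stats::sd(records$muT[ok]),
    mean_ratio = mean(records$ratio_final[ok]),
    sd_ratio = stats::sd(records$ratio_final[ok]),
    division_number_counts = table(factor(records$division_number,
                                          levels = c(0L, 2L, 4L)))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d cells (%d divided)\n", x$n, x$n_divided))
  cat(sprintf("  T     : %.2f +/- %.2f h (CV %.1f%%)\n",
              x$mean_T, x$sd_T, x$cv_T))
  cat(sprintf("  mu*T  : %.2f +/- %.2f\n", x$mean_muT, x$sd_muT))
  cat(sprintf("  V(T)/V(0): %.2f +/- %.2f\n", x$mean_ratio, x$sd_ratio))
  cat("  daughters:",
      paste(sprintf("%s -> %d", names(x$division_number_counts),
                    as.integer(x$division_number_counts)),
            collapse = ", "), "\n")
  invisible(x)
}
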