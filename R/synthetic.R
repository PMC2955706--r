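#' Specification of a synthetic single-cell cohort
#'
#' Describes a cohort of cells cultivated under one of the four
#' illumination regimes, to be realised by [generate_cohort()]. Schedule
#' parameters are condition specific and recycled across cells, so e.g. a
#' vector of `t_off` values produces an LD cohort with light switched off
#' at varied times, as in the on-chip experiments.
#'
#' @param condition One of `"LL"`, `"LD"`, `"LDL"`, `"L1L2"`.
#' @param n_cells Number of cells (>= 1).
#' @param schedule_params Named list: `par` (all conditions); `t_off`
#'   (LD, LDL); `t_on` (LDL); `par2`, `t_switch` (L1L2). Each entry may be
#'   a vector, recycled over cells.
#' @param params A [cycle_params()].
#' @param sampling_interval Sampling interval in hours; default 1/120
#'   (30 s, the recording interval of the on-chip system). Coarser
#'   sampling is fine for fast tests.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#' @param arrest_horizon_h How long after the last scheduled light change
#'   an arrested (never-dividing) cell is still recorded; default 48 h.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(condition = c("LL", "LD", "LDL", "L1L2"),
                        n_cells, schedule_params, params = cycle_params(),
                        sampling_interval = 1 / 120, seed = 1L,
                        arrest_horizon_h = 48) {
  condition <- match.arg(condition)
  stopifnot(n_cells >= 1, sampling_interval > 0, arrest_horizon_h > 0,
            inherits(params, "cycle_params"), is.list(schedule_params))
  need <- switch(condition,
                 LL = "par",
                 LD = c("par", "t_off"),
                 LDL = c("par", "t_off", "t_on"),
                 L1L2 = c("par", "t_switch", "par2"))
  if (!all(need %in% names(schedule_params)))
    stop(condition, " cohorts need schedule_params: ",
         paste(need, collapse = ", "), call. = FALSE)
  structure(list(condition = condition, n_cells = as.integer(n_cells),
                 schedule_params = schedule_params, params = params,
                 sampling_interval = sampling_interval,
                 seed = as.integer(seed),
                 arrest_horizon_h = arrest_horizon_h),
            class = "cohort_spec")
}

# Build the schedule for cell i from recycled condition parameters.
cell_schedule <- function(spec, i) {
  p <- lapply(spec$schedule_params, function(x) x[((i - 1L) %% length(x)) + 1L])
  switch(spec$condition,
         LL = schedule_LL(p$par),
         LD = schedule_LD(p$par, p$t_off),
         LDL = schedule_LDL(p$par, p$t_off, p$t_on),
         L1L2 = schedule_L1L2(p$par, p$t_switch, p$par2))
}

#' Generate a cohort of noisy single-cell volume trajectories
#'
#' Realises a [cohort_spec()]: for each cell an initial volume and
#' between-cell lognormal multipliers on the growth rate and the timer
#' threshold are drawn, one cell cycle is simulated, the volume path is
#' sampled at the spec's interval, and multiplicative lognormal
#' measurement noise is applied to every sample. At division-phase entry
#' the trajectory carries the morphological signature used by the
#' division detector: the volume drops by `shrinkage_fraction` (default
#' 10%) over the shrinkage subphase and then plateaus until mitosis
#' completion. Cells that never divide (e.g. uncommitted cells left in
#' darkness) are recorded for `arrest_horizon_h` past the last light
#' change.
#'
#' Each trajectory's `annotations` attribute carries the full ground
#' truth: the noiseless-given-multipliers `cycle_result`, the true initial
#' volume and the drawn multipliers.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [volume_trajectory()] objects.
#' @examples
#' spec <- cohort_spec("LL", n_cells = 3, schedule_params = list(par = 200),
#'                     sampling_interval = 0.05, seed = 7)
#' trajs <- generate_cohort(spec)
#' analyse_cohort(trajs)[, c("cell_id", "T", "muT", "division_number")]
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pp <- spec$params
  with_seed(spec$seed, {
    v0s <- pp$v0_mean * rlnorm_cv(spec$n_cells, pp$v0_cv)
    mu_mults <- rlnorm_cv(spec$n_cells, pp$cv_mu)
    thr_mults <- rlnorm_cv(spec$n_cells, pp$cv_threshold)
    lapply(seq_len(spec$n_cells), function(i) {
      schedule <- cell_schedule(spec, i)
      eng <- cycle_engine(schedule, pp, v0s[i],
                          mu_mult = mu_mults[i], thr_mult = thr_mults[i])
      res <- result_from_engine(eng, pp, v0s[i], mu_mults[i])
      traj <- sample_trajectory(res, schedule, pp, v0s[i],
                                spec$sampling_interval,
                                spec$arrest_horizon_h)
      volume_trajectory(cell_id = sprintf("cell_%03d", i),
                        time_h = traj$time_h,
                        volume_um3 = traj$volume_um3,
                        schedule = schedule,
                        annotations = list(
                          cycle_result = res,
                          v0_true = v0s[i],
                          mu_multiplier = mu_mults[i],
                          threshold_multiplier = thr_mults[i],
                          daughter_volumes = res$daughter_volumes,
                          division_number = res$division_number))
    })
  })
}

# Assemble a cycle_result from an engine run (shared with simulate_cycle's
# noiseless path; multipliers already folded into the engine).
result_from_engine <- function(eng, params, v0, mu_mult) {
  rates <- light_period_rates(eng, params)
  if (is.na(eng$t_entry)) {
    division_number <- 0L; daughters <- numeric(0); subphases <- numeric(0)
  } else {
    division_number <- as.integer(
      mitotic_sizer(eng$v_final / v0, params))
    daughters <- if (division_number > 0L)
      rep(eng$v_final / division_number, division_number) else numeric(0)
    subphases <- subphase_schedule(eng$t_entry, division_number, params)
  }
  structure(list(t_division_entry = eng$t_entry,
                 v_initial = v0, v_final = eng$v_final,
                 mu_initial_light = if (length(rates)) rates[1L] else NA_real_,
                 mu_second_light = if (length(rates) >= 2L) rates[2L]
                                   else NA_real_,
                 committed = eng$committed, t_commitment = eng$t_commit,
                 division_number = division_number,
                 daughter_volumes = daughters,
                 subphase_times = subphases,
                 timer_trace = eng$knots,
                 threshold_effective = eng$thr,
                 mu_multiplier = mu_mult),
            class = "cycle_result")
}

# Sample the noise-free volume path of one simulated cycle, then apply
# multiplicative measurement noise (uses the active RNG stream).
sample_trajectory <- function(res, schedule, params, v0,
                              sampling_interval, arrest_horizon_h) {
  k <- res$timer_trace
  k <- k[!duplicated(k$t, fromLast = TRUE), , drop = FALSE]
  if (is.na(res$t_division_entry)) {
    seg <- as.data.frame(schedule)
    t_last <- max(seg$t_start, seg$t_end[is.finite(seg$t_end)], 0)
    t_max <- t_last + arrest_horizon_h
  } else {
    t_max <- max(res$subphase_times)
  }
  times <- seq(0, t_max, by = sampling_interval)
  log_v <- if (nrow(k) >= 2L)
    stats::approx(k$t, k$log_v, xout = pmin(times, max(k$t)), rule = 2)$y
  else rep(k$log_v[1L], length(times))
  vol <- exp(log_v)
  if (!is.na(res$t_division_entry)) {
    t_entry <- res$t_division_entry
    shrink_end <- res$subphase_times[["shrinkage_end"]]
    v_final <- res$v_final
    frac <- params$shrinkage_fraction
    in_shrink <- times >= t_entry & times < shrink_end
    after <- times >= shrink_end
    if (shrink_end > t_entry)
      vol[in_shrink] <- v_final * (1 - frac * (times[in_shrink] - t_entry) /
                                     (shrink_end - t_entry))
    vol[after] <- v_final * (1 - frac)
  }
  if (params$cv_measurement > 0)
    vol <- vol * rlnorm_cv(length(vol), params$cv_measurement)
  data.frame(time_h = times, volume_um3 = vol)
}

#' Render a synthetic single-cell image with known geometry
#'
#' Draws one bright ellipsoidal cell on a darker background, with
#' anti-aliased edges (4x4 subpixel coverage) and optional Gaussian pixel
#' noise. The ground-truth geometry and the prolate-spheroid volume are
#' attached, so the volumetry pipeline can be validated against a closed
#' form.
#'
#' @param La Full long-axis length (um).
#' @param Lb Full short-axis length (um), `<= La`.
#' @param orientation Long-axis angle in radians (counter-clockwise from
#'   the x axis).
#' @param pixel_size Pixel edge length (um per pixel).
#' @param noise_sd Gaussian intensity noise SD (image intensities span
#'   roughly 0.2 background to 0.8 foreground).
#' @param seed Integer seed for the noise, or `NULL`.
#' @param dim Raster dimensions `c(nx, ny)` in pixels (default 640 x 480).
#' @return An object of class `cell_image`: a list with `pixels` (numeric
#'   matrix, x by y), `pixel_size` and `ground_truth`
#'   (`La`, `Lb`, `orientation`, `true_volume`).
#' @export
generate_cell_image <- function(La, Lb, orientation = 0,
                                pixel_size = 0.1, noise_sd = 0,
                                seed = NULL, dim = c(640L, 480L)) {
  stopifnot(La >= Lb, Lb > 0, pixel_size > 0, noise_sd >= 0,
            length(dim) == 2L)
  nx <- as.integer(dim[1L]); ny <- as.integer(dim[2L])
  a <- La / 2; b <- Lb / 2
  if (La >= nx * pixel_size || La >= ny * pixel_size)
    stop("cell is larger than the raster at this pixel size",
         call. = FALSE)
  cx <- nx * pixel_size / 2; cy <- ny * pixel_size / 2
  # 4x4 subpixel coverage for anti-aliased edges
  sub <- (seq_len(4L) - 0.5) / 4
  offs <- expand.grid(dx = sub, dy = sub)
  x0 <- (seq_len(nx) - 1) * pixel_size
  y0 <- (seq_len(ny) - 1) * pixel_size
  cover <- matrix(0, nx, ny)
  ct <- cos(orientation); st <- sin(orientation)
  for (k in seq_len(nrow(offs))) {
    xs <- x0 + offs$dx[k] * pixel_size - cx
    ys <- y0 + offs$dy[k] * pixel_size - cy
    u <- outer(xs, ys, function(x, y) x * ct + y * st)
    w <- outer(xs, ys, function(x, y) -x * st + y * ct)
    cover <- cover + ((u / a)^2 + (w / b)^2 <= 1)
  }
  cover <- cover / nrow(offs)
  img <- 0.2 + 0.6 * cover
  if (noise_sd > 0) {
    noise_fun <- function() matrix(stats::rnorm(nx * ny, 0, noise_sd),
                                   nx, ny)
    img <- img + if (is.null(seed)) noise_fun() else
      with_seed(seed, noise_fun())
  }
  structure(list(pixels = img, pixel_size = pixel_size,
                 ground_truth = list(La = La, Lb = Lb,
                                     orientation = orientation,
                                     true_volume = spheroid_volume(La, Lb))),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf("Cell image %d x %d px, %.3g um/px",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  gt <- x$ground_truth
  if (!is.null(gt))
    cat(sprintf("; truth La = %.2f um, Lb = %.2f um, V = %.1f um^3",
                gt$La, gt$Lb, gt$true_volume))
  cat("\n")
  invisible(x)
}
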