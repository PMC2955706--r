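# Event-driven cell-cycle engine.
#
# Within each constant-PAR segment both the log-volume and the timer signal
# are linear in time, so commitment and division-phase entry are solved in
# closed form per segment; no numeric ODE stepping is involved.

# Runs one interdivision phase. mu_mult scales every growth rate (one
# between-cell lognormal draw); thr_mult scales the timer threshold.
# Returns knot points of the piecewise-linear (t, log_v, s) paths plus the
# event record.
cycle_engine <- function(schedule, params, v0, mu_mult = 1, thr_mult = 1) {
  thr <- params$timer_threshold * thr_mult
  s_commit <- log(params$commitment_ratio)
  segs <- as.data.frame(schedule)
  n <- nrow(segs)
  # implicit terminal darkness after a finite schedule
  if (is.finite(segs$t_end[n])) {
    segs <- rbind(segs, data.frame(t_start = segs$t_end[n], t_end = Inf,
                                   par = 0))
    n <- n + 1L
  }
  t <- 0; s <- 0; logv <- log(v0)
  committed <- FALSE; mu_mem <- NA_real_; t_commit <- NA_real_
  t_entry <- NA_real_
  kt <- t; klogv <- logv; ks <- s  # knot accumulators
  seg_mu <- numeric(n)
  for (i in seq_len(n)) {
    mu_seg <- growth_rate(segs$par[i], params$calib) * mu_mult
    seg_mu[i] <- mu_seg
    repeat {
      r_timer <- if (committed) mu_mem else mu_seg
      dt_seg <- segs$t_end[i] - t
      dt_commit <- if (!committed && mu_seg > 0) (s_commit - s) / mu_seg
                   else Inf
      dt_fire <- if (r_timer > 0) (thr - s) / r_timer else Inf
      dt <- min(dt_seg, dt_commit, dt_fire)
      if (is.infinite(dt)) break  # open-ended arrest: no further events
      t <- t + dt
      logv <- logv + mu_seg * dt
      s <- s + r_timer * dt
      kt <- c(kt, t); klogv <- c(klogv, logv); ks <- c(ks, s)
      if (dt_fire <= min(dt_seg, dt_commit)) {
        t_entry <- t
        break
      }
      if (dt_commit <= dt_seg) {
        committed <- TRUE
        mu_mem <- mu_seg
        t_commit <- t
        next
      }
      break  # segment boundary
    }
    if (!is.na(t_entry) || is.infinite(segs$t_end[i])) break
  }
  list(t_entry = t_entry, committed = committed, t_commit = t_commit,
       mu_mem = mu_mem, v_final = exp(logv), s_final = s,
       knots = data.frame(t = kt, log_v = klogv, s = ks),
       seg_mu = seg_mu, segs = segs, thr = thr)
}

# Effective growth rates of the distinct light periods seen before entry.
light_period_rates <- function(eng, params) {
  lit <- eng$segs$par > params$calib$par_compensation
  eng$seg_mu[lit]
}

# Evaluate RNG-dependent code under a seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Lognormal multiplier(s) with mean 1 and the given CV.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Accrued timer signal at a given time
#'
#' Evaluates the interdivision-timer signal \eqn{s(t) = \int_0^t r(\tau)
#' d\tau} of a noiseless cell under a light schedule. Before commitment the
#' accrual rate \eqn{r} is the instantaneous light-dependent growth rate
#' (so \eqn{s = \log(V/V_0)} exactly and nothing accrues in darkness);
#' after commitment it is the growth rate memorised at the moment of
#' commitment, and accrual continues even in darkness. The division phase
#' is entered when \eqn{s} reaches the timer threshold; beyond that point
#' the signal is reported clamped at the threshold.
#'
#' @param schedule A [light_schedule()].
#' @param params A [cycle_params()].
#' @param t Time(s) in hours, non-negative.
#' @return The accrued signal(s), dimensionless.
#' @export
accrue_timer <- function(schedule, params, t) {
  stopifnot(inherits(schedule, "light_schedule"),
            inherits(params, "cycle_params"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  eng <- cycle_engine(schedule, params, v0 = params$v0_mean)
  k <- eng$knots
  k <- k[!duplicated(k$t, fromLast = TRUE), , drop = FALSE]
  if (nrow(k) == 1L) return(rep(k$s, length(t)))
  stats::approx(k$t, k$s, xout = t, rule = 2)$y
}

#' Commitment sizer
#'
#' A cell passes the primary arrest point — and so becomes able to divide
#' on schedule even in subsequent darkness — only once its volume has
#' reached `commitment_ratio` times its initial volume.
#'
#' @param v Current volume (um^3), at least `v0`.
#' @param v0 Initial volume (um^3), positive.
#' @param params A [cycle_params()].
#' @return `TRUE` iff `v / v0 >= commitment_ratio`.
#' @export
commitment_check <- function(v, v0, params = cycle_params()) {
  stopifnot(is.numeric(v), is.numeric(v0),
            inherits(params, "cycle_params"))
  if (any(v0 <= 0)) stop("v0 must be positive", call. = FALSE)
  if (any(v < v0))
    stop("v must not be smaller than v0", call. = FALSE)
  v / v0 >= params$commitment_ratio
}

#' Mitotic sizer
#'
#' Maps the final-to-initial volume ratio at division-phase entry to the
#' number of daughter cells. Multiple fission only ever produces even
#' daughter numbers: 0 (no division), 2 (one round of mitosis) or 4 (two
#' rounds).
#'
#' @param ratio Final-to-initial volume ratio, positive; vectorised.
#' @param params A [cycle_params()].
#' @return Integer division number(s) in `{0, 2, 4}`.
#' @export
mitotic_sizer <- function(ratio, params = cycle_params()) {
  stopifnot(is.numeric(ratio), inherits(params, "cycle_params"))
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be positive and finite", call. = FALSE)
  ifelse(ratio < params$mitotic_cutpoint_low, 0L,
         ifelse(ratio < params$mitotic_cutpoint_high, 2L, 4L))
}

# Boundary times of the division subphases appended after entry.
subphase_schedule <- function(t_entry, division_number, params) {
  d <- params$subphase_durations
  names_used <- c("shrinkage", "rotation", "first_mitosis",
                  if (division_number == 4L) "second_mitosis",
                  "mitosis_completion")
  bounds <- t_entry + cumsum(d[names_used])
  names(bounds) <- paste0(names_used, "_end")
  bounds
}

#' Simulate one cell cycle under a light schedule
#'
#' Integrates cell volume and the interdivision-timer signal forward under
#' a piecewise-constant light schedule, using closed-form solutions within
#' each constant-PAR segment. On timer firing the cell enters the division
#' phase: the final volume is recorded, the fixed-duration subphase
#' schedule is appended (its durations do not depend on light), the
#' mitotic sizer sets the division number from the final-to-initial volume
#' ratio, and the final volume is partitioned equally among the daughters.
#' A cell that never commits and is left in darkness arrests: the result
#' records no entry and a division number of zero.
#'
#' With `rng_seed = NULL` the run is noiseless and fully deterministic.
#' With a seed, one lognormal growth-rate multiplier and one timer
#' threshold multiplier are drawn per call (CVs `cv_mu`, `cv_threshold`),
#' reproducibly, without disturbing the caller's RNG.
#'
#' @param schedule A [light_schedule()].
#' @param params A [cycle_params()].
#' @param v0 Initial volume (um^3); defaults to `params$v0_mean`.
#' @param rng_seed Integer seed, or `NULL` for a noiseless run.
#' @return An object of class `cycle_result`: a list with the entry time
#'   `t_division_entry` (`NA` on arrest), initial and final volumes,
#'   per-light-period growth rates `mu_initial_light` / `mu_second_light`,
#'   commitment flag and time, `division_number`, `daughter_volumes`,
#'   `subphase_times` (named boundary times) and the piecewise-linear
#'   `timer_trace` (columns `t`, `log_v`, `s`).
#' @examples
#' res <- simulate_cycle(schedule_LL(200))
#' res$v_final / res$v_initial  # 4.1: the division-entry size threshold
#' @export
simulate_cycle <- function(schedule, params = cycle_params(),
                           v0 = params$v0_mean, rng_seed = NULL) {
  stopifnot(inherits(schedule, "light_schedule"),
            inherits(params, "cycle_params"))
  if (!is.numeric(v0) || length(v0) != 1L || v0 <= 0)
    stop("v0 must be a positive scalar", call. = FALSE)
  mults <- c(mu = 1, thr = 1)
  cut_low <- params$mitotic_cutpoint_low
  cut_high <- params$mitotic_cutpoint_high
  if (!is.null(rng_seed)) {
    draws <- with_seed(rng_seed, {
      m <- c(mu = rlnorm_cv(1, params$cv_mu),
             thr = rlnorm_cv(1, params$cv_threshold))
      bands <- if (isTRUE(params$stochastic_bands)) {
        c(low = stats::runif(1, 1.8, 2.2), high = stats::runif(1, 2.7, 3.1))
      } else c(low = cut_low, high = cut_high)
      list(m = m, bands = bands)
    })
    mults <- draws$m
    cut_low <- draws$bands["low"]
    cut_high <- draws$bands["high"]
  }
  eng <- cycle_engine(schedule, params, v0,
                      mu_mult = mults[["mu"]], thr_mult = mults[["thr"]])
  rates <- light_period_rates(eng, params)
  mu1 <- if (length(rates) >= 1L) rates[1L] else NA_real_
  mu2 <- if (length(rates) >= 2L) rates[2L] else NA_real_
  if (is.na(eng$t_entry)) {
    division_number <- 0L
    daughters <- numeric(0)
    subphases <- numeric(0)
  } else {
    ratio <- eng$v_final / v0
    division_number <- ifelse(ratio < cut_low, 0L,
                              ifelse(ratio < cut_high, 2L, 4L))
    # entry implies commitment, so ratio >= commitment ratio and the sizer
    # yields 2 or 4; guard kept for pathological parameterisations
    daughters <- if (division_number > 0L)
      rep(eng$v_final / division_number, division_number) else numeric(0)
    subphases <- subphase_schedule(eng$t_entry, division_number, params)
  }
  structure(list(t_division_entry = eng$t_entry,
                 v_initial = v0,
                 v_final = eng$v_final,
                 mu_initial_light = mu1,
                 mu_second_light = mu2,
                 committed = eng$committed,
                 t_commitment = eng$t_commit,
                 division_number = division_number,
                 daughter_volumes = daughters,
                 subphase_times = subphases,
                 timer_trace = eng$knots,
                 threshold_effective = eng$thr,
                 mu_multiplier = mults[["mu"]]),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  if (is.na(x$t_division_entry)) {
    cat(sprintf(
      "Cell cycle: growth arrest (no division-phase entry); V = %.1f um^3%s\n",
      x$v_final,
      if (x$committed) ", committed" else ", uncommitted"))
  } else {
    cat(sprintf("Cell cycle: division-phase entry at T = %.3f h\n",
                x$t_division_entry))
    cat(sprintf("  V(0) = %.1f um^3, V(T) = %.1f um^3 (ratio %.2f)\n",
                x$v_initial, x$v_final, x$v_final / x$v_initial))
    cat(sprintf("  mu (first light period) = %.4f /h; mu*T = %.3f\n",
                x$mu_initial_light,
                x$mu_initial_light * x$t_division_entry))
    cat(sprintf("  daughters: %d x %.1f um^3\n", x$division_number,
                if (x$division_number > 0) x$daughter_volumes[1] else 0))
  }
  invisible(x)
}

#' Serialise a simulated cycle result to JSON
#'
#' Flat JSON of the scalar outcome fields plus daughter volumes and the
#' subphase boundary times; the timer trace is included as parallel
#' arrays.
#'
#' @param result A [simulate_cycle()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cycle_result <- function(result, path) {
  stopifnot(inherits(result, "cycle_result"))
  obj <- unclass(result)
  obj$timer_trace <- as.list(result$timer_trace)
  obj$subphase_times <- as.list(result$subphase_times)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Simulate a lineage of successive cell cycles
#'
#' Follows one daughter per generation, as in single-cell cultivation where
#' surplus daughters are removed from the chamber. Each daughter starts at
#' the mother's final volume divided by the division number (the quarter
#' convention for two rounds of fission, half for binary fission) and
#' experiences the same schedule, restarted at its birth. A generation that
#' arrests truncates the lineage; this is reported, not raised.
#'
#' @param schedule A [light_schedule()] applied to every generation.
#' @param params A [cycle_params()].
#' @param generations Number of cycles to attempt (>= 1).
#' @param v0 Initial volume of the founder (um^3).
#' @param rng_seed Integer seed for per-generation noise draws, or `NULL`
#'   for a noiseless lineage.
#' @return A list of [simulate_cycle()] results, possibly shorter than
#'   `generations` if the lineage arrested.
#' @export
simulate_lineage <- function(schedule, params = cycle_params(),
                             generations, v0 = params$v0_mean,
                             rng_seed = NULL) {
  stopifnot(generations >= 1)
  gen_seeds <- if (is.null(rng_seed)) rep(list(NULL), generations)
               else with_seed(rng_seed,
                              as.list(sample.int(.Machine$integer.max,
                                                 generations)))
  out <- vector("list", generations)
  v <- v0
  for (g in seq_len(generations)) {
    res <- simulate_cycle(schedule, params, v0 = v,
                          rng_seed = gen_seeds[[g]])
    out[[g]] <- res
    if (res$division_number == 0L) {
      out <- out[seq_len(g)]
      break
    }
    v <- res$v_final / res$division_number
  }
  out
}
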