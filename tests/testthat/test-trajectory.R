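# Measurement pipeline: division detection, per-period rates, products,
# cohort summaries; closure against the simulator's ground truth.

test_that("division entry is detected at the shrinkage onset", {
  trajs <- noiseless_cohort("LL", list(par = 200))
  truth <- attr(trajs[[1]], "annotations")$cycle_result
  t_hat <- detect_division_entry(trajs[[1]])
  expect_lt(abs(t_hat - truth$t_division_entry), 1 / 120 + 1e-9)

  # monotone growth only: no division called
  s <- schedule_LL(200)
  grow <- volume_trajectory("g", seq(0, 5, by = 0.05),
                            volume_at(80, 0.14, seq(0, 5, by = 0.05)), s)
  expect_true(is.na(detect_division_entry(grow)))

  # dark-arrested flat trajectory: no division called
  flat <- volume_trajectory("f", seq(0, 48, by = 0.5), rep(120, 97),
                            schedule_LD(200, 1))
  expect_true(is.na(detect_division_entry(flat)))
})

test_that("pipeline closes on noiseless cohorts under all four conditions", {
  p <- noiseless_params()
  mu <- growth_rate(200, p$calib)
  specs <- list(
    LL = list(par = 200),
    LD = list(par = 200, t_off = log(3) / mu),
    LDL = list(par = 200, t_off = log(1.5) / mu, t_on = log(1.5) / mu + 9),
    L1L2 = list(par = 200, t_switch = log(1.5) / mu, par2 = 20))
  for (cond in names(specs)) {
    trajs <- noiseless_cohort(cond, specs[[cond]])
    rec <- analyse_cohort(trajs, params = p)
    truth <- attr(trajs[[1]], "annotations")$cycle_result
    expect_equal(rec$condition[1], cond)
    # entry time within one sampling interval of ground truth
    expect_lt(abs(rec$T[1] - truth$t_division_entry), 1 / 120 + 1e-9)
    # per-period rates recovered to near machine precision
    expect_equal(rec$mu_L1[1], truth$mu_initial_light, tolerance = 1e-6)
    # measured size ratio within a few sampling intervals of growth
    expect_equal(rec$ratio_final[1], truth$v_final / truth$v_initial,
                 tolerance = 5e-3)
    expect_equal(rec$division_number[1], truth$division_number)
  }
})

test_that("per-light-period rates exclude darkness and match each period", {
  p <- noiseless_params()
  mu <- growth_rate(200, p$calib)
  # LDL: equal rates before and after the dark interval
  trajs <- noiseless_cohort("LDL", list(par = 200, t_off = log(1.5) / mu,
                                        t_on = log(1.5) / mu + 9))
  seg <- segment_phases(trajs[[1]])
  mus <- estimate_mu_per_light_period(trajs[[1]], seg)
  expect_length(mus, 2)
  expect_equal(unname(mus["L1"]), unname(mus["L2"]), tolerance = 1e-6)
  expect_equal(unname(mus["L1"]), mu, tolerance = 1e-6)
  # L1L2: the two distinct rates are both recovered
  trajs2 <- noiseless_cohort("L1L2", list(par = 200,
                                          t_switch = log(1.5) / mu,
                                          par2 = 100))
  seg2 <- segment_phases(trajs2[[1]])
  mus2 <- estimate_mu_per_light_period(trajs2[[1]], seg2)
  expect_equal(unname(mus2["L1"]), mu, tolerance = 1e-6)
  expect_equal(unname(mus2["L2"]), growth_rate(100, p$calib),
               tolerance = 1e-6)
})

test_that("timer products behave per condition", {
  p <- noiseless_params()
  mu <- growth_rate(200, p$calib)
  thr <- p$timer_threshold
  # LL: raw product equals dark-adjusted product equals the threshold
  ll <- analyse_cohort(noiseless_cohort("LL", list(par = 200)), params = p)
  expect_equal(ll$muT[1], thr, tolerance = 1e-3)
  expect_equal(ll$muT[1], ll$muT_dark_adjusted[1])
  # uncommitted LDL with 9 h darkness: raw product inflated, dark-adjusted
  # product back at the threshold
  ldl <- analyse_cohort(noiseless_cohort(
    "LDL", list(par = 200, t_off = log(1.5) / mu,
                t_on = log(1.5) / mu + 9)), params = p)
  expect_gt(ldl$muT[1], thr + 1)
  expect_equal(ldl$muT_dark_adjusted[1], thr, tolerance = 1e-3)
  # uncommitted PAR step: additive accrual over the two periods recovers
  # the threshold even though the raw product overshoots
  l1l2 <- analyse_cohort(noiseless_cohort(
    "L1L2", list(par = 200, t_switch = log(1.5) / mu, par2 = 20)),
    params = p)
  expect_gt(l1l2$muT[1], thr)
  expect_equal(l1l2$accrual_sum[1], thr, tolerance = 1e-3)
})

test_that("division number classification recovers truth with and without annotations", {
  trajs <- noiseless_cohort("LL", list(par = 200))
  seg <- segment_phases(trajs[[1]])
  expect_equal(classify_division_number(trajs[[1]], seg), 4L)
  expect_equal(classify_division_number(trajs[[1]], seg,
                                        use_annotation = FALSE), 4L)
  # no entry -> 0
  flat <- volume_trajectory("f", seq(0, 48, by = 0.5), rep(120, 97),
                            schedule_LD(200, 1))
  expect_equal(classify_division_number(flat, segment_phases(flat)), 0L)
})

test_that("cohort summary computes sample statistics and tallies", {
  rec <- data.frame(T = c(10, 10, 10), muT = c(1.2, 1.4, 1.6),
                    ratio_final = c(4, 4.1, 4.2),
                    division_number = c(4L, 4L, 2L))
  s <- summarise_cohort(rec)
  expect_equal(s$cv_T, 0)
  expect_equal(s$mean_muT, 1.4)
  expect_equal(s$sd_muT, 0.2)
  expect_equal(as.integer(s$division_number_counts[c("2", "4")]), c(1L, 2L))
  expect_error(summarise_cohort(rec[1, ]), "at least 2")
})

test_that("growth rate recovery stays within 5% for 95% of noisy cells", {
  # 30 samples/h, 5% measurement noise, no between-cell variability in mu
  # so the generating rate is the known truth
  p <- cycle_params(cv_mu = 0, cv_threshold = 0, cv_measurement = 0.05,
                    v0_cv = 0.1)
  spec <- cohort_spec("LL", n_cells = 200, list(par = 200), params = p,
                      sampling_interval = 1 / 30, seed = 2024)
  rec <- analyse_cohort(generate_cohort(spec))
  mu_true <- growth_rate(200, p$calib)
  rel_err <- abs(rec$mu_L1 - mu_true) / mu_true
  expect_gte(mean(rel_err <= 0.05, na.rm = TRUE), 0.95)
})

test_that("stochastic cohort dispersion lands in a plausible band", {
  spec <- cohort_spec("LL", n_cells = 26, list(par = 200),
                      sampling_interval = 1 / 60, seed = 5)
  s <- summarise_cohort(analyse_cohort(generate_cohort(spec)))
  expect_gt(s$cv_T, 15)
  expect_lt(s$cv_T, 40)
  expect_lt(abs(s$mean_muT - 1.4), 0.2)
})
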