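# Interdivision timer, commitment sizer, mitotic sizer, cycle simulator.

test_that("noiseless continuous light obeys the timer identity at every PAR", {
  p <- cycle_params()
  for (par in c(10, 20, 40, 100, 200, 300)) {
    res <- simulate_cycle(schedule_LL(par), p)
    mu <- growth_rate(par, p$calib)
    expect_equal(mu * res$t_division_entry, p$timer_threshold,
                 tolerance = 1e-12)
    expect_equal(res$v_final / res$v_initial, exp(p$timer_threshold),
                 tolerance = 1e-12)
    expect_equal(res$division_number, 4L)
  }
})

test_that("committed cells divide on schedule regardless of when light ends", {
  p <- cycle_params()
  mu <- growth_rate(200, p$calib)
  entries <- sapply(c(2.1, 2.5, 3, 3.5, 4), function(ratio_off) {
    res <- simulate_cycle(schedule_LD(200, log(ratio_off) / mu), p)
    expect_true(res$committed)
    res$t_division_entry
  })
  # entry time depends only on mu, not on the light-off time
  expect_equal(entries, rep(p$timer_threshold / mu, 5), tolerance = 1e-12)
})

test_that("an uncommitted cell arrests in darkness indefinitely", {
  p <- cycle_params()
  mu <- growth_rate(200, p$calib)
  res <- simulate_cycle(schedule_LD(200, log(1.5) / mu), p)
  expect_false(res$committed)
  expect_true(is.na(res$t_division_entry))
  expect_equal(res$division_number, 0L)
  # the timer signal stays frozen below threshold at +48 h and beyond
  s <- accrue_timer(schedule_LD(200, log(1.5) / mu), p,
                    log(1.5) / mu + c(0, 1, 48, 60))
  expect_equal(s, rep(log(1.5), 4), tolerance = 1e-12)
})

test_that("a dark interval before commitment shifts entry by exactly its length", {
  p <- cycle_params()
  mu <- growth_rate(200, p$calib)
  t_off <- log(1.5) / mu
  base <- simulate_cycle(schedule_LL(200), p)
  for (t_dark in c(0.8, 4, 9)) {
    res <- simulate_cycle(schedule_LDL(200, t_off, t_off + t_dark), p)
    expect_equal(res$t_division_entry,
                 base$t_division_entry + t_dark, tolerance = 1e-12)
    expect_equal(res$v_final, base$v_final, tolerance = 1e-12)
    # the dark-adjusted product is the timer threshold
    expect_equal(mu * (res$t_division_entry - t_dark), p$timer_threshold,
                 tolerance = 1e-12)
  }
})

test_that("a PAR step-down before commitment accrues the two rates additively", {
  p <- cycle_params()
  mu1 <- growth_rate(200, p$calib)
  t_sw <- log(1.5) / mu1  # switch before commitment
  for (par2 in c(100, 20, 10)) {
    mu2 <- growth_rate(par2, p$calib)
    res <- simulate_cycle(schedule_L1L2(200, t_sw, par2), p)
    accrual <- mu1 * t_sw + mu2 * (res$t_division_entry - t_sw)
    expect_equal(accrual, p$timer_threshold, tolerance = 1e-12)
  }
})

test_that("after commitment the memorised rate governs entry under a PAR step", {
  p <- cycle_params()
  mu1 <- growth_rate(200, p$calib)
  t_sw <- log(2.5) / mu1  # switch after commitment
  res <- simulate_cycle(schedule_L1L2(200, t_sw, 20), p)
  expect_true(res$committed)
  # first-light-period rate times total duration equals the threshold
  expect_equal(mu1 * res$t_division_entry, p$timer_threshold,
               tolerance = 1e-12)
  # but the cell enters below the continuous-light size ratio
  expect_lt(res$v_final / res$v_initial, exp(p$timer_threshold))
})

test_that("timer accrual equals log(V/V0) at every instant before commitment", {
  p <- cycle_params()
  sched <- schedule_LDL(200, 3, 9)
  res <- simulate_cycle(sched, p)
  ts <- seq(0, min(res$t_commitment, 20), length.out = 40)
  s <- accrue_timer(sched, p, ts)
  k <- res$timer_trace
  logv <- approx(k$t, k$log_v, xout = ts, rule = 2)$y
  expect_equal(s, logv - log(res$v_initial), tolerance = 1e-10)
})

test_that("dim light below compensation gives neither growth nor division", {
  res <- simulate_cycle(schedule_LL(0.2))
  expect_true(is.na(res$t_division_entry))
  expect_equal(res$v_final, res$v_initial)
  expect_equal(res$division_number, 0L)
})

test_that("commitment sizer gates on the doubling ratio", {
  expect_true(commitment_check(160, 80))
  expect_false(commitment_check(159, 80))
  expect_false(commitment_check(87, 69))  # hatched daughter, ratio 1.26
  expect_error(commitment_check(60, 80), "smaller")
  expect_error(commitment_check(80, 0), "positive")
})

test_that("mitotic sizer maps volume ratios to even daughter numbers", {
  expect_equal(mitotic_sizer(2.5), 2L)
  expect_equal(mitotic_sizer(3.5), 4L)
  expect_equal(mitotic_sizer(1.5), 0L)
  expect_equal(mitotic_sizer(c(2.0, 2.89, 2.9)), c(2L, 2L, 4L))
  # never odd, over a dense sweep of ratios
  sweep <- mitotic_sizer(seq(0.1, 6, by = 0.01))
  expect_true(all(sweep %in% c(0L, 2L, 4L)))
  expect_error(mitotic_sizer(0), "positive")
})

test_that("daughters partition the final volume exactly", {
  res <- simulate_cycle(schedule_LL(100))
  expect_equal(sum(res$daughter_volumes), res$v_final, tolerance = 1e-12)
  expect_length(res$daughter_volumes, res$division_number)
  # quarter rule: mother of 277 um^3 yields 69.25 um^3 daughters
  p <- cycle_params()
  mu <- growth_rate(200, p$calib)
  v0 <- 277 / exp(p$timer_threshold)
  res2 <- simulate_cycle(schedule_LL(200), p, v0 = v0)
  expect_equal(res2$v_final, 277, tolerance = 1e-9)
  expect_equal(res2$daughter_volumes, rep(69.25, 4), tolerance = 1e-9)
})

test_that("division-phase duration is light-independent", {
  p <- cycle_params()
  durations <- sapply(c(10, 40, 200), function(par) {
    res <- simulate_cycle(schedule_LL(par), p)
    max(res$subphase_times) - res$t_division_entry
  })
  expect_equal(durations, rep(durations[1], 3))
  expect_equal(durations[1], sum(p$subphase_durations))
})

test_that("seeded runs are reproducible and noiseless runs deterministic", {
  a <- simulate_cycle(schedule_LL(200), rng_seed = 7)
  b <- simulate_cycle(schedule_LL(200), rng_seed = 7)
  expect_identical(a, b)
  c1 <- simulate_cycle(schedule_LL(200), rng_seed = 8)
  expect_false(isTRUE(all.equal(a$t_division_entry, c1$t_division_entry)))
  n1 <- simulate_cycle(schedule_LL(200))
  n2 <- simulate_cycle(schedule_LL(200))
  expect_identical(n1, n2)
})

test_that("lineages follow one daughter and inherit the split volume", {
  p <- cycle_params()
  lin <- simulate_lineage(schedule_LL(200), p, generations = 3)
  expect_length(lin, 3)
  mus_T <- sapply(lin, function(r) {
    growth_rate(200, p$calib) * r$t_division_entry
  })
  expect_equal(mus_T, rep(p$timer_threshold, 3), tolerance = 1e-12)
  for (g in 2:3)
    expect_equal(lin[[g]]$v_initial,
                 lin[[g - 1]]$v_final / lin[[g - 1]]$division_number,
                 tolerance = 1e-12)
  # an arresting generation truncates the lineage without error
  mu <- growth_rate(200, p$calib)
  lin2 <- simulate_lineage(schedule_LD(200, log(1.5) / mu), p,
                           generations = 4)
  expect_length(lin2, 1)
  expect_equal(lin2[[1]]$division_number, 0L)
})
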