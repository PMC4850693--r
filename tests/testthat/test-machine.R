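test_that("planner estimate reproduces the dose-rate-limited coplanar case", {
  pl <- coplanar_plan(c(90, 270), mu_total = 300)  # 180 deg gantry span
  est <- tps_time_estimate(pl)
  # gantry-limited 30 s would need 600 MU/min > 400, so 400 binds
  expect_equal(est$beam_on_time, 45)
  expect_equal(est$gantry_speed, 4)
  expect_equal(est$dose_rate, 400)
})

test_that("planner gantry speed is capped by the ring-coupling ratio", {
  tr <- wave_trajectory(c(0, 60), c(0, 60))
  cp <- build_control_points(discretize_beams(tr, validate = FALSE))
  pl <- delivery_plan(cp, rep(10 / nrow(cp), nrow(cp)))  # MU not binding
  est <- tps_time_estimate(pl)
  expect_equal(est$beam_on_time, 60 / 2.5)
  expect_equal(est$ring_speeds, 2.5)
})

test_that("zero-MU plans are purely motion-limited", {
  pl <- coplanar_plan(c(90, 270), mu_total = 0)
  expect_equal(tps_time_estimate(pl)$beam_on_time, 180 / 6)
})

test_that("controller picks the dose rate giving a simultaneous finish", {
  tr <- wave_trajectory(c(0, 60), c(0, 0))
  cp <- build_control_points(discretize_beams(tr))
  pl <- delivery_plan(cp, rep(50 / nrow(cp), nrow(cp)))
  ctl <- controller_simulate(pl)
  expect_equal(ctl$beam_on_time, 10)       # max(60/6, 50/400*60)
  expect_equal(ctl$dose_rates, 300)        # 50 MU / 10 s = 300 MU/min
})

test_that("each interior manipulation point adds exactly one 0.1 s stop", {
  pl <- generate_plan(seed = 7, n_subarcs = 2)
  ctl <- controller_simulate(pl)
  expect_equal(ctl$mp_stop_total, 0.1)
  expect_equal(ctl$beam_on_time, sum(ctl$subarc_times) + 0.1)
  st <- summarize_trace(ctl$trace)
  expect_equal(st$total_time, ctl$beam_on_time)

  pl4 <- generate_plan(seed = 7, n_subarcs = 4)
  expect_equal(controller_simulate(pl4, emit_trace = FALSE)$mp_stop_total,
               3 * 0.1)
})

test_that("trace conserves MU to within 0.5 MU and stays monotone", {
  for (seed in c(3, 11, 25)) {
    pl <- generate_plan(seed = seed, n_subarcs = 3, mu_total = 250)
    ctl <- controller_simulate(pl)
    expect_lt(abs(ctl$total_mu_delivered - pl$total_mu), 0.5)
    expect_lt(abs(attr(ctl$trace, "total_mu") - pl$total_mu), 0.5)
    expect_true(all(diff(ctl$trace$cumulative_mu) >= -1e-9))
    expect_true(all(diff(ctl$trace$t) > 0))
    # speeds within machine ranges or exactly zero
    v <- ctl$trace$gantry_speed
    expect_true(all(v == 0 | (v >= 0.1 - 1e-9 & v <= 6 + 1e-9)))
    w <- ctl$trace$ring_speed
    expect_true(all(w == 0 | (w >= 0.1 - 1e-9 & w <= 2.5 + 1e-9)))
    # stop samples carry the ~100 MU/min ramp dose rate and zero speed
    stops <- ctl$trace$phase == "mp_stop"
    expect_true(any(stops))
    expect_true(all(ctl$trace$dose_rate[stops] == 100))
    expect_true(all(v[stops] == 0))
  }
})

test_that("controller is never slower than the conservative planner", {
  for (seed in 1:40) {
    pl <- generate_plan(seed = seed, n_subarcs = 1,
                        mu_total = 50 + 10 * seed)
    tps <- tps_time_estimate(pl)
    ctl <- controller_simulate(pl, emit_trace = FALSE)
    expect_lte(ctl$beam_on_time, tps$beam_on_time + 1e-9)
  }
  # multi-sub-arc: within (n-1) * stop duration of the planner bound in the
  # homogeneous regimes (all sub-arcs motion-limited, or all dose-rate
  # limited); mixed regimes can beat the single-dose-rate planner locally
  # yet lose globally, so no bound is asserted there
  for (seed in 1:10) {
    for (mu in c(30, 2000)) {
      pl <- generate_plan(seed = seed, n_subarcs = 3, mu_total = mu)
      tps <- tps_time_estimate(pl)
      ctl <- controller_simulate(pl, emit_trace = FALSE)
      expect_lte(ctl$beam_on_time, tps$beam_on_time + 2 * 0.1 + 1e-9)
    }
  }
})

test_that("both solvers match exhaustive search over table and speed grid", {
  mc <- machine_constraints()
  for (seed in c(2, 9, 17, 33)) {
    n_sub <- 1 + seed %% 3
    pl <- generate_plan(seed = seed, n_subarcs = n_sub,
                        mu_total = 100 + 17 * seed)
    expect_equal(tps_time_estimate(pl)$beam_on_time,
                 oracle_tps_time(pl, mc), tolerance = 2e-3)
    expect_equal(controller_simulate(pl, emit_trace = FALSE)$beam_on_time,
                 oracle_controller_time(pl, mc), tolerance = 2e-3)
  }
})

test_that("times respond monotonically to MU and constraint widening", {
  pl_lo <- generate_plan(seed = 5, n_subarcs = 2, mu_total = 100)
  pl_hi <- generate_plan(seed = 5, n_subarcs = 2, mu_total = 400)
  expect_lte(tps_time_estimate(pl_lo)$beam_on_time,
             tps_time_estimate(pl_hi)$beam_on_time)
  expect_lte(controller_simulate(pl_lo, emit_trace = FALSE)$beam_on_time,
             controller_simulate(pl_hi, emit_trace = FALSE)$beam_on_time)
  wide <- machine_constraints(gantry_speed = c(0.1, 12),
                              ring_speed = c(0.1, 5),
                              dose_rate_table = seq(150, 800, by = 50))
  expect_lte(tps_time_estimate(pl_hi, wide)$beam_on_time,
             tps_time_estimate(pl_hi)$beam_on_time)
  expect_lte(controller_simulate(pl_hi, wide,
                                 emit_trace = FALSE)$beam_on_time,
             controller_simulate(pl_hi, emit_trace = FALSE)$beam_on_time)
})

test_that("trace summary reports time-weighted beam-on means", {
  pl <- coplanar_plan(c(90, 270), mu_total = 300)
  ctl <- controller_simulate(pl)
  st <- summarize_trace(ctl$trace)
  expect_equal(st$mean_gantry_speed, 4)    # 180 deg in 45 s
  expect_equal(st$mean_dose_rate, 400)
  expect_equal(st$total_mu, 300)
  expect_error(summarize_trace(ctl$trace[0, ]), "empty")
})

test_that("overestimation metric matches the printed dose-rate example", {
  mu <- 301
  t_tps <- mu / 180 * 60
  t_act <- mu / 243 * 60
  ov <- time_overestimation(t_tps, t_act)
  expect_equal(round(ov), 26)
  expect_equal(time_overestimation(10, 10), 0)
  expect_equal(time_overestimation(10, 5), 50)
})

test_that("leaf-speed screening flags only infeasible travel", {
  ap1 <- mlc_aperture(rep(-3, 4), rep(3, 4))
  ap2 <- mlc_aperture(c(-3, -3, 2, -3), c(3, 3, 3, 3))  # leaf 3 moves 5 cm
  tr <- wave_trajectory(c(0, 24), c(0, 0))
  cp <- build_control_points(discretize_beams(tr))
  pl <- delivery_plan(cp, rep(1, 4),
                      apertures = list(ap1, ap1, ap2, ap2))
  v <- leaf_travel_feasibility(pl, segment_times = c(1, 1, 1))
  expect_equal(nrow(v), 1)
  expect_equal(v$leaf, 3)
  expect_equal(v$required_speed, 5)
  # static apertures: feasible for any times, including zero
  pl0 <- delivery_plan(cp, rep(1, 4), apertures = rep(list(ap1), 4))
  expect_equal(nrow(leaf_travel_feasibility(pl0, c(0, 0, 0))), 0)
  # zero time with motion -> infinite-speed violation
  vinf <- leaf_travel_feasibility(pl, segment_times = c(1, 0, 1))
  expect_true(any(is.infinite(vinf$required_speed)))
})

test_that("infeasible plans raise errors naming the binding constraint", {
  tr <- wave_trajectory(c(0, 24), c(0, 0))
  cp <- build_control_points(discretize_beams(tr))
  pl <- delivery_plan(cp, rep(1000 / 4, 4))  # 1000 MU over 24 deg
  # dose-rate-limited time 150 s -> gantry would crawl at 0.16 deg/s: fine
  expect_silent(tps_time_estimate(pl))
  # but a tiny arc with huge MU pushes the gantry below its minimum speed
  pl2 <- delivery_plan(cp, rep(1e5 / 4, 4))
  expect_error(tps_time_estimate(pl2), "minimum speed")
})
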