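p_def <- op_params()

test_that("refeeding initial conditions sit on the diet line", {
  st <- operating_point(p_def)
  ic1 <- refeeding_initial_condition(p_def, 1)
  expect_equal(ic1$F, st$Fst, tolerance = 1e-8)
  expect_equal(ic1$u, st$ust, tolerance = 1e-8)
  ic <- refeeding_initial_condition(p_def, 1.4)
  expect_equal(ic$u, 1.346957, tolerance = 1e-5)
  expect_equal(ic$F, 0.827566, tolerance = 1e-5)
  ic2 <- refeeding_initial_condition(p_def, 0.7)
  expect_equal(ic2$u, 0.673479, tolerance = 1e-5)
  expect_equal(ic2$F, 0.288783, tolerance = 1e-5)
  expect_error(refeeding_initial_condition(p_def, 0.1), "negative")
})

test_that("the operating point is a fixed point of the dynamics", {
  st <- operating_point(p_def, n = 100, check = FALSE)
  traj <- simulate_dynamics(p_def, list(F = st$Fst, u = st$ust),
                            sim_config(t_end = 50))
  expect_lt(max(rel_err(traj$F, st$Fst)), 1e-6)
  expect_lt(max(rel_err(traj$u, st$ust)), 1e-6)
  expect_identical(detect_transient(traj), "monotone")
})

test_that("recovery from under/over-feeding jumps to the appetite line and
           produces the matching transient", {
  pf <- with_fast_leptin(p_def)   # physiological leptin turnover
  for (case in list(list(f = 0.7, cls = "overshoot"),
                    list(f = 1.4, cls = "undershoot"))) {
    ic <- refeeding_initial_condition(p_def, case$f)
    fine <- simulate_dynamics(pf, ic, sim_config(t_end = 2, dt_out = 0.1))
    # first ad-libitum intake is the appetite value at the starting fat
    expect_equal(fine$u[2], appetite_intake(ic$F, p_def), tolerance = 0.05)
    long <- simulate_dynamics(pf, ic, sim_config(t_end = 400))
    expect_identical(detect_transient(long), case$cls)
  }
})

test_that("a diet-line step (exercise) gives a monotone intake rise", {
  st <- operating_point(p_def, n = 100, check = FALSE)
  p_ex <- op_preset("fig4D")    # raised energy expenditure
  traj <- simulate_dynamics(p_ex, list(F = st$Fst, u = st$ust),
                            sim_config(t_end = 400))
  expect_identical(detect_transient(traj), "monotone")
  expect_gt(traj$u[nrow(traj)], st$ust)     # intake up
  expect_lt(traj$F[nrow(traj)], st$Fst)     # fat down
})

test_that("intake hugs the appetite line once leptin is fast (timescale separation)", {
  pf <- with_fast_leptin(p_def)
  ic <- refeeding_initial_condition(p_def, 0.7)
  traj <- simulate_dynamics(pf, ic, sim_config(t_end = 50))
  dev <- rel_err(traj$u, appetite_intake(traj$F, p_def, n = 100))
  expect_true(all(dev[-1] < 0.05))
})

test_that("trajectories converge to the operating point and conserve the
           energy balance", {
  st <- operating_point(p_def, n = 100, check = FALSE)
  ic <- refeeding_initial_condition(p_def, 0.7)
  traj <- simulate_dynamics(p_def, ic, sim_config(t_end = 400))
  expect_lt(rel_err(traj$F[nrow(traj)], st$Fst), 0.01)
  expect_lt(rel_err(traj$u[nrow(traj)], st$ust), 0.01)
  # pointwise energy bookkeeping on a fine grid
  fine <- simulate_dynamics(p_def, ic, sim_config(t_end = 20, dt_out = 0.05))
  nt <- nrow(fine)
  dFdt <- (fine$F[3:nt] - fine$F[1:(nt - 2)]) / (2 * 0.05)
  rhs <- (p_def$aF * fine$u - p_def$gammaE - p_def$gammaF * fine$F)[2:(nt - 1)]
  expect_lt(max(abs(dFdt - rhs)), 1e-3)
})

test_that("quasi-steady leptin mode keeps intake exactly on the appetite line", {
  ic <- refeeding_initial_condition(p_def, 0.7)
  traj <- simulate_dynamics(p_def, ic,
                            sim_config(t_end = 30,
                                       leptin_mode = "quasi-steady"))
  expect_equal(traj$u, appetite_intake(traj$F, p_def, n = 100),
               tolerance = 1e-7)
  expect_equal(traj$L, leptin_qss(traj$F, traj$u, p_def), tolerance = 1e-10)
})

test_that("unsettled trajectories are reported inconclusive, not guessed", {
  ic <- refeeding_initial_condition(p_def, 0.7)
  short <- simulate_dynamics(p_def, ic, sim_config(t_end = 10))
  expect_identical(detect_transient(short), "inconclusive")
})

test_that("trajectory CSV writer and reader round-trip", {
  ic <- refeeding_initial_condition(p_def, 1.4)
  traj <- simulate_dynamics(p_def, ic, sim_config(t_end = 10))
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(back$F, traj$F, tolerance = 1e-12)
  expect_equal(back$u, traj$u, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = 1, x = 2), bad, row.names = FALSE)
  expect_error(read_trajectory(bad), "columns exactly")
})

test_that("leptin-rate rescaling leaves the steady state untouched", {
  pf <- with_fast_leptin(p_def, 25)
  s1 <- operating_point(p_def, check = FALSE)
  s2 <- operating_point(pf, check = FALSE)
  expect_equal(s2$Fst, s1$Fst)
  expect_equal(s2$ust, s1$ust)
  F <- seq(0.1, 1.5, length.out = 20)
  expect_equal(appetite_intake(F, pf, n = 7), appetite_intake(F, p_def, n = 7),
               tolerance = 1e-9)
})
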