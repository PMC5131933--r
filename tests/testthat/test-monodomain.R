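test_that("a uniform unstimulated sheet stays exactly uniform", {
  g <- sim_grid(12, 12)
  cfg <- sim_config(g, duration_ms = 20, protocol = NULL)
  m <- run_monodomain(cfg)
  for (t in seq_len(dim(m$frames)[3])) {
    fr <- m$frames[, , t]
    expect_equal(max(fr) - min(fr), 0)
  }
})

test_that("pure diffusion conserves the spatial mean and smooths gradients", {
  g <- sim_grid(16, 16)
  cfg <- sim_config(g, duration_ms = 50, protocol = NULL)
  set.seed(7)
  v0 <- matrix(runif(16 * 16, -90, -20), 16, 16)
  m <- run_monodomain(cfg, passive = TRUE, init_v = v0)
  expect_equal(dim(m$frames)[3], 51)
  means <- apply(m$frames, 3, mean)
  # no-flux + 5-point stencil conserve the discrete mean to round-off
  expect_lt(max(abs(means - means[1])), 1e-9)
  # variance decays monotonically under diffusion (up to round-off)
  vars <- apply(m$frames, 3, function(f) var(as.vector(f)))
  expect_true(all(diff(vars) <= 1e-8 * vars[1]))
  expect_lt(vars[51], vars[1])
})

test_that("single-cell action potential matches the independent stiff-ODE oracle", {
  skip_if_not_installed("deSolve")
  mine <- sim_courtemanche_cell(duration_ms = 600, stim_times_ms = 10,
                                stim_amplitude = 20, stim_duration_ms = 2)
  orac <- crn_oracle_ap(duration_ms = 600, stim_on = 10, stim_dur = 2,
                        stim_amp = 20)
  # resting potential within 2%
  expect_lt(abs(mine$V[1] - orac$V[1]) / abs(orac$V[1]), 0.02)
  # APD90 within 2%
  apd_mine <- apd(mine$time_ms, mine$V)
  apd_orac <- apd(orac$time_ms, orac$V)
  expect_lt(abs(apd_mine - apd_orac) / apd_orac, 0.02)
  # full trace agreement away from the upstroke (sup-norm on repolarization)
  late <- mine$time_ms > 50
  expect_lt(max(abs(mine$V[late] - orac$V[late])), 2.5)
})

test_that("remodeling scenarios shorten the action potential as expected", {
  ctrl <- sim_courtemanche_cell(600, 10, 20)
  ical <- sim_courtemanche_cell(600, 10, 20,
                                scenario = scenario_preset("0.3xICaL"))
  af <- sim_courtemanche_cell(600, 10, 20, scenario = scenario_preset("AF"))
  a_ctrl <- apd(ctrl$time_ms, ctrl$V)
  a_ical <- apd(ical$time_ms, ical$V)
  a_af <- apd(af$time_ms, af$V)
  expect_gt(a_ctrl, a_ical)
  expect_gt(a_ical, a_af)
})

test_that("halving the macro time step barely changes the single-cell trace", {
  a <- sim_courtemanche_cell(400, 10, 20, dt_max_ms = 0.1)
  b <- sim_courtemanche_cell(400, 10, 20, dt_max_ms = 0.05)
  expect_lt(abs(a$V[nrow(a)] - b$V[nrow(b)]), 0.5)
})

test_that("the tissue solver is deterministic", {
  g <- sim_grid(20, 20)
  cfg <- sim_config(g, duration_ms = 60,
                    protocol = stim_protocol(n_s1 = 1, amplitude = 25,
                                             duration_ms = 2))
  m1 <- run_monodomain(cfg)
  m2 <- run_monodomain(cfg)
  expect_identical(m1$frames, m2$frames)
})

test_that("a stimulated wave propagates with a plausible conduction velocity", {
  g <- sim_grid(60, 120)  # 1.5 x 3 cm strip
  cfg <- sim_config(g, duration_ms = 90,
                    protocol = stim_protocol(n_s1 = 1, amplitude = 25,
                                             duration_ms = 2))
  m <- run_monodomain(cfg)
  act <- function(col) {
    v <- m$frames[30, col, ]
    which(v > -40)[1]
  }
  t1 <- act(30); t2 <- act(100)
  expect_false(is.na(t1) || is.na(t2))
  cv <- (100 - 30) * 0.25 / (t2 - t1)  # mm/ms
  expect_gt(cv, 0.2)
  expect_lt(cv, 0.8)
})

test_that("numerical blow-up aborts with a diagnostic", {
  g <- sim_grid(8, 8)
  # absurd stimulus drives V past the guard
  cfg <- sim_config(g, duration_ms = 30,
                    protocol = stim_protocol(n_s1 = 1, amplitude = 1e5,
                                             duration_ms = 20))
  expect_error(run_monodomain(cfg), "blow-up")
})
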