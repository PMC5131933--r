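test_that("grid, protocol and config constructors validate their inputs", {
  expect_error(sim_grid(2, 10), "3 x 3")
  expect_error(sim_grid(10, 10, dx_mm = 0), "positive")
  g <- sim_grid(10, 12)
  expect_s3_class(g, "sim_grid")
  expect_identical(g$boundary, "no_flux")

  p <- stim_protocol(s1_time_ms = 1, n_s1 = 2, s1_cycle_ms = 350,
                     s2_coupling_interval_ms = 300)
  expect_equal(p$s1_times_ms, c(1, 351))
  expect_equal(p$s2_time_ms, 651)  # S2 fires one coupling interval after last S1
  expect_error(stim_protocol(amplitude = -1), "positive")

  expect_error(sim_config(g, duration_ms = 100, dt_min_ms = 0.2),
               "dt_min_ms")
  expect_error(sim_config(g, duration_ms = 100, record_from_ms = 200),
               "record_from_ms")
  cfg <- sim_config(g, duration_ms = 100)
  expect_equal(cfg$D_cm2_per_ms, 0.001)
  expect_equal(cfg$dt_min_ms, 0.01)
  expect_equal(cfg$dt_max_ms, 0.1)
})

test_that("protocol regions resolve inside the grid and reject bad masks", {
  g <- sim_grid(40, 40)
  reg <- spiralps:::resolve_protocol_regions(stim_protocol(), g)
  expect_true(all(reg$s1 >= 1) && all(reg$s1 <= 40))
  expect_true(all(reg$s2 >= 1) && all(reg$s2 <= 40))
  expect_error(
    spiralps:::resolve_protocol_regions(
      stim_protocol(s1_region = c(1, 50, 1, 5)), g),
    "outside grid")
})

test_that("scenario multipliers apply by name, reject unknowns, and control is identity", {
  base <- courtemanche_params()
  ctrl <- apply_scenario(base, scenario_config())
  expect_identical(ctrl, base)

  sc <- scenario_config(g_CaL = 0.3)
  out <- apply_scenario(base, sc)
  expect_equal(out[["g_CaL"]], 0.3 * base[["g_CaL"]])
  expect_equal(out[setdiff(names(out), "g_CaL")],
               base[setdiff(names(base), "g_CaL")])
  expect_identical(base, courtemanche_params())  # base untouched

  expect_error(scenario_config(g_bogus = 2), "unknown")
  expect_error(scenario_config(g_Na = -1), "positive")
})

test_that("the AF preset applies the seven remodeling multipliers simultaneously", {
  af <- scenario_preset("AF")$multipliers
  expect_equal(unname(af[c("g_Na", "g_to", "g_CaL", "g_Kur", "sr_leak",
                           "g_K1", "k_NaCa_max")]),
               c(0.9, 0.3, 0.3, 0.5, 1.25, 2.0, 1.4))
  out <- apply_scenario(courtemanche_params(), scenario_preset("AF"))
  expect_equal(out[["k_NaCa_max"]], 1600 * 1.4)
})

test_that("applying a scenario then control equals applying it once (closure)", {
  base <- courtemanche_params()
  once <- apply_scenario(base, scenario_preset("0.3xICaL"))
  twice <- apply_scenario(once, scenario_config())
  expect_identical(once, twice)
})

test_that("D_scale acts on the diffusion coefficient", {
  out <- apply_scenario(courtemanche_params(), scenario_preset("0.3xD"))
  expect_equal(out[["D_cm2_per_ms"]], 0.0003)
})
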