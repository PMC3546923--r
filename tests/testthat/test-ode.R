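p0 <- los_parameters()

test_that("rhs composes fluxes into the five mass balances", {
  # no enzymes, zero state: only the cPLA2 source feeds AA
  e <- los_environment(Fa = 0, GPx_full = 0, HEDH_full = 0, cpla2_scale = 1)
  d <- los_rhs(los_state(), e, p0)
  expect_gt(d[["AA"]], 0)
  expect_equal(unname(d[c("HP", "HT", "LTA4", "oxoETE")]), rep(0, 4))
  expect_equal(d[["AA"]], cpla2_rate(los_state(), e, p0))

  # pure LTA4 decay with the published constant
  d2 <- los_rhs(los_state(LTA4 = 1), los_environment(Fa = 0, PL = 0), p0)
  expect_equal(d2[["LTA4"]], -0.07)
})

test_that("isolated LTA4 pool decays with the closed-form exponential", {
  e <- los_environment(Fa = 0, GPx_full = 0, HEDH_full = 0, PL = 0)
  tt <- seq(0, 40, by = 5)
  tc <- los_simulate(e, p0, times = tt, init = los_state(LTA4 = 1))
  expect_equal(tc$LTA4, exp(-0.07 * tt), tolerance = 1e-7)
})

test_that("closed catalytic variant conserves AA + HP + LTA4", {
  # sources, sinks and HP/HT interconversion off; only the 5-LO cycle runs
  p_closed <- los_parameters(k_ox = 0, k_ox2 = 0, k_HTd = 0, k_LTAd = 0,
    k_oxoETEd = 0)
  e_closed <- los_environment(PL = 0, GPx_full = 0, HEDH_full = 0,
    LOOH = 0, Ca = 100)
  tc <- los_simulate(e_closed, p_closed, t_end = 200, n_points = 21,
    init = los_state(AA = 20, HP = 0.5))
  total <- tc$AA + tc$HP + tc$LTA4
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-7)
  # and the cycle is actually turning over
  expect_lt(tc$AA[21], tc$AA[1])
})

test_that("steady state converges, is self-consistent and init-independent", {
  e <- los_scenario("fig10_table2_base")
  ss <- los_steady_state(e, p0)
  expect_true(ss$converged)
  expect_lte(ss$residual_norm, 1e-9)
  expect_lte(max(abs(los_rhs(ss$state, e, p0))), 1e-6)

  # steady-state flux balances implied by the mass balances
  v <- los_rates(ss$state, e, p0)
  expect_equal(v$V_AA_PLA2, v$V_AAcons, tolerance = 1e-6)
  expect_equal(v$V_LTAsyn, p0[["k_LTAd"]] * ss$state[["LTA4"]],
    tolerance = 1e-6)
  expect_equal(v$V_HEDH, p0[["k_oxoETEd"]] * ss$state[["oxoETE"]],
    tolerance = 1e-6)

  # a second, distinct initial condition lands on the same state
  ss2 <- los_steady_state(e, p0,
    init = los_state(AA = 1, HP = 5, HT = 0.5, LTA4 = 0.01, oxoETE = 10))
  for (nm in names(ss$state)) {
    expect_equal(ss2$state[[nm]], ss$state[[nm]], tolerance = 1e-3,
      label = nm)
  }

  # long-time limit of plain integration agrees with the polished state
  tc <- los_simulate(e, p0, times = c(0, 5e4))
  expect_equal(unname(unlist(tc[2, -1])), unname(ss$state),
    tolerance = 1e-3)
})

test_that("without 5-LO there is no AA steady state but products vanish", {
  e <- los_environment(Fa = 0, cpla2_scale = 1e-3)
  ss <- los_steady_state(e, p0, init = los_state(LTA4 = 0.5, oxoETE = 1),
    t_max = 2^14)
  expect_false(ss$converged)
  expect_false(ss$species_converged[["AA"]])
  expect_lt(ss$state[["LTA4"]], 1e-6)
  expect_lt(abs(ss$residuals[["LTA4"]]), 1e-9)
})

test_that("clamped species stay fixed while the rest relax", {
  e <- los_scenario("fig10_table2_base")
  init <- los_state(AA = 0.123, HP = 1, HT = 0.1)
  ss <- los_steady_state(e, p0, init = init, clamp = "AA")
  expect_identical(ss$state[["AA"]], 0.123)
  expect_true(ss$converged)  # convergence judged on the free species
  free <- setdiff(names(init), "AA")
  expect_lte(max(abs(los_rhs(ss$state, e, p0)[free])), 1e-8)
})

test_that("negative concentration excursions are flagged, not hidden", {
  # starting below zero must warn
  expect_warning(
    los_simulate(los_environment(Fa = 0, PL = 0), p0, t_end = 1,
      init = los_state(LTA4 = -1e-3)),
    "negative concentration")
})

test_that("tidy time-course export carries units and round-trips", {
  e <- los_environment(Fa = 0, GPx_full = 0, HEDH_full = 0, PL = 0)
  tc <- los_simulate(e, p0, t_end = 5, n_points = 6,
    init = los_state(LTA4 = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  long <- timecourse_tidy(tc, path)
  expect_true(file.exists(path))
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 5 * 6)
  expect_true(all(back$units == "uM"))
  expect_equal(back$value[back$species == "LTA4"], tc$LTA4)
})
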