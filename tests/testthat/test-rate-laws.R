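p0 <- los_parameters()

test_that("catalytic-cycle terms hit their closed-form anchors", {
  e <- los_environment(Z = 0, Ca = 0)
  tm <- five_lo_terms(los_state(), e, p0)
  expect_equal(tm$Delta_Z, 1)
  expect_equal(tm$Delta_2Ca, 1)
  expect_equal(tm$Delta_zCa, 1)
  expect_equal(tm$delta_HP, 1)

  tm <- five_lo_terms(los_state(), los_environment(Z = p0[["K_dz"]]), p0)
  expect_equal(tm$Delta_Z, 2)

  tm <- five_lo_terms(los_state(), los_environment(Ca = p0[["K_2Ca"]]), p0)
  expect_equal(tm$Delta_2Ca, 2)
  expect_equal(tm$rho1, p0[["k_ox"]] + p0[["k_ox2"]])
  expect_equal(tm$rho2, p0[["k_r"]] + p0[["k_r2"]])
})

test_that("the Z/Ca occupancy factorization holds for random inputs", {
  withr::with_seed(41, {
    for (i in 1:25) {
      e <- random_env()
      tm <- five_lo_terms(random_state(), e, p0)
      expect_equal(tm$Delta_zCa,
        tm$Delta_Z * (1 + e[["Ca"]] / p0[["K_3Ca"]]), tolerance = 1e-12)
      expect_gte(tm$Delta_Z, 1)
      expect_gte(tm$Delta_2Ca, 1)
      expect_gte(tm$Delta_zCa, 1)
      expect_gte(tm$delta_HP, 1)
      expect_gt(tm$Delta_tot, 0)
    }
  })
})

test_that("5-LO fluxes vanish in the zero-input limits", {
  e <- los_environment()
  v <- five_lo_rates(los_state(AA = 30, HP = 3), los_environment(Fa = 0), p0)
  expect_true(all(abs(unlist(v)) == 0))

  v <- five_lo_rates(los_state(), los_environment(LOOH = 0, LOH = 0), p0)
  expect_true(all(abs(unlist(v)) == 0))
})

test_that("stoichiometric identities hold exactly at random states", {
  withr::with_seed(42, {
    for (i in 1:25) {
      s <- random_state()
      e <- random_env()
      v <- five_lo_rates(s, e, p0)
      expect_identical(v$V_HTsyn_pseudo, v$V_HPcons_pseudo)
      expect_identical(v$V_LOHsyn_pseudo, v$V_LOOHcons_pseudo)
      # carbon balance of the catalytic cycle: consumed AA leaves either
      # as LTA4 or as net released HP
      expect_equal(v$V_AAcons, v$V_LTAsyn + v$V_HPsyn,
        tolerance = 1e-10)
    }
  })
})

test_that("every enzymatic flux is linear in its enzyme total", {
  withr::with_seed(43, {
    for (i in 1:10) {
      s <- random_state()
      e <- random_env()
      e2 <- e
      e2[["Fa"]] <- 2 * e[["Fa"]]
      v1 <- five_lo_rates(s, e, p0)
      v2 <- five_lo_rates(s, e2, p0)
      for (nm in names(v1)) expect_equal(v2[[nm]], 2 * v1[[nm]])
      e2 <- e; e2[["GPx_full"]] <- 2 * e[["GPx_full"]]
      expect_equal(gpx_rate(s, e2, p0), 2 * gpx_rate(s, e, p0))
      e2 <- e; e2[["HEDH_full"]] <- 2 * e[["HEDH_full"]]
      expect_equal(hedh_rate(s, e2, p0), 2 * hedh_rate(s, e, p0))
    }
  })
})

test_that("inhibitor limits shut the catalytic cycle down", {
  s <- los_state(AA = 30, HP = 1, HT = 0.2)
  e_ref <- los_environment()
  v_ref <- five_lo_rates(s, e_ref, p0)
  # competitive inhibitor saturation: all five fluxes -> 0
  v_pf <- five_lo_rates(s, los_environment(PF = 1e9), p0)
  for (nm in names(v_ref)) {
    expect_lt(abs(v_pf[[nm]]), abs(v_ref[[nm]]) * 1e-4 + 1e-15)
  }
  # redox inhibitor saturation with no peroxide to re-oxidize
  s0 <- los_state(AA = 30, HP = 0)
  v_z <- five_lo_rates(s0, los_environment(Z = 1e9, LOOH = 0), p0)
  v_z0 <- five_lo_rates(s0, los_environment(Z = 0, LOOH = 0), p0)
  expect_lt(v_z$V_AAcons, v_z0$V_AAcons * 1e-4)
})

test_that("calcium acts only through the redox cycle", {
  # with the Ca-stimulated rate constants off and both Ca sites saturated
  # away, fluxes must be Ca-independent
  p_noca <- los_parameters(k_ox2 = 0, k_r2 = 0, K_2Ca = 1e15, K_3Ca = 1e15)
  s <- los_state(AA = 25, HP = 2, HT = 0.3, oxoETE = 1)
  v0 <- five_lo_rates(s, los_environment(Ca = 0, LOOH = 3, Z = 2), p_noca)
  v1 <- five_lo_rates(s, los_environment(Ca = 1000, LOOH = 3, Z = 2),
    p_noca)
  for (nm in names(v0)) expect_equal(v1[[nm]], v0[[nm]], tolerance = 1e-9)
})

test_that("cPLA2 rate matches its closed form and saturates at Vmax", {
  # half-saturating Ca and PL: 450 * 0.5 * 0.5
  e <- los_environment(Ca = 0.1, PL = 20, cpla2_scale = 1)
  expect_equal(cpla2_rate(los_state(), e, p0), 112.5)
  expect_equal(
    cpla2_rate(los_state(), los_environment(PL = 0, cpla2_scale = 1), p0), 0)
  e_sat <- los_environment(Ca = 1e9, PL = 1e9, cpla2_scale = 1)
  expect_equal(cpla2_rate(los_state(), e_sat, p0), 450, tolerance = 1e-6)
  # monotone in both Ca and PL
  r1 <- cpla2_rate(los_state(), los_environment(Ca = 1, PL = 10,
    cpla2_scale = 1), p0)
  r2 <- cpla2_rate(los_state(), los_environment(Ca = 2, PL = 10,
    cpla2_scale = 1), p0)
  r3 <- cpla2_rate(los_state(), los_environment(Ca = 1, PL = 20,
    cpla2_scale = 1), p0)
  expect_gt(r2, r1)
  expect_gt(r3, r1)
})

test_that("GPx rate: zero limits and product inhibition", {
  e <- los_environment(GSH = 0)
  expect_equal(gpx_rate(los_state(HP = 5), e, p0), 0)
  expect_equal(gpx_rate(los_state(HP = 0), los_environment(), p0), 0)
  # strictly decreasing in HT and in GSSG
  e1 <- los_environment(GSH = 1000, GSSG = 10)
  v_base <- gpx_rate(los_state(HP = 5, HT = 0), e1, p0)
  v_ht <- gpx_rate(los_state(HP = 5, HT = 10), e1, p0)
  expect_lt(v_ht, v_base)
  e2 <- los_environment(GSH = 1000, GSSG = 100)
  expect_lt(gpx_rate(los_state(HP = 5), e2, p0),
    gpx_rate(los_state(HP = 5), e1, p0))
})

test_that("HEDH rate: zero/balance limits and a hand-evaluated anchor", {
  e <- los_environment()
  expect_equal(hedh_rate(los_state(HT = 0, oxoETE = 0), e, p0), 0)
  # numerator balance: pick oxoETE so forward and reverse terms cancel
  ht <- 0.5; nadp <- 300; nadph <- 700
  oxo_bal <- (p0[["k1_hedh"]] * p0[["k2_hedh"]] * (ht / p0[["K_HT_hedh"]]) *
      (nadp / p0[["K_NADP_hedh"]])) /
    (p0[["km1_hedh"]] * p0[["km2_hedh"]] * (nadph / p0[["K_NADPH_hedh"]])) *
    p0[["K_oxoETE_hedh"]]
  e_bal <- los_environment(NADP = nadp, NADPH = nadph)
  expect_equal(hedh_rate(los_state(HT = ht, oxoETE = oxo_bal), e_bal, p0),
    0, tolerance = 1e-12)
  # direct-evaluation anchor at HT = K_HT, NADP = K_NADP, products absent:
  # B = k1*k2, A = 2*k1 + k2, V = HEDH_full * B / A
  e_anchor <- los_environment(NADP = p0[["K_NADP_hedh"]], NADPH = 0,
    HEDH_full = 0.1)
  v_hand <- 0.1 * (88.34 * 1724) / (2 * 88.34 + 1724)
  expect_equal(hedh_rate(los_state(HT = p0[["K_HT_hedh"]]), e_anchor, p0),
    v_hand, tolerance = 1e-12)
  expect_gt(v_hand, 0)
})

test_that("degradation fluxes are first order with the published constants", {
  d0 <- degradation_rates(los_state(), p0)
  expect_true(all(unlist(d0) == 0))
  expect_equal(degradation_rates(los_state(LTA4 = 1), p0)$V_LTAd, 0.07)
  expect_equal(degradation_rates(los_state(HT = 10), p0)$V_HTd, 0.01)
  expect_equal(degradation_rates(los_state(oxoETE = 2), p0)$V_oxoETEd, 0.01)
})

test_that("oxygenase AA sweep shows substrate inhibition with an interior peak", {
  e <- los_scenario("fig4_invitro")
  aa <- seq(1, 300, by = 1)
  v <- vapply(aa, function(a) {
    five_lo_rates(los_state(AA = a, HP = 0.01), e, p0)$V_AAcons
  }, numeric(1))
  i <- which.max(v)
  expect_gt(i, 1)
  expect_lt(i, length(aa))
  expect_gt(v[i], v[length(aa)])
  expect_gt(v[i], v[1])
})

test_that("toy-cycle QSSA null-space oracle reproduces the oxygenase rate law", {
  skip_if_not_installed("MASS")
  # strip the model to a 3-state cycle: free ferric enzyme, AA-bound,
  # HP-complex; no regulatory site, no redox pool, no LTA4 branch
  p_toy <- los_parameters(K_AA_i = 1e14, K_r = 1e14, k_LTAsyn = 0)
  e_toy <- los_environment(Z = 0, PF = 0, Ca = 0, LOOH = 0, LOH = 0,
    Fa = 0.1, cpla2_scale = 0)
  koff <- 1e7                      # fast binding equilibrium at K_AA
  for (AA in c(2, 10.7, 60, 250)) {
    kon <- koff / p_toy[["K_AA"]]
    # transition-rate matrix over (F, F.AA, F.HP); columns sum to zero
    M <- matrix(c(
      -kon * AA,            koff,                 p_toy[["k_3"]],
       kon * AA,           -(koff + p_toy[["k_lo"]]), 0,
       0,                   p_toy[["k_lo"]],     -p_toy[["k_3"]]),
      nrow = 3, byrow = TRUE)
    ns <- MASS::Null(t(M))
    w <- abs(ns[, 1]) / sum(abs(ns[, 1]))
    v_oracle <- p_toy[["k_lo"]] * w[2] * e_toy[["Fa"]]
    v_model <- five_lo_rates(los_state(AA = AA), e_toy, p_toy)$V_AAcons
    expect_equal(v_model, v_oracle, tolerance = 1e-3)
  }
})
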