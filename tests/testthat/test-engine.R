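test_that("identical inputs give bit-identical trajectories", {
  p <- apply_scenario_overrides(default_parameters(),
                                cpsim:::.study3_base())
  a <- simulate_cp(p, 8)
  b <- simulate_cp(p, 8)
  expect_identical(a$ts, b$ts)
  expect_identical(a$beats, b$beats)
  expect_identical(a$final_state, b$final_state)
})

test_that("total blood volume is a first integral of the closed loop", {
  s <- simulate_cp(default_parameters(), 120)
  drift <- max(abs(s$ts$V_blood - default_parameters()$V_blood))
  expect_lt(drift, 1e-6)
})

test_that("volume expansion adds exactly the infused volume and conserves thereafter", {
  p <- volume_expansion(default_parameters(), 500, duration = 20, start = 5)
  s <- simulate_cp(p, 40)
  vb <- s$ts$V_blood
  t <- s$ts$t
  expect_equal(vb[t < 5][1], p$V_blood)
  expect_equal(max(abs(vb[t > 26] - (p$V_blood + 500))), 0,
               tolerance = 1e-6)
  ## zero-volume event leaves the trajectory unchanged
  p0 <- apply_scenario_overrides(default_parameters(), list(
    ve_volume = 0, ve_start = 5, ve_duration = 20))
  expect_identical(simulate_cp(p0, 10)$ts,
                   simulate_cp(default_parameters(), 10)$ts)
})

test_that("derivative evaluation satisfies Kirchhoff balances at every node", {
  p <- default_parameters()
  s <- simulate_cp(p, 15)
  y <- s$final_state
  d <- cpsim:::.engine_derivs(as.numeric(y), s$final_T, unclass(p), 0)
  dy <- d$dy; der <- d$derived
  ## closed loop: compartment derivative sum is zero (no infusion)
  expect_equal(sum(dy[1:14]), 0, tolerance = 1e-10)
  ## chamber mass balance
  expect_equal(dy[14], der[["Q_mv"]] - der[["Q_av"]], tolerance = 1e-10)
  expect_equal(dy[8], der[["Q_tv"]] - der[["Q_rvo"]], tolerance = 1e-10)
  ## arteriolar node: inertance inflow splits into capillary and shunt paths
  expect_equal(dy[10], y[["Q_pa"]] - der[["Q_pal"]] - der[["Q_ps"]],
               tolerance = 1e-10)
  ## capillary and venous nodes
  expect_equal(dy[11], der[["Q_pal"]] - der[["Q_pc"]], tolerance = 1e-10)
  expect_equal(dy[12], der[["Q_pc"]] + der[["Q_ps"]] - der[["Q_pv"]],
               tolerance = 1e-10)
  ## valve flows are non-negative (diode law)
  expect_gte(der[["Q_av"]], 0)
  expect_gte(der[["Q_mv"]], 0)
  expect_gte(der[["Q_tv"]], 0)
  expect_gte(der[["Q_rvo"]], 0)
})

test_that("an all-unstressed state with zero boundary pressures is an equilibrium", {
  p <- apply_scenario_overrides(default_parameters(), list(
    V_u_L = 2, V_u_cw = 2, FRC_nom = 2, amp_mus = 0,
    V_u_pcd = 14 + 12 + 25 + 25 + 40, # pericardium unstressed at chamber volumes
    V_u_vc = 100, V_blood = 1000))
  y <- stats::setNames(numeric(23), cpsim:::.cp_state_names)
  y["V_sa"] <- p$V_u_sa; y["V_sp"] <- p$V_u_sp; y["V_ep"] <- p$V_u_ep
  bas <- basal_autonomic_state(p)
  y["V_sv"] <- bas$V_u_sv; y["V_ev"] <- bas$V_u_ev; y["V_vc"] <- p$V_u_vc
  y["V_ra"] <- p$V_u_ra; y["V_la"] <- p$V_u_la
  y["V_rv"] <- 25; y["V_lv"] <- 25   # symmetric, with V_spt solving to ~0
  y["V_pa"] <- p$V_u_pa; y["V_pal"] <- p$V_u_pal
  y["V_pc"] <- p$V_u_pc; y["V_pv"] <- p$V_u_pv
  y["V_A"] <- 2; y["u"] <- 0; y["xPsa"] <- 0
  y["sTs"] <- bas$L_b; y["sTv"] <- bas$f_ev_b
  y["sE"] <- bas$L_b; y["sR"] <- bas$L_b; y["sVu"] <- bas$L_b
  d <- cpsim:::.engine_derivs(as.numeric(y), 1, unclass(p), 0)
  der <- d$derived
  expect_equal(der[["P_pl"]], 0, tolerance = 1e-9)
  expect_equal(der[["P_A"]], 0, tolerance = 1e-9)
  ## ventricular pressures are the (equal) ED wall pressures; the free
  ## walls are above their unstressed volumes here, so flows are the
  ## only nonzero terms allowed and only through open AV valves is zero:
  expect_equal(d$dy[16], 0, tolerance = 1e-9)           # dV_A
  expect_equal(sum(d$dy[1:14]), 0, tolerance = 1e-10)   # closed loop
  ## pulmonary nodes with zero boundary pressures sit at equilibrium
  expect_equal(d$dy[10], 0, tolerance = 1e-9)           # arterioles
  expect_equal(d$dy[11], 0, tolerance = 1e-9)           # capillaries
  expect_equal(d$dy[12], 0, tolerance = 1e-9)           # veins
  expect_equal(d$dy[15], 0, tolerance = 1e-9)           # inertance flow
  expect_lt(abs(der[["V_spt"]]), 1)                     # near-symmetric
})

test_that("halving the integration step leaves the short-run trajectory unchanged to high order", {
  p <- default_parameters()
  a <- simulate_cp(p, 5, dt = 5e-4, record_dt = 0.05)
  b <- simulate_cp(p, 5, dt = 2.5e-4, record_dt = 0.05)
  rel <- abs(a$final_state - b$final_state) /
    pmax(abs(b$final_state), 1)
  expect_lt(max(rel), 1e-3)
})

test_that("periodic-state search stops once breath summaries repeat", {
  p <- study3_params()
  warm <- simulate_cp(p, 200)
  t0 <- Sys.time()
  s <- find_periodic_state(p, max_time = 120, tol = 5e-3,
                           init = warm$final_state, T_beat = warm$final_T)
  expect_s3_class(s, "cp_sim")
  ## already periodic: returns after a couple of chunks, well under max_time
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 30)
  ## tol = 0 always exhausts max_time (with a warning)
  expect_warning(find_periodic_state(p, max_time = 32, tol = 0, chunk = 16),
                 "not converged")
})

test_that("pressures stay finite and volumes positive across scenario extremes", {
  p <- apply_scenario_overrides(default_parameters(),
    utils::modifyList(cpsim:::.study2_base(), list(PEEP = 20)))
  s <- simulate_cp(p, 60)
  vols <- s$ts[, c("V_lv", "V_rv", "V_la", "V_ra", "V_A")]
  expect_true(all(is.finite(as.matrix(s$ts))))
  expect_true(all(vols > 0))
})
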