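test_that("static equilibrium at zero airway pressure defines the FRC", {
  p <- default_parameters()
  eq <- frc_equilibrium(p, 0)
  expect_equal(eq, 2.25, tolerance = 1e-6)
  d <- respiratory_derivatives(eq, 0, 0, p)
  expect_equal(d$dV_A, 0, tolerance = 1e-9)
  expect_equal(d$P_A, 0, tolerance = 1e-9)
  ## FRC_nom default is consistent with the nominal mechanics
  expect_equal(p$FRC_nom, frc_equilibrium(p, 0), tolerance = 1e-6)
})

test_that("series respiratory compliance matches the ventilated-study configurations", {
  s3 <- study3_params()
  crs <- s3$C_L * s3$C_cw / (s3$C_L + s3$C_cw)
  expect_equal(crs, 0.039, tolerance = 0.0005 / 0.039)
  s2 <- apply_scenario_overrides(default_parameters(), cpsim:::.study2_base())
  expect_equal(s2$C_L * s2$C_cw / (s2$C_L + s2$C_cw), 0.0394,
               tolerance = 1e-3)
})

test_that("relaxation toward a pressure step is first order with time constant R_aw * C_series", {
  p <- default_parameters()
  crs <- p$C_L * p$C_cw / (p$C_L + p$C_cw)
  frc <- frc_equilibrium(p, 0)
  v_inf <- frc_equilibrium(p, 10)
  ## dV/dt = (V_inf - V) / (R_aw * C_series) for any V: linear relaxation
  for (v in c(frc, 2.4, 2.6, v_inf)) {
    d <- respiratory_derivatives(v, 10, 0, p)
    expect_equal(d$dV_A, (v_inf - v) / (p$R_aw * crs), tolerance = 1e-10)
  }
})

test_that("FRC calibration rescales unstressed volumes to hit the target equilibrium", {
  p <- default_parameters()
  q <- calibrate_frc(p, 3.1)
  expect_equal(frc_equilibrium(q, 0), 3.1, tolerance = 1e-9)
  ## symmetric compliances with equal unstressed volumes: FRC = V_u
  sym <- apply_scenario_overrides(p, list(C_L = 0.15, C_cw = 0.15,
                                          V_u_L = 1.8, V_u_cw = 1.8,
                                          FRC_nom = 1.8))
  expect_equal(frc_equilibrium(sym, 0), 1.8)
  expect_error(calibrate_frc(p, 0), "positive")
})

test_that("ventilator waveform honors PEEP floor, period, and mode", {
  none <- default_parameters()
  expect_identical(ventilator_pressure(seq(0, 10, 0.1), none),
                   rep(0, 101))
  p <- apply_scenario_overrides(none, list(
    vent_mode = "PCV", PEEP = 5, support = 3, RR = 15, IE_ratio = 0.5))
  t <- seq(0, 12, by = 0.001)
  pao <- ventilator_pressure(t, p)
  expect_true(all(pao >= 5 - 1e-12))
  ## period 4 s: expiratory plateau at PEEP, inspiratory at PEEP + support
  expect_equal(ventilator_pressure(3.9, p), 5)
  expect_equal(ventilator_pressure(3.9 + 4, p), 5)
  expect_equal(ventilator_pressure(1.0, p), 8)
  expect_equal(ventilator_pressure(1.0 + 4, p), 8)
  ## stepping PEEP shifts the end-expiratory pressure one for one
  p20 <- apply_scenario_overrides(p, list(PEEP = 20))
  expect_equal(ventilator_pressure(3.9, p20) - ventilator_pressure(3.9, p),
               15)
  ## VCV rises linearly through inspiration to the same plateau
  pv <- apply_scenario_overrides(p, list(vent_mode = "VCV"))
  ti <- 4 / 3
  ramp <- ventilator_pressure(c(0.25, 0.5, 1) * ti, pv)
  expect_equal(ramp, 5 + 3 * c(0.25, 0.5, 1), tolerance = 1e-9)
})

test_that("spontaneous effort waveform is inspiratory-only and vanishes when sedated", {
  p <- default_parameters()
  t <- seq(0, 10, by = 0.01)
  pm <- muscle_pressure(t, p)
  expect_true(all(pm >= 0))
  expect_equal(max(pm), p$amp_mus, tolerance = 1e-3)
  ## expiration (last two thirds of the 5 s spontaneous cycle) is passive
  expect_equal(muscle_pressure(3, p), 0)
  sed <- apply_scenario_overrides(p, list(amp_mus = 0))
  expect_identical(muscle_pressure(t, sed), rep(0, length(t)))
})

test_that("PEEP-induced pleural pressure rise grows as lung elastance falls relative to the chest wall", {
  ## same total elastance partitioned two ways: compliant lung + stiff
  ## chest wall transmits PEEP to the pleural space far more than the
  ## stiff lung + compliant chest wall partition
  dppl <- function(E_L, E_cw, peep) {
    p <- apply_scenario_overrides(default_parameters(), list(
      C_L = 1 / E_L, C_cw = 1 / E_cw, V_u_L = 0.4, V_u_cw = 1))
    v0 <- frc_equilibrium(p, 0); v1 <- frc_equilibrium(p, peep)
    (v1 - p$V_u_cw) / p$C_cw - (v0 - p$V_u_cw) / p$C_cw
  }
  d_ardsp <- dppl(20.23, 5.31, 10)   # stiff lung, compliant chest wall
  d_ardsexp <- dppl(15.95, 15.88, 10) # balanced partitioning
  expect_lt(d_ardsp, d_ardsexp)
  ## analytic check: static transmission ratio is E_cw / (E_L + E_cw)
  expect_equal(d_ardsp, 10 * 5.31 / (20.23 + 5.31), tolerance = 1e-9)
  expect_equal(d_ardsexp, 10 * 15.88 / (15.95 + 15.88), tolerance = 1e-9)
})
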