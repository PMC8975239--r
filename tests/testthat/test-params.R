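test_that("default parameter set reproduces the printed basal values", {
  p <- default_parameters()
  ## heart walls and pericardium
  expect_equal(p$E_max_lvf0, 2.392)
  expect_equal(p$E_max_rvf0, 1.412)
  expect_equal(p$E_max_spt0, 32.4)
  expect_equal(c(p$k_E_rvf, p$k_E_lvf, p$k_E_pcd, p$k_E_spt),
               c(0.011, 0.014, 0.005, 0.175))
  expect_equal(c(p$P_0_rvf, p$P_0_lvf, p$P_0_pcd, p$P_0_spt),
               c(1.5, 1.5, 0.5, 1.11))
  expect_equal(c(p$V_u_rvf, p$V_u_lvf, p$V_u_pcd, p$V_u_spt),
               c(35.904, 14.758, 200, 0))
  expect_equal(p$V_peri, 40)
  ## pulmonary circulation
  expect_equal(p$C_pa, 0.76)
  expect_equal(p$R_pa, 0.023)
  expect_equal(p$L_pa, 1.8e-4)
  expect_equal(p$C_pal, 5.8 / 3)
  expect_equal(p$C_pc, 2 * 5.8 / 3)
  expect_equal(p$V_u_pal, 108.24 * 0.4)
  expect_equal(p$V_u_pc, 108.24 * 0.6)
  expect_equal(c(p$C_pv, p$V_u_pv, p$R_pv), c(25.37, 105.6, 0.0056))
  expect_equal(p$R_pp_tot, 0.0894)
  ## respiratory nominal values and basal heart period
  expect_equal(p$R_aw, 1.7459)
  expect_equal(c(p$C_L, p$C_cw), c(0.2, 0.2445))
  expect_equal(p$T_0, 0.58)
  expect_equal(p$BSA, 1.9)
})

test_that("configuration loading applies overrides and rejects bad input", {
  ## empty document -> pericardial defaults
  p <- load_parameters(NULL)
  expect_equal(p$k_E_pcd, 0.005)
  expect_equal(p$P_0_pcd, 0.5)
  expect_equal(p$V_u_pcd, 200)
  ## single override leaves everything else untouched
  p2 <- load_parameters(list(T_0 = 0.27))
  expect_equal(p2$T_0, 0.27)
  same <- setdiff(names(p), "T_0")
  expect_identical(p2[same], p[same])
  ## sectioned documents are accepted
  p3 <- load_parameters(list(heart = list(T_0 = 0.35),
                             ventilator = list(PEEP = 5)))
  expect_equal(p3$T_0, 0.35)
  expect_equal(p3$PEEP, 5)
  ## bounds and schema violations
  expect_error(load_parameters(list(sh = 1.2)), "sh")
  expect_error(load_parameters(list(not_a_param = 1)), "not_a_param")
  expect_error(load_parameters(list(PEEP = -2)), "PEEP")
  expect_error(load_parameters(list(chemo_central_gain = 1)), "chemoreflex")
})

test_that("parameter serialization round-trips bit-exactly", {
  p <- load_parameters(list(T_0 = 0.27, sh = 0.35, PEEP = 7.5))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  q <- load_parameters(f)
  num <- names(p)[vapply(p, is.numeric, logical(1))]
  for (nm in num) expect_identical(q[[nm]], p[[nm]], label = nm)
  expect_identical(q$vent_mode, p$vent_mode)
})

test_that("scenario overrides return modified copies and leave base intact", {
  base <- default_parameters()
  s3 <- apply_scenario_overrides(base, cpsim:::.study3_base())
  expect_equal(s3$C_L, 0.06)
  expect_equal(s3$C_cw, 0.11)
  expect_equal(s3$E_max_lvf0, 1.9)
  expect_equal(s3$T_0, 0.35)
  s2 <- apply_scenario_overrides(base, cpsim:::.study2_base())
  expect_equal(s2$R_sp0, 1)
  expect_equal(s2$R_ep0, 0.5)
  expect_equal(s2$R_pp_tot, 0.23)
  expect_equal(s2$sh, 0.35)
  ## base untouched, empty override is the identity
  expect_equal(base$C_L, 0.2)
  expect_identical(apply_scenario_overrides(base, list()), base)
  expect_error(apply_scenario_overrides(base, list(nope = 1)), "nope")
})

test_that("pulmonary compliance/unstressed-volume split follows the 2:1 and 3:2 conventions", {
  s <- derive_pulmonary_splits(5.8, 108.24)
  expect_equal(round(s$C_pal, 2), 1.93)
  expect_equal(round(s$C_pc, 2), 3.87)
  expect_equal(round(s$V_u_pal, 2), 43.30)
  expect_equal(round(s$V_u_pc, 2), 64.94)
  expect_identical(derive_pulmonary_splits(3, 5),
                   list(C_pal = 1, C_pc = 2, V_u_pal = 2, V_u_pc = 3))
  expect_equal(derive_pulmonary_splits(1, 1)$C_pal, 1 / 3)
  expect_equal(derive_pulmonary_splits(1, 1)$V_u_pal, 0.4)
  ## structural identities for arbitrary inputs
  for (x in list(c(2.3, 57), c(0.11, 4000), c(9, 0.5))) {
    s <- derive_pulmonary_splits(x[1], x[2])
    expect_equal(s$C_pc, 2 * s$C_pal)
    expect_equal(s$V_u_pc, 1.5 * s$V_u_pal)
    expect_equal(s$C_pal + s$C_pc, x[1])
    expect_equal(s$V_u_pal + s$V_u_pc, x[2])
  }
  expect_error(derive_pulmonary_splits(-1, 5), "positive")
})

test_that("peripheral resistance partition satisfies the lumped-resistance and flow-divider identities", {
  pr <- partition_peripheral_resistances(0.0894, 0.017)
  expect_equal(pr$R_pal_frc, 0.0894 / (2 * 0.983))
  expect_equal(pr$R_pal_frc, 0.04548, tolerance = 3e-4)
  expect_equal(pr$R_ps, 5.259, tolerance = 1e-4)
  for (x in list(c(0.0894, 0.017), c(0.23, 0.35), c(1.7, 0.6))) {
    pr <- partition_peripheral_resistances(x[1], x[2])
    ## parallel-series recombination returns the lumped value exactly
    ser <- pr$R_pc + pr$R_pal_frc
    expect_equal(pr$R_ps * ser / (pr$R_ps + ser), x[1])
    ## conductance split routes fraction sh through the shunt
    expect_equal((1 / pr$R_ps) / (1 / pr$R_ps + 1 / ser), x[2])
  }
  ## sh -> 0: shunt branch disabled, gas path carries the full resistance
  pr0 <- partition_peripheral_resistances(0.0894, 0)
  expect_identical(pr0$R_ps, Inf)
  expect_equal(pr0$R_pal_frc + pr0$R_pc, 0.0894)
  expect_error(partition_peripheral_resistances(0.0894, 1), "sh")
})

test_that("arteriolar resistance grows quadratically with lung inflation", {
  expect_equal(variable_rpal(2.25, 0, 0.0894, 2.25), 0.0894 / 2)
  expect_equal(variable_rpal(2.25, 0.35, 0.23, 2.25), 0.23 / (2 * 0.65))
  expect_equal(round(variable_rpal(2.25, 0.35, 0.23, 2.25), 4), 0.1769)
  expect_equal(variable_rpal(4.5, 0, 0.0894, 2.25), 2 * 0.0894)
  expect_error(variable_rpal(-1, 0, 0.0894), "V_A")
  expect_error(variable_rpal(2, 1, 0.0894), "sh")
})
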