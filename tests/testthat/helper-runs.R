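## Shared simulation runs, computed once per test session. Acceptance
## tests and several unit tests consume the same long runs; caching
## keeps the suite fast without changing what is computed.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

## nominal resting simulation (spontaneous quiet breathing, no ventilator)
nominal_run <- function(duration = 2000) {
  cached_run(paste0("nominal_", duration),
             simulate_cp(default_parameters(), duration))
}

## the intra-breath ventilation configuration (sedated, PCV, PEEP 5,
## RR 15, end-inspiratory pause) used for SVV analyses
study3_params <- function(extra = list()) {
  apply_scenario_overrides(default_parameters(),
                           utils::modifyList(cpsim:::.study3_base(), extra))
}

study3_run <- function() cached_run("study3", {
  simulate_cp(study3_params(), 240)
})

## mean per-breath SVV/dPP over the trailing window of a run
svv_of <- function(sim, window = 60) {
  beats <- segment_beats(sim)
  br <- breath_summaries(beats, sim$breath_starts)
  br <- br[br$t_start >= sim$t_end - window & is.finite(br$SVV_lv), ,
           drop = FALSE]
  c(SVV_lv = mean(br$SVV_lv), SVV_rv = mean(br$SVV_rv),
    dPP = mean(br$dPP))
}

## end-expiratory beat summary (means over the last few such beats)
end_exp_surface <- function(sim, n = 3) {
  b <- segment_beats(sim)
  ee <- b[b$end_expiratory, , drop = FALSE]
  colMeans(utils::tail(ee, n))
}

## brute-force bisection oracle for the septal volume balance
bisect_vspt <- function(V_lv, V_rv, phi, p,
                        E_lvf = p$E_max_lvf0, E_rvf = p$E_max_rvf0,
                        E_spt = p$E_max_spt0, tol = 1e-12) {
  g <- function(vs)
    wall_pressure(vs, phi, E_spt, p$V_u_spt, p$P_0_spt, p$k_E_spt) -
    wall_pressure(V_lv - vs, phi, E_lvf, p$V_u_lvf, p$P_0_lvf, p$k_E_lvf) +
    wall_pressure(V_rv + vs, phi, E_rvf, p$V_u_rvf, p$P_0_rvf, p$k_E_rvf)
  lo <- -V_rv - 100; hi <- V_lv + 100
  stopifnot(g(lo) < 0, g(hi) > 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
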