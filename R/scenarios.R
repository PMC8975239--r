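## Built-in simulation protocols: ventilation studies, sensitivity grids
## and pathology comparisons. Each scenario is an ordered list of phases;
## a phase holds parameter overrides, a duration and an analysis window.
## Default durations are shortened relative to the clinical protocols
## they emulate (the autonomic effectors settle within ~2 minutes, see
## the methods vignette); `full_duration = TRUE` restores the long
## phases.

.study2_base <- function() list(
  E_max_lvf0 = 4, E_max_rvf0 = 0.4, k_E_lvf = 0.007, k_E_rvf = 0.0065,
  T_0 = 0.27, R_sp0 = 1, R_ep0 = 0.5, R_pp_tot = 0.23, sh = 0.35,
  C_L = 0.065, C_cw = 0.1, V_u_L = 0.4, V_u_cw = 1,
  amp_mus = 0, FiO2 = 0.5,
  vent_mode = "PCV", RR = 15, IE_ratio = 0.5, support = 19, PEEP = 0)

.study3_base <- function() list(
  E_max_lvf0 = 1.9, k_E_lvf = 0.016, k_E_rvf = 0.011,
  P_0_lvf = 0.8, P_0_rvf = 1.5,
  T_0 = 0.35, R_sp0 = 3, R_ep0 = 1,
  C_L = 0.06, C_cw = 0.11, V_u_L = 0.4, V_u_cw = 1,
  amp_mus = 0,
  vent_mode = "PCV", RR = 15, IE_ratio = 0.5, end_insp_pause = 0.5,
  support = 15.5, PEEP = 5)

.study1_base <- function() list(
  E_max_lvf0 = 3.05, E_max_rvf0 = 0.8, k_E_lvf = 0.008, k_E_rvf = 0.007)

## pathology configurations for the pulse-pressure-variation protocol:
## hypovolemia = reduced total blood volume; sepsis = reduced systemic
## peripheral resistances; both calibrated once to the same low mean
## arterial pressure (see methods vignette).
.hypovolemic_base <- function() c(.study2_base()[
  c("C_L", "C_cw", "V_u_L", "V_u_cw", "amp_mus", "vent_mode", "RR",
    "IE_ratio", "support")], list(V_blood = 4700, PEEP = 0))

.septic_base <- function() c(.study2_base()[
  c("C_L", "C_cw", "V_u_L", "V_u_cw", "amp_mus", "vent_mode", "RR",
    "IE_ratio", "support")], list(R_sp0 = 0.95, R_ep0 = 0.35, PEEP = 0))

.peep_phases <- function(base, peeps, dur, extra = NULL) {
  lapply(peeps, function(pp)
    list(name = paste0("PEEP", pp),
         overrides = utils::modifyList(c(base, extra %||% list()),
                                       list(PEEP = pp)),
         duration = dur))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in scenario specifications
#'
#' Returns the phase list of a named protocol. Available scenarios:
#' \describe{
#'   \item{table3_baseline}{nominal resting conditions, spontaneous
#'     quiet breathing, no ventilator; one long phase.}
#'   \item{study1_ppv}{spontaneously breathing subject under increasing
#'     pressure support: no ventilation, then PEEP 10 and PEEP 20 with
#'     3 cmH2O support.}
#'   \item{study2_peep_ve}{sedated, ventilated patient; PEEP ladder
#'     0..20 cmH2O in 5 cmH2O steps, then volume expansion (625 ml) at
#'     PEEP 20.}
#'   \item{study3_intrabreath}{sedated, ventilated patient at PEEP 5
#'     with an end-inspiratory pause; the intra-breath analysis
#'     configuration.}
#'   \item{ards_partitioning}{PEEP ladder under pulmonary-ARDS
#'     (stiff lung, compliant chest wall) and extrapulmonary-ARDS
#'     (balanced) elastance partitioning.}
#'   \item{volemia_dpp}{hypovolemic vs septic virtual patient: PEEP
#'     0 -> 10 application and a separate 500 ml volume-expansion arm.}
#' }
#'
#' @param name scenario name.
#' @param full_duration use the full clinical phase durations instead of
#'   the shortened defaults.
#' @return list with elements \code{name}, \code{phases},
#'   \code{analysis_window} (s).
#' @export
scenario_spec <- function(name, full_duration = FALSE) {
  dur <- if (full_duration) 1200 else 180
  aw <- if (full_duration) 600 else 60
  spec <- switch(
    name,
    table3_baseline = list(
      phases = list(list(name = "baseline", overrides = list(),
                         duration = if (full_duration) 2000 else 300)),
      analysis_window = 30),
    study1_ppv = list(
      phases = list(
        list(name = "PPV0", overrides = .study1_base(), duration = dur),
        list(name = "PPV10",
             overrides = c(.study1_base(),
                           list(vent_mode = "PSV", support = 3, PEEP = 10,
                                RR = 12, IE_ratio = 0.5)),
             duration = dur),
        list(name = "PPV20",
             overrides = c(.study1_base(),
                           list(vent_mode = "PSV", support = 3, PEEP = 20,
                                RR = 12, IE_ratio = 0.5)),
             duration = dur)),
      analysis_window = aw),
    study2_peep_ve = {
      ph <- .peep_phases(.study2_base(), seq(0, 20, by = 5), dur)
      ve_dur <- if (full_duration) 600 else 60
      ph <- c(ph, list(list(
        name = "PEEP20+VE",
        overrides = utils::modifyList(
          .study2_base(),
          list(PEEP = 20, ve_volume = 625, ve_start = 0,
               ve_duration = ve_dur)),
        duration = dur + ve_dur)))
      list(phases = ph, analysis_window = aw)
    },
    study3_intrabreath = list(
      phases = list(list(name = "PEEP5", overrides = .study3_base(),
                         duration = if (full_duration) 1200 else 240)),
      analysis_window = aw),
    ards_partitioning = {
      ## ARDS virtual patients: study-2 cardiovascular configuration with
      ## the lung/chest-wall elastance partitioning of the two groups
      mk <- function(C_L, C_cw)
        .peep_phases(utils::modifyList(.study2_base(),
                                       list(C_L = C_L, C_cw = C_cw)),
                     seq(0, 20, by = 5), dur)
      list(phases = list(ARDSp = mk(1 / 20.23, 1 / 5.31),
                         ARDSexp = mk(1 / 15.95, 1 / 15.88)),
           analysis_window = aw, grouped = TRUE)
    },
    volemia_dpp = list(
      phases = list(
        hypovolemic = list(
          list(name = "PEEP0", overrides = .hypovolemic_base(),
               duration = dur),
          list(name = "PEEP10",
               overrides = utils::modifyList(.hypovolemic_base(),
                                             list(PEEP = 10)),
               duration = dur),
          list(name = "VE",
               overrides = utils::modifyList(
                 .hypovolemic_base(),
                 list(ve_volume = 500, ve_start = 0,
                      ve_duration = if (full_duration) 600 else 60)),
               duration = dur + if (full_duration) 600 else 60)),
        septic = list(
          list(name = "PEEP0", overrides = .septic_base(),
               duration = dur),
          list(name = "PEEP10",
               overrides = utils::modifyList(.septic_base(),
                                             list(PEEP = 10)),
               duration = dur),
          list(name = "VE",
               overrides = utils::modifyList(
                 .septic_base(),
                 list(ve_volume = 500, ve_start = 0,
                      ve_duration = if (full_duration) 600 else 60)),
               duration = dur + if (full_duration) 600 else 60))),
      analysis_window = aw, grouped = TRUE),
    stop("unknown scenario: ", name))
  spec$name <- name
  spec
}

.run_phase_list <- function(phases, base, analysis_window, dt, record_dt) {
  sim <- NULL
  out <- list()
  rows <- list()
  for (ph in phases) {
    p <- apply_scenario_overrides(base, ph$overrides)
    sim <- if (is.null(sim))
      simulate_cp(p, ph$duration, dt = dt, record_dt = record_dt)
    else
      continue_cp(sim, ph$duration, params = p,
                  dt = dt, record_dt = record_dt)
    beats <- segment_beats(sim)
    breaths <- breath_summaries(beats, sim$breath_starts)
    avg <- phase_average(beats, window = analysis_window, BSA = p$BSA,
                         end_expiratory_only = any(beats$end_expiratory))
    bw <- breaths[breaths$t_start >= sim$t_end - analysis_window &
                    is.finite(breaths$SVV_lv), , drop = FALSE]
    avg$SVV_lv <- if (nrow(bw)) mean(bw$SVV_lv) else NA_real_
    avg$SVV_rv <- if (nrow(bw)) mean(bw$SVV_rv) else NA_real_
    avg$dPP <- if (nrow(bw)) mean(bw$dPP) else NA_real_
    avg <- cbind(data.frame(phase = ph$name), avg)
    rows[[length(rows) + 1]] <- avg
    out[[ph$name]] <- sim
  }
  list(sims = out, summary = do.call(rbind, rows))
}

#' Run a built-in or user-supplied scenario
#'
#' Executes the phases of a protocol sequentially, carrying the model
#' state across phase boundaries (parameters change stepwise at phase
#' onset and are then held constant), and summarises each phase over its
#' trailing analysis window at end-expiratory beats.
#'
#' @param name scenario name (see [scenario_spec()]) or a spec list of
#'   the same shape.
#' @param params base parameter set the phase overrides are applied to.
#' @param full_duration use full clinical phase durations.
#' @param dt,record_dt integration and recording steps (s).
#' @return object of class \code{cp_scenario}: list with \code{name},
#'   \code{summary} (one row per phase, per group for grouped
#'   scenarios), and \code{sims} (the per-phase simulations).
#' @export
run_scenario <- function(name, params = default_parameters(),
                         full_duration = FALSE, dt = 5e-4,
                         record_dt = 0.01) {
  spec <- if (is.character(name)) scenario_spec(name, full_duration)
          else name
  if (isTRUE(spec$grouped)) {
    res <- lapply(names(spec$phases), function(g) {
      r <- .run_phase_list(spec$phases[[g]], params, spec$analysis_window,
                           dt, record_dt)
      r$summary <- cbind(data.frame(group = g), r$summary)
      r
    })
    names(res) <- names(spec$phases)
    out <- list(name = spec$name,
                summary = do.call(rbind, lapply(res, `[[`, "summary")),
                sims = lapply(res, `[[`, "sims"))
  } else {
    r <- .run_phase_list(spec$phases, params, spec$analysis_window,
                         dt, record_dt)
    out <- list(name = spec$name, summary = r$summary, sims = r$sims)
  }
  rownames(out$summary) <- NULL
  class(out) <- "cp_scenario"
  out
}

#' @export
print.cp_scenario <- function(x, ...) {
  cat("<cp_scenario> ", x$name, "\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Parameter sensitivity sweep of stroke volume variation
#'
#' Runs the intra-breath ventilation configuration with one scalar
#' parameter scaled by each factor in \code{factors} and reports LV and
#' RV stroke volume variation together with their perturbed-over-baseline
#' (P/B) ratios.
#'
#' @param parameter parameter name (e.g. "k_E_spt", "k_E_pcd",
#'   "R_pp_tot", or any scalar parameter).
#' @param factors multiplicative factors (1 is run as the baseline
#'   reference and always included).
#' @param base_overrides configuration the sweep is built on (defaults
#'   to the intra-breath study configuration).
#' @param params base parameter set.
#' @param settle settling time before the analysis window (s).
#' @param dt integration step (s).
#' @return data.frame with factor, SVV_lv, SVV_rv, PB_lv, PB_rv.
#' @export
sweep_svv <- function(parameter, factors = c(0.5, 1, 2),
                      base_overrides = .study3_base(),
                      params = default_parameters(),
                      settle = 180, analysis_window = 60, dt = 5e-4) {
  factors <- sort(unique(c(1, factors)))
  base <- apply_scenario_overrides(params, base_overrides)
  if (is.null(base[[parameter]]))
    stop("unknown parameter: ", parameter)
  one <- function(f) {
    p <- apply_scenario_overrides(
      base, stats::setNames(list(base[[parameter]] * f), parameter))
    sim <- simulate_cp(p, settle + analysis_window, dt = dt)
    beats <- segment_beats(sim)
    br <- breath_summaries(beats, sim$breath_starts)
    br <- br[br$t_start >= sim$t_end - analysis_window &
               is.finite(br$SVV_lv), , drop = FALSE]
    c(SVV_lv = mean(br$SVV_lv), SVV_rv = mean(br$SVV_rv))
  }
  res <- t(vapply(factors, one, c(SVV_lv = 0, SVV_rv = 0)))
  base_row <- which(factors == 1)
  out <- data.frame(factor = factors, SVV_lv = res[, 1], SVV_rv = res[, 2],
                    PB_lv = res[, 1] / res[base_row, 1],
                    PB_rv = res[, 2] / res[base_row, 2])
  rownames(out) <- NULL
  out
}
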