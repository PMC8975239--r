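.cp_state_names <- c(
  "V_sa", "V_sp", "V_ep", "V_sv", "V_ev", "V_vc", "V_ra", "V_rv",
  "V_pa", "V_pal", "V_pc", "V_pv", "V_la", "V_lv", "Q_pa", "V_A", "u",
  "xPsa", "sTs", "sTv", "sE", "sR", "sVu")

#' Construct a physiologically plausible initial model state
#'
#' Distributes the total blood volume over the compartments at rough
#' resting pressures, sets the alveolar volume to its static equilibrium
#' under the configured PEEP, and initialises the autonomic effector
#' states at their setpoint (basal tone) values. Any run should be given
#' a settling period before analysis; this state only needs to be inside
#' the model's basin of attraction.
#'
#' @param params a \code{cp_params} object.
#' @return named state vector (23 entries).
#' @export
initial_state <- function(params) {
  p <- params
  bas <- basal_autonomic_state(p)
  y <- stats::setNames(numeric(23), .cp_state_names)
  y["V_sa"] <- p$V_u_sa + p$C_sa * 90
  y["V_sp"] <- p$V_u_sp + p$C_sp * 15
  y["V_ep"] <- p$V_u_ep + p$C_ep * 15
  y["V_sv"] <- bas$V_u_sv + p$C_sv * 5
  y["V_ev"] <- bas$V_u_ev + p$C_ev * 5
  y["V_vc"] <- p$V_u_vc + p$C_vc * 5
  y["V_ra"] <- p$V_u_ra + 40
  y["V_rv"] <- 120
  y["V_pa"] <- p$V_u_pa + p$C_pa * 16
  y["V_pal"] <- p$V_u_pal + p$C_pal * 13
  y["V_pc"] <- p$V_u_pc + p$C_pc * 10
  y["V_pv"] <- p$V_u_pv + p$C_pv * 8
  y["V_la"] <- p$V_u_la + 40
  y["V_lv"] <- 120
  ## enforce the closed-loop first integral exactly
  excess <- p$V_blood - sum(y[1:14])
  y["V_sv"] <- y["V_sv"] + excess * 0.55
  y["V_ev"] <- y["V_ev"] + excess * 0.45
  if (y["V_sv"] < 0 || y["V_ev"] < 0)
    stop("initial_state: total blood volume too small for unstressed volumes")
  y["Q_pa"] <- 0
  y["V_A"] <- frc_equilibrium(p, P_ao = if (p$vent_mode == "none") 0 else p$PEEP)
  y["u"] <- 0
  y["xPsa"] <- p$P_n
  y["sTs"] <- bas$L_b
  y["sTv"] <- bas$f_ev_b
  y["sE"] <- bas$L_b
  y["sR"] <- bas$L_b
  y["sVu"] <- bas$L_b
  y
}

#' Simulate the cardiopulmonary model
#'
#' Integrates the full coupled system with the classic fourth-order
#' Runge-Kutta method at a fixed step (default 0.0005 s, i.e. 2 kHz).
#' The interventricular septum is solved algebraically inside every
#' derivative evaluation; the heart period is refreshed from the
#' autonomic effectors at each cardiac-cycle rollover. Identical inputs
#' produce bit-identical outputs.
#'
#' Per-beat summaries (end-diastolic and minimum volumes, arterial
#' pressure extrema, mean pressures) are accumulated at the full
#' integration rate regardless of the recording decimation.
#'
#' @param params a \code{cp_params} object.
#' @param duration simulated time (s).
#' @param dt integration step (s).
#' @param record_dt sampling period of the recorded time series (s).
#' @param init initial state vector (from [initial_state()] or a
#'   previous run's \code{$final_state}); NULL builds the default.
#' @param T_beat heart period for the first beat (s); NA uses the basal
#'   autonomic value.
#' @return object of class \code{cp_sim} with elements \code{ts}
#'   (data.frame of recorded channels), \code{beats} (per-beat
#'   data.frame), \code{breath_starts}, \code{final_state},
#'   \code{final_T} and \code{params}.
#' @export
simulate_cp <- function(params, duration, dt = 5e-4, record_dt = 0.01,
                        init = NULL, T_beat = NA_real_) {
  stopifnot(inherits(params, "cp_params"))
  if (is.null(init)) init <- initial_state(params)
  if (is.na(T_beat)) T_beat <- max(0.2, basal_autonomic_state(params)$T)
  res <- .engine_run(as.numeric(init), T_beat, unclass(params),
                     duration, dt, record_dt)
  ts <- as.data.frame(t(res$ts))
  names(ts) <- as.character(res$ts_cols)
  beats <- as.data.frame(t(res$beats))
  names(beats) <- as.character(res$beat_cols)
  if (nrow(beats)) {
    beats$SV_lv <- beats$EDV_lv - beats$ESV_lv
    beats$SV_rv <- beats$EDV_rv - beats$ESV_rv
    beats$EF_lv <- ifelse(beats$EDV_lv > 0, beats$SV_lv / beats$EDV_lv, 0)
    beats$EF_rv <- ifelse(beats$EDV_rv > 0, beats$SV_rv / beats$EDV_rv, 0)
    beats$PP <- beats$P_sa_max - beats$P_sa_min
    beats$HR <- 60 / (beats$t_end - beats$t_start)
  }
  out <- list(ts = ts, beats = beats,
              breath_starts = as.numeric(res$breath_starts),
              final_state = stats::setNames(as.numeric(res$final_state),
                                            .cp_state_names),
              final_T = res$final_T, t_end = res$t_end,
              dt = dt, record_dt = record_dt, params = params)
  class(out) <- "cp_sim"
  out
}

#' Continue a simulation from its final state
#'
#' @param sim a \code{cp_sim} object.
#' @param params parameter set for the continuation (defaults to the
#'   previous one; overriding emulates a scenario phase change).
#' @param duration additional simulated time (s).
#' @param ... passed to [simulate_cp()].
#' @return a new \code{cp_sim} object.
#' @export
continue_cp <- function(sim, duration, params = sim$params, ...) {
  stopifnot(inherits(sim, "cp_sim"))
  simulate_cp(params, duration, init = sim$final_state,
              T_beat = sim$final_T, ...)
}

#' Integrate to a periodic (breath-locked) steady state
#'
#' Runs the model in chunks and stops once every per-beat summary,
#' averaged over the last breath-sized window, changes by less than
#' \code{tol} (relative) between consecutive chunks, or when
#' \code{max_time} is reached (with a warning).
#'
#' @param params a \code{cp_params} object.
#' @param max_time maximum simulated time (s).
#' @param tol relative breath-to-breath tolerance.
#' @param chunk chunk length (s); defaults to a few breaths.
#' @param init,T_beat,dt,record_dt as in [simulate_cp()].
#' @return the last chunk's \code{cp_sim} object.
#' @export
find_periodic_state <- function(params, max_time = 300, tol = 1e-3,
                                chunk = NULL, init = NULL,
                                T_beat = NA_real_, dt = 5e-4,
                                record_dt = 0.01) {
  if (is.null(chunk)) {
    Tb <- if (params$vent_mode != "none") 60 / params$RR
          else 60 / params$RR_spont
    chunk <- max(4 * Tb, 15)
  }
  sim <- simulate_cp(params, chunk, dt = dt, record_dt = record_dt,
                     init = init, T_beat = T_beat)
  prev <- .beat_fingerprint(sim)
  t_acc <- chunk
  while (t_acc < max_time) {
    sim <- continue_cp(sim, chunk, dt = dt, record_dt = record_dt)
    cur <- .beat_fingerprint(sim)
    t_acc <- t_acc + chunk
    if (!is.null(prev) && !is.null(cur) &&
        all(abs(cur - prev) <= tol * pmax(abs(prev), 1e-6)))
      return(sim)
    prev <- cur
  }
  warning("find_periodic_state: not converged within max_time = ",
          max_time, " s; returning last state")
  sim
}

.beat_fingerprint <- function(sim) {
  b <- sim$beats
  if (!nrow(b)) return(NULL)
  w <- b[b$t_start >= max(b$t_start) - 10, , drop = FALSE]
  c(mean(w$SV_lv), mean(w$SV_rv), mean(w$EDV_lv), mean(w$EDV_rv),
    mean(w$P_sa_mean), mean(w$HR))
}

#' @export
print.cp_sim <- function(x, ...) {
  cat("<cp_sim> ", x$t_end, " s simulated, ", nrow(x$beats), " beats, ",
      length(x$breath_starts), " breaths recorded\n", sep = "")
  if (nrow(x$beats)) {
    b <- utils::tail(x$beats, 10)
    cat(sprintf("  last beats: HR %.1f bpm, SV(lv) %.1f ml, P_sa %.1f/%.1f mmHg\n",
                mean(b$HR), mean(b$SV_lv), mean(b$P_sa_max),
                mean(b$P_sa_min)))
  }
  invisible(x)
}

#' @export
summary.cp_sim <- function(object, last = 30, ...) {
  b <- object$beats
  b <- b[b$t_start >= object$t_end - last, , drop = FALSE]
  out <- data.frame(
    HR = mean(b$HR), T = mean(b$t_end - b$t_start),
    P_sa_mean = mean(b$P_sa_mean), P_sa_sys = mean(b$P_sa_max),
    P_sa_dia = mean(b$P_sa_min), P_pa_mean = mean(b$P_pa_mean),
    EDV_lv = mean(b$EDV_lv), ESV_lv = mean(b$ESV_lv),
    EDV_rv = mean(b$EDV_rv), ESV_rv = mean(b$ESV_rv),
    SV_lv = mean(b$SV_lv), SV_rv = mean(b$SV_rv),
    EF_lv = mean(b$EF_lv), EF_rv = mean(b$EF_rv),
    CO = mean(b$SV_lv) * mean(b$HR) / 1000,
    P_la_mean = mean(b$P_la_mean), P_ra_mean = mean(b$P_ra_mean),
    V_spt_mean = mean(b$V_spt_mean))
  class(out) <- c("cp_sim_summary", class(out))
  out
}

#' @export
plot.cp_sim <- function(x, channels = c("P_sa", "P_lv", "P_pa", "V_lv"),
                        last = 10, ...) {
  ts <- x$ts
  ts <- ts[ts$t >= max(ts$t) - last, , drop = FALSE]
  op <- graphics::par(mfrow = c(length(channels), 1),
                      mar = c(2.5, 4, 0.5, 0.5))
  on.exit(graphics::par(op))
  for (ch in channels)
    graphics::plot(ts$t, ts[[ch]], type = "l", xlab = "t (s)", ylab = ch)
  invisible(x)
}

#' Schedule a volume-expansion (fluid administration) event
#'
#' Returns a parameter set whose next simulation infuses
#' \code{added_volume} ml into the extrasplanchnic venous compartment at
#' a constant rate over \code{duration} seconds, starting at
#' \code{start} seconds of simulated time. Total blood volume increases
#' by exactly \code{added_volume}; conservation holds thereafter.
#'
#' @param params a \code{cp_params} object.
#' @param added_volume infused volume (ml), >= 0; 0 removes the event.
#' @param duration infusion duration (s).
#' @param start infusion onset (s, phase-local).
#' @return modified \code{cp_params}.
#' @export
volume_expansion <- function(params, added_volume, duration = 600,
                             start = 0) {
  if (added_volume < 0) stop("volume_expansion: added_volume must be >= 0")
  apply_scenario_overrides(params, list(
    ve_volume = added_volume, ve_start = start, ve_duration = duration))
}
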