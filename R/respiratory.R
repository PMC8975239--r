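#' Single-compartment respiratory mechanics
#'
#' Linear lung + chest-wall mechanics driven by airway-opening pressure
#' and (optionally) respiratory-muscle pressure:
#' P_pl = (V_A - V_u_cw)/C_cw - P_mus,
#' P_A  = P_pl + (V_A - V_u_L)/C_L,
#' dV_A/dt = (P_ao - P_A)/R_aw.
#' All pressures in cmH2O, volumes in liters.
#'
#' @param V_A alveolar volume (l).
#' @param P_ao airway-opening pressure (cmH2O).
#' @param P_mus respiratory muscle pressure (cmH2O, positive inflates).
#' @param params a \code{cp_params} object.
#' @return list with dV_A (l/s), P_A and P_pl (cmH2O).
#' @export
respiratory_derivatives <- function(V_A, P_ao, P_mus, params) {
  P_pl <- (V_A - params$V_u_cw) / params$C_cw - P_mus
  P_A <- P_pl + (V_A - params$V_u_L) / params$C_L
  list(dV_A = (P_ao - P_A) / params$R_aw, P_A = P_A, P_pl = P_pl)
}

#' Static equilibrium lung volume
#'
#' Zero-flow alveolar volume for a constant airway pressure (the FRC
#' when \code{P_ao = 0}).
#'
#' @param params a \code{cp_params} object.
#' @param P_ao constant airway pressure (cmH2O).
#' @return equilibrium alveolar volume (l).
#' @export
frc_equilibrium <- function(params, P_ao = 0) {
  (P_ao + params$V_u_cw / params$C_cw + params$V_u_L / params$C_L) /
    (1 / params$C_cw + 1 / params$C_L)
}

#' Calibrate unstressed volumes to a target FRC
#'
#' Scales the lung and chest-wall unstressed volumes by a common factor
#' so that the zero-flow, zero-airway-pressure equilibrium equals
#' \code{target_FRC}.
#'
#' @param params a \code{cp_params} object.
#' @param target_FRC target functional residual capacity (l).
#' @return \code{params} with adjusted \code{V_u_L}, \code{V_u_cw}.
#' @export
calibrate_frc <- function(params, target_FRC) {
  if (!is.finite(target_FRC) || target_FRC <= 0)
    stop("calibrate_frc: target_FRC must be positive")
  v0 <- frc_equilibrium(params, 0)
  if (v0 <= 0) stop("calibrate_frc: infeasible (non-positive equilibrium)")
  s <- target_FRC / v0
  params$V_u_L <- params$V_u_L * s
  params$V_u_cw <- params$V_u_cw * s
  params
}

#' Ventilator airway-pressure waveform
#'
#' Periodic airway-opening pressure program. PCV and PSV share the same
#' square-wave-with-ramp shape (patient triggering is out of scope for
#' sedated runs): pressure rises over a short smoothing ramp to
#' PEEP + support, is held through inspiration and the optional
#' end-inspiratory pause, and is released back to PEEP for expiration.
#' VCV delivers the flow-programmed equivalent: a linear pressure rise
#' over inspiration to the same plateau. Mode "none" gives P_ao = 0.
#'
#' @param t time (s), vectorised.
#' @param params a \code{cp_params} object (ventilator fields:
#'   vent_mode, PEEP, support, RR, IE_ratio, end_insp_pause, vent_ramp).
#' @return P_ao (cmH2O).
#' @export
ventilator_pressure <- function(t, params) {
  p <- params
  if (p$vent_mode == "none") return(rep(0, length(t)))
  Tb <- 60 / p$RR
  Ti <- Tb * p$IE_ratio / (1 + p$IE_ratio)
  plateau_end <- min(Ti + p$end_insp_pause, Tb - 2 * p$vent_ramp)
  tb <- t %% Tb
  r <- p$vent_ramp
  up <- if (p$vent_mode == "VCV") {
    pmin(tb / max(Ti, r), 1)                       # linear flow-programmed rise
  } else {
    ifelse(tb < r, (1 - cos(pi * tb / r)) / 2, 1)  # fast smoothed step
  }
  frac <- ifelse(tb < plateau_end, up,
                 ifelse(tb < plateau_end + r,
                        (1 + cos(pi * (tb - plateau_end) / r)) / 2, 0))
  p$PEEP + p$support * frac
}

#' Respiratory-muscle pressure waveform
#'
#' Spontaneous-effort drive used for actively breathing scenarios: a
#' half-sine inspiratory effort of amplitude \code{amp_mus} occupying
#' the first third of each spontaneous breath (I:E 1:2), zero during
#' expiration. \code{amp_mus = 0} reproduces a fully sedated patient.
#'
#' @param t time (s), vectorised.
#' @param params a \code{cp_params} object (amp_mus, RR_spont).
#' @return P_mus (cmH2O).
#' @export
muscle_pressure <- function(t, params) {
  if (params$amp_mus == 0) return(rep(0, length(t)))
  Tr <- 60 / params$RR_spont
  Ti <- Tr / 3
  tb <- t %% Tr
  ifelse(tb < Ti, params$amp_mus * sin(pi * tb / Ti), 0)
}
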