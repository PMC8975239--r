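#' Baroreflex static maps
#'
#' Afferent and efferent static characteristics of the arterial
#' baroreflex: a sigmoidal afferent firing rate of (low-pass filtered)
#' systemic arterial pressure, a monotonically decreasing exponential
#' sympathetic efferent, and an increasing sigmoidal vagal efferent.
#' Effectors add a first-order-lagged, delayed, log-compressed
#' sympathetic drive (and, for the heart period, a linear vagal drive)
#' on top of the basal parameter values.
#'
#' @param P filtered arterial pressure (mmHg).
#' @param params a \code{cp_params} object.
#' @return list with f_ab, f_es, f_ev (spikes/s) and the log-compressed
#'   sympathetic drive L = log(f_es - f_es_min + 1).
#' @export
baroreflex_static <- function(P, params) {
  p <- params
  ex <- exp((P - p$P_n) / p$k_a)
  f_ab <- (p$f_ab_min + p$f_ab_max * ex) / (1 + ex)
  f_es <- p$f_es_inf + (p$f_es_0 - p$f_es_inf) * exp(-p$k_es * f_ab)
  exv <- exp((f_ab - p$f_ab_0) / p$k_ev)
  f_ev <- (p$f_ev_0 + p$f_ev_inf * exv) / (1 + exv)
  L <- log(max(f_es - p$f_es_min, 0) + 1)
  list(f_ab = f_ab, f_es = f_es, f_ev = f_ev, L = L)
}

#' Basal (setpoint) autonomic tone and effective values
#'
#' Evaluates the reflex maps at the arterial setpoint P_n and returns
#' the tonic effector contributions and the resulting basal effective
#' values: heart period, wall elastances, peripheral resistances and
#' venous unstressed volumes. These are the values the model holds when
#' the ANS is frozen or when pressure sits at its setpoint for all
#' history.
#'
#' @param params a \code{cp_params} object.
#' @return list with L_b, f_ev_b and effective T, E_max_lvf, E_max_rvf,
#'   E_max_spt, R_sp, R_ep, V_u_sv, V_u_ev.
#' @export
basal_autonomic_state <- function(params) {
  p <- params
  s <- baroreflex_static(p$P_n, p)
  list(
    L_b = s$L, f_ev_b = s$f_ev,
    T = p$T_0 + p$G_Ts * s$L + p$G_Tv * s$f_ev,
    E_max_lvf = p$E_max_lvf0 + p$G_E_lvf * s$L,
    E_max_rvf = p$E_max_rvf0 + p$G_E_rvf * s$L,
    E_max_spt = p$E_max_spt0 + p$G_E_spt * s$L,
    R_sp = p$R_sp0 + p$G_R_sp * s$L,
    R_ep = p$R_ep0 + p$G_R_ep * s$L,
    V_u_sv = max(0, p$V_u_sv0 + p$G_Vu_sv * s$L),
    V_u_ev = max(0, p$V_u_ev0 + p$G_Vu_ev * s$L)
  )
}
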