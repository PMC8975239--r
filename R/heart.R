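#' Half-sine cardiac activation function
#'
#' Activation level of the ventricular walls over the cardiac cycle.
#' Systole occupies the first T_sys seconds of the beat with
#' phi = sin^2(pi * t / T_sys); the remainder of the beat is diastole
#' (phi = 0). The systolic duration shortens with heart rate:
#' T_sys = T_sys0 - k_sys / T.
#'
#' @param u cycle clock, fraction of the heart period in [0, 1).
#' @param T heart period (s).
#' @param T_sys0,k_sys systolic-duration law coefficients (s, s^2).
#' @return activation phi in [0, 1].
#' @export
activation_phi <- function(u, T, T_sys0 = 0.5, k_sys = 0.075) {
  stopifnot(all(T > 0))
  T_sys <- T_sys0 - k_sys / T
  tc <- u * T
  ifelse(tc >= 0 & tc <= T_sys, sin(pi * tc / T_sys)^2, 0)
}

#' Biphasic wall transmural pressure
#'
#' Variable-elastance pressure-volume relation of a cardiac wall,
#' blending the end-systolic line E_max (V - V_u) and the end-diastolic
#' exponential P_0 (exp(k_E V) - 1) by the activation phi:
#' P = phi * E_max * (V - V_u) + (1 - phi) * P_0 * (exp(k_E V) - 1).
#' With septal parameters the signed volume convention applies
#' (negative V = bulge toward the left ventricle).
#'
#' @param V wall-bounded blood volume (ml).
#' @param phi activation in [0, 1].
#' @param E_max current end-systolic elastance (mmHg/ml).
#' @param V_u unstressed volume (ml).
#' @param P_0 end-diastolic scaling factor (mmHg).
#' @param k_E end-diastolic elastance coefficient (1/ml).
#' @return transmural pressure (mmHg).
#' @export
wall_pressure <- function(V, phi, E_max, V_u, P_0, k_E) {
  stopifnot(all(phi >= 0 & phi <= 1))
  phi * E_max * (V - V_u) + (1 - phi) * P_0 * (exp(k_E * V) - 1)
}

#' Pericardial pressures
#'
#' Exponential transmural pressure of the pericardial membrane as a
#' function of the total volume it encloses (four chambers plus
#' pericardial fluid), and the resulting absolute pericardial pressure
#' P_peri = P_pl + P_pcd.
#'
#' @param V_tot total enclosed volume (ml).
#' @param P_pl pleural pressure (mmHg).
#' @param P_0_pcd,k_E_pcd,V_u_pcd pericardial parameters.
#' @return list with P_pcd and P_peri (mmHg).
#' @export
pericardial_pressure <- function(V_tot, P_pl, P_0_pcd = 0.5,
                                 k_E_pcd = 0.005, V_u_pcd = 200) {
  P_pcd <- P_0_pcd * (exp(k_E_pcd * (V_tot - V_u_pcd)) - 1)
  list(P_pcd = P_pcd, P_peri = P_pl + P_pcd)
}

#' Solve the septal volume balance
#'
#' The septal wall position is determined algebraically at every instant
#' by requiring its transmural pressure to balance the pressure
#' difference between the two ventricular free walls:
#' P_spt(V_spt) = P_lvf(V_lv - V_spt) - P_rvf(V_rv + V_spt).
#' All three wall relations are increasing in V_spt, so the root is
#' unique; it is found by safeguarded Newton iteration (bisection
#' fallback) to |g| < 1e-9 mmHg.
#'
#' @param V_lv,V_rv ventricular volumes (ml).
#' @param phi activation in [0, 1] (free walls and septum activate
#'   simultaneously).
#' @param params a \code{cp_params} object (wall parameters; the
#'   effective septal elastance may be passed via \code{E_max_spt}).
#' @param E_max_lvf,E_max_rvf,E_max_spt effective (ANS-modulated)
#'   end-systolic elastances; default to the basal values in
#'   \code{params}.
#' @param tol convergence tolerance on the pressure imbalance (mmHg).
#' @return septal volume V_spt (ml), signed (positive = bulge into RV).
#' @export
solve_septal_volume <- function(V_lv, V_rv, phi, params,
                                E_max_lvf = params$E_max_lvf0,
                                E_max_rvf = params$E_max_rvf0,
                                E_max_spt = params$E_max_spt0,
                                tol = 1e-9) {
  p <- params
  g <- function(vs)
    wall_pressure(vs, phi, E_max_spt, p$V_u_spt, p$P_0_spt, p$k_E_spt) -
    wall_pressure(V_lv - vs, phi, E_max_lvf, p$V_u_lvf, p$P_0_lvf, p$k_E_lvf) +
    wall_pressure(V_rv + vs, phi, E_max_rvf, p$V_u_rvf, p$P_0_rvf, p$k_E_rvf)
  gp <- function(vs) {
    dspt <- phi * E_max_spt +
      (1 - phi) * p$P_0_spt * p$k_E_spt * exp(p$k_E_spt * vs)
    dlvf <- phi * E_max_lvf +
      (1 - phi) * p$P_0_lvf * p$k_E_lvf * exp(p$k_E_lvf * (V_lv - vs))
    drvf <- phi * E_max_rvf +
      (1 - phi) * p$P_0_rvf * p$k_E_rvf * exp(p$k_E_rvf * (V_rv + vs))
    dspt + dlvf + drvf
  }
  lo <- -V_rv; hi <- V_lv
  if (g(lo) > 0 || g(hi) < 0) { # widen: admissible states keep root inside
    lo <- lo - 100; hi <- hi + 100
    if (g(lo) > 0 || g(hi) < 0)
      stop("solve_septal_volume: bracket failure; V_lv=", V_lv,
           " V_rv=", V_rv, " phi=", phi)
  }
  vs <- 0
  for (it in 1:100) {
    gv <- g(vs)
    if (abs(gv) < tol) return(vs)
    step <- gv / gp(vs)
    vs_new <- vs - step
    if (!is.finite(vs_new) || vs_new <= lo || vs_new >= hi)
      vs_new <- (lo + hi) / 2
    if (gv > 0) hi <- vs else lo <- vs
    vs <- vs_new
  }
  vs
}
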