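#' Default cardiopulmonary parameter set
#'
#' Returns the full parameter vector of the model as a flat named list of
#' class \code{cp_params}. Pressures are in mmHg on the blood side and
#' cmH2O on the airway side, volumes in ml (blood) and liters (gas),
#' resistances in mmHg.s/ml, compliances in ml/mmHg, elastances in
#' mmHg/ml, times in seconds.
#'
#' Cardiac wall, pericardial and pulmonary-vessel values are the printed
#' basal set of the model. Values marked "inherited" below are not part
#' of this model's own contribution: they come from the base-model
#' lineage the heart/circulation description builds on (Ursino-Magosso
#' style baroreflex and systemic circulation) and were calibrated once
#' against the normal-resting hemodynamic surface (see the methods
#' vignette); they are never tuned per run.
#'
#' @return named list of class \code{cp_params}.
#' @export
default_parameters <- function() {
  pp <- derive_pulmonary_splits(5.8, 108.24)
  p <- list(
    ## ---- heart free walls and septum (basal, pre-ANS-tone) ----
    E_max_lvf0 = 2.392, E_max_rvf0 = 1.412, E_max_spt0 = 32.4,
    k_E_lvf = 0.014, k_E_rvf = 0.011, k_E_spt = 0.175,
    P_0_lvf = 1.5, P_0_rvf = 1.5, P_0_spt = 1.11,
    V_u_lvf = 14.758, V_u_rvf = 35.904, V_u_spt = 0,
    ## systolic-duration law T_sys = T_sys0 - k_sys / T
    T_sys0 = 0.55, k_sys = 0.075,
    ## valve / ejection viscous losses (inherited)
    k_R_lv = 3.75e-4, k_R_rv = 1.35e-3,
    R_mv = 2.5e-3, R_tv = 2.5e-3,
    ## ---- atria: variable elastance, no inter-atrial interaction ----
    ## (inherited/calibrated; atrial systole leads ventricular onset)
    E_ra_min = 0.10, E_ra_max = 0.13, V_u_ra = 14,
    E_la_min = 0.17, E_la_max = 0.28, V_u_la = 12,
    atrial_lead = 0.10,   # fraction of heart period
    ## ---- pericardium ----
    P_0_pcd = 0.5, k_E_pcd = 0.005, V_u_pcd = 200, V_peri = 40,
    ## ---- pulmonary circulation ----
    C_pa = 0.76, V_u_pa = 0, R_pa = 0.023, L_pa = 1.8e-4,
    C_pal = pp$C_pal, C_pc = pp$C_pc,
    V_u_pal = pp$V_u_pal, V_u_pc = pp$V_u_pc,
    C_pv = 25.37, V_u_pv = 105.6, R_pv = 0.0056,
    R_pp_tot = 0.0894, sh = 0.017, FRC_nom = 2.25,
    cap_margin = 8,     # capillary-collapse transmural reserve (mmHg)
    ## ---- systemic circulation (inherited/calibrated) ----
    C_sa = 0.28, V_u_sa = 0,
    C_sp = 2.05, V_u_sp = 274.4,
    C_ep = 1.67, V_u_ep = 134.64,
    R_sa = 0.06,                         # lumped arterial resistance
    R_sp0 = 2.3, R_ep0 = 0.82,          # basal (pre-tone), ANS-controlled
    C_sv = 61.11, V_u_sv0 = 1410,        # basal (pre-tone), ANS-controlled
    C_ev = 50, V_u_ev0 = 1520,           # basal (pre-tone), ANS-controlled
    R_sv = 0.08, R_ev = 0.05,
    C_vc = 60, V_u_vc = 130, R_vc = 0.02,
    V_blood = 5470, BSA = 1.9,
    ## ---- respiratory mechanics (single compartment) ----
    R_aw = 1.7459, C_L = 0.2, C_cw = 0.2445,
    V_u_L = 1.5, V_u_cw = 3.166875,      # calibrated: FRC = 2.25 l
    ## spontaneous breathing drive (basal breathing amplitude; zero = sedated)
    amp_mus = 4.0, RR_spont = 12,
    ## ---- ventilator ----
    vent_mode = "none",                  # one of none, PCV, PSV, VCV
    PEEP = 0, support = 0, RR = 15, IE_ratio = 0.5,
    end_insp_pause = 0, FiO2 = 0.21,     # FiO2 carried, unused (no gas exchange)
    vent_ramp = 0.05,
    ## ---- autonomic control (inherited Ursino-Magosso structure) ----
    T_0 = 0.58,
    tau_p = 2.076, P_n = 86.5, k_a = 11.758,
    f_ab_min = 2.52, f_ab_max = 47.78,
    f_es_inf = 2.1, f_es_0 = 16.11, k_es = 0.0675, f_es_min = 2.66,
    f_ev_0 = 3.2, f_ev_inf = 6.3, f_ab_0 = 25, k_ev = 7.06,
    G_Ts = -0.13, tau_Ts = 2.0, D_Ts = 2.0,
    G_Tv = 0.09, tau_Tv = 1.5, D_Tv = 0.2,
    G_E_lvf = 0.475, G_E_rvf = 0.282, G_E_spt = 6.43,
    tau_E = 8.0, D_E = 2.0,
    G_R_sp = 0.695, G_R_ep = 0.53, tau_R = 6.0, D_R = 2.0,
    G_Vu_sv = -265.4, G_Vu_ev = -132.5, tau_Vu = 20.0, D_Vu = 5.0,
    ans_frozen = FALSE,
    ## chemoreflex sensitivities are configuration hooks only: gas exchange
    ## is not modelled, so nonzero values are rejected with a clear error.
    chemo_central_gain = 0, chemo_peripheral_gain = 0,
    ## volume-expansion event (0 = no event)
    ve_volume = 0, ve_start = 0, ve_duration = 1
  )
  class(p) <- "cp_params"
  p
}

#' Split the lumped pulmonary peripheral compliance and unstressed volume
#'
#' The pulmonary peripheral bed is represented by two nodes, arterioles
#' (pal) and capillaries (pc), whose parallel combination must reproduce
#' the lumped values: C_pal + C_pc = total compliance and
#' V_u_pal + V_u_pc = total unstressed volume, with the conventional
#' ratios C_pc = 2 C_pal and V_u_pc = 1.5 V_u_pal.
#'
#' @param C_pp_total total peripheral compliance (ml/mmHg).
#' @param V_u_pp_total total peripheral unstressed volume (ml).
#' @return list with C_pal, C_pc, V_u_pal, V_u_pc.
#' @export
derive_pulmonary_splits <- function(C_pp_total, V_u_pp_total) {
  if (!is.finite(C_pp_total) || C_pp_total <= 0 ||
      !is.finite(V_u_pp_total) || V_u_pp_total <= 0)
    stop("derive_pulmonary_splits: inputs must be positive")
  list(C_pal = C_pp_total / 3, C_pc = 2 * C_pp_total / 3,
       V_u_pal = V_u_pp_total * 2 / 5, V_u_pc = V_u_pp_total * 3 / 5)
}

#' Partition the total pulmonary peripheral resistance
#'
#' Splits the lumped peripheral resistance R_pp_tot into the arteriolar
#' (pre-capillary) resistance at nominal FRC, the post-capillary
#' resistance, and the shunt resistance. These are the unique values for
#' which the parallel-series combination seen from the arteriolar node
#' returns R_pp_tot and a fraction sh of steady flow takes the shunt
#' branch.
#'
#' @param R_pp_tot total peripheral resistance (mmHg.s/ml).
#' @param sh shunt fraction in [0, 1).
#' @param FRC_nom nominal functional residual capacity (l); carried for
#'   interface symmetry with [variable_rpal()].
#' @return list with R_pal_frc, R_pc, R_ps (R_ps = Inf when sh = 0).
#' @export
partition_peripheral_resistances <- function(R_pp_tot, sh, FRC_nom = 2.25) {
  if (!is.finite(R_pp_tot) || R_pp_tot <= 0)
    stop("partition_peripheral_resistances: R_pp_tot must be positive")
  if (sh < 0 || sh >= 1)
    stop("partition_peripheral_resistances: sh must be in [0, 1)")
  half <- R_pp_tot / (2 * (1 - sh))
  list(R_pal_frc = half, R_pc = half,
       R_ps = if (sh == 0) Inf else R_pp_tot / sh)
}

#' Alveolar-volume-dependent pulmonary arteriolar resistance
#'
#' R_pal grows quadratically with lung inflation, capturing compression
#' of the alveolar capillary bed by lung expansion:
#' R_pal = R_pp_tot / (2 (1 - sh)) * (V_A / FRC_nom)^2.
#'
#' @param V_A alveolar volume (l).
#' @param sh shunt fraction in [0, 1).
#' @param R_pp_tot total peripheral resistance (mmHg.s/ml).
#' @param FRC_nom nominal FRC (l).
#' @return R_pal (mmHg.s/ml).
#' @export
variable_rpal <- function(V_A, sh, R_pp_tot, FRC_nom = 2.25) {
  if (any(V_A <= 0)) stop("variable_rpal: V_A must be positive")
  if (sh < 0 || sh >= 1) stop("variable_rpal: sh must be in [0, 1)")
  R_pp_tot / (2 * (1 - sh)) * (V_A / FRC_nom)^2
}

## keys whose value is not a positive scalar by nature
.cp_param_nonpositive_ok <- c(
  "V_u_pa", "V_u_sa", "V_u_spt", "PEEP", "support", "end_insp_pause",
  "amp_mus", "G_Ts", "G_Vu_sv", "G_Vu_ev", "sh", "ve_volume", "ve_start",
  "chemo_central_gain", "chemo_peripheral_gain", "atrial_lead"
)

.cp_validate <- function(p) {
  num <- p[!names(p) %in% c("vent_mode", "ans_frozen")]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad))
    stop("parameter not a finite scalar: ", paste(bad, collapse = ", "))
  if (p$sh < 0 || p$sh >= 1) stop("shunt fraction sh out of range [0, 1)")
  if (p$PEEP < 0) stop("PEEP must be >= 0")
  if (!p$vent_mode %in% c("none", "PCV", "PSV", "VCV"))
    stop("vent_mode must be one of none, PCV, PSV, VCV")
  if (p$vent_mode != "none" && p$RR <= 0)
    stop("RR must be > 0 when a ventilator mode is active")
  if (p$chemo_central_gain != 0 || p$chemo_peripheral_gain != 0)
    stop("chemoreflex sensitivities must be zero: gas exchange is not modelled")
  must_pos <- c("E_max_lvf0", "E_max_rvf0", "E_max_spt0", "k_E_lvf",
                "k_E_rvf", "k_E_spt", "P_0_lvf", "P_0_rvf", "P_0_spt",
                "V_u_lvf", "V_u_rvf", "P_0_pcd", "k_E_pcd", "V_u_pcd",
                "V_peri", "C_pa", "R_pa", "L_pa", "C_pal", "C_pc", "C_pv",
                "R_pv", "R_pp_tot", "FRC_nom", "C_sa", "C_sp", "C_ep",
                "C_sv", "C_ev", "C_vc", "R_sa", "R_sp0", "R_ep0", "R_sv", "R_ev",
                "R_vc", "V_blood", "BSA", "R_aw", "C_L", "C_cw", "T_0",
                "tau_p", "tau_E", "tau_R", "tau_Vu", "tau_Ts", "tau_Tv")
  neg <- must_pos[vapply(must_pos, function(k) p[[k]] <= 0, logical(1))]
  if (length(neg))
    stop("parameter must be positive: ", paste(neg, collapse = ", "))
  invisible(p)
}

#' Load a parameter set from a configuration document
#'
#' Builds the default parameter set and applies overrides taken from a
#' named list, a YAML file, or NULL (pure defaults). Sections (heart,
#' pulmonary, ...) may be used for organisation; keys are global and
#' unknown keys are rejected.
#'
#' @param config NULL, a named list of overrides, or path to a YAML file.
#' @return a validated \code{cp_params} object.
#' @export
load_parameters <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be NULL, a list, or a file path")
  ## flatten one level of sectioning
  flat <- list()
  for (nm in names(config)) {
    el <- config[[nm]]
    if (is.list(el)) flat[names(el)] <- el else flat[[nm]] <- el
  }
  ## numeric fields serialized as full-precision strings come back numeric
  for (nm in setdiff(names(flat), c("vent_mode", "ans_frozen")))
    if (is.character(flat[[nm]])) flat[[nm]] <- as.numeric(flat[[nm]])
  apply_scenario_overrides(default_parameters(), flat)
}

#' Apply per-scenario parameter overrides
#'
#' Returns a copy of \code{base} with the named overrides applied;
#' \code{base} is left untouched. Unknown parameter names are a
#' configuration error.
#'
#' @param base a \code{cp_params} object.
#' @param overrides named list (possibly empty).
#' @return a validated \code{cp_params} copy.
#' @export
apply_scenario_overrides <- function(base, overrides = list()) {
  stopifnot(inherits(base, "cp_params"))
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be named")
    unknown <- setdiff(names(overrides), names(base))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  }
  .cp_validate(base)
  base
}

#' Serialize a parameter set to YAML
#'
#' @param params a \code{cp_params} object.
#' @param path file path to write to.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "cp_params"))
  yaml::write_yaml(unclass(params), path,
                   handlers = list(numeric = function(x)
                     format(x, digits = 17, scientific = TRUE)))
  invisible(path)
}

#' @export
print.cp_params <- function(x, ...) {
  cat("<cp_params> cardiopulmonary parameter set (", length(x),
      " parameters)\n", sep = "")
  cat("  heart period T_0 = ", x$T_0, " s; blood volume = ", x$V_blood,
      " ml; shunt = ", x$sh, "\n", sep = "")
  cat("  ventilator: ", x$vent_mode,
      if (x$vent_mode != "none")
        paste0(" (PEEP ", x$PEEP, " cmH2O, support ", x$support,
               " cmH2O, RR ", x$RR, "/min)"), "\n", sep = "")
  invisible(x)
}
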