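#' Per-beat summaries from a simulation or a sampled time series
#'
#' For a \code{cp_sim} object the per-beat table accumulated by the
#' engine at the full integration rate is returned, augmented with the
#' end-expiratory flag. For a plain data.frame of sampled channels
#' (columns \code{t}, \code{V_lv}, \code{V_rv}, \code{P_sa}) the beats
#' are cut at the supplied beat start times: EDV is the volume at beat
#' start (activation onset), ESV the minimum volume within the beat.
#'
#' @param x a \code{cp_sim} object or a data.frame of sampled channels.
#' @param beat_times beat start times (s); required for the data.frame
#'   method.
#' @param breath_starts inspiration onset times used for the
#'   end-expiratory flag (taken from the simulation when available).
#' @return data.frame with one row per complete beat.
#' @export
segment_beats <- function(x, beat_times = NULL, breath_starts = NULL) {
  if (inherits(x, "cp_sim")) {
    b <- x$beats
    if (is.null(breath_starts)) breath_starts <- x$breath_starts
  } else {
    if (is.null(beat_times) || length(beat_times) < 2)
      return(data.frame())
    b <- do.call(rbind, lapply(seq_len(length(beat_times) - 1), function(i) {
      w <- x[x$t >= beat_times[i] & x$t < beat_times[i + 1], , drop = FALSE]
      if (!nrow(w)) return(NULL)
      data.frame(t_start = beat_times[i], t_end = beat_times[i + 1],
                 EDV_lv = w$V_lv[1], ESV_lv = min(w$V_lv),
                 EDV_rv = w$V_rv[1], ESV_rv = min(w$V_rv),
                 P_sa_max = max(w$P_sa), P_sa_min = min(w$P_sa))
    }))
    b$SV_lv <- b$EDV_lv - b$ESV_lv
    b$SV_rv <- b$EDV_rv - b$ESV_rv
    b$EF_lv <- ifelse(b$EDV_lv > 0, b$SV_lv / b$EDV_lv, 0)
    b$EF_rv <- ifelse(b$EDV_rv > 0, b$SV_rv / b$EDV_rv, 0)
    b$PP <- b$P_sa_max - b$P_sa_min
    b$HR <- 60 / (b$t_end - b$t_start)
  }
  b$end_expiratory <- flag_end_expiratory(b, breath_starts)
  b
}

#' Flag end-expiratory beats
#'
#' A beat is end-expiratory when its start precedes the next inspiration
#' onset by less than one heart period, i.e. it is the last beat wholly
#' inside the expiratory pause.
#'
#' @param beats per-beat data.frame (columns t_start, t_end).
#' @param breath_starts inspiration onset times (s).
#' @return logical vector along the rows of \code{beats}.
#' @export
flag_end_expiratory <- function(beats, breath_starts) {
  if (is.null(breath_starts) || !length(breath_starts) || !nrow(beats))
    return(rep(FALSE, if (is.null(beats)) 0 else nrow(beats)))
  vapply(seq_len(nrow(beats)), function(i) {
    t0 <- beats$t_start[i]
    nxt <- breath_starts[breath_starts > t0]
    if (!length(nxt)) return(FALSE)
    (nxt[1] - t0) < (beats$t_end[i] - beats$t_start[i])
  }, logical(1))
}

#' Stroke volume variation over one breathing cycle
#'
#' SVV = (SV_max - SV_min) / ((SV_max + SV_min)/2) * 100, evaluated over
#' the stroke volumes of the beats within one breath.
#'
#' @param sv stroke volumes within one breathing cycle (ml).
#' @return SVV in percent; NA (with a warning) for fewer than 2 beats.
#' @export
svv <- function(sv) {
  if (length(sv) < 2) {
    warning("svv undefined for fewer than 2 beats")
    return(NA_real_)
  }
  (max(sv) - min(sv)) / ((max(sv) + min(sv)) / 2) * 100
}

#' Pulse pressure variation over one breathing cycle
#'
#' dPP = (PP_max - PP_min) / ((PP_max + PP_min)/2) * 100, with PP the
#' per-beat arterial pulse pressure (systolic minus diastolic).
#'
#' @param pp per-beat pulse pressures within one breathing cycle (mmHg).
#' @return dPP in percent; NA (with a warning) for fewer than 2 beats.
#' @export
delta_pp <- function(pp) {
  if (length(pp) < 2) {
    warning("delta_pp undefined for fewer than 2 beats")
    return(NA_real_)
  }
  (max(pp) - min(pp)) / ((max(pp) + min(pp)) / 2) * 100
}

#' Ventricular afterload as end-systolic wall stress
#'
#' sigma = P_es,tm * V_es^(1/3), with P_es,tm the end-systolic
#' transmural pressure (chamber minus pericardial) and V_es the
#' end-systolic volume. Arbitrary units; used for intra-breath percent
#' changes.
#'
#' @param P_es_transmural end-systolic transmural pressure (mmHg).
#' @param V_es end-systolic volume (ml).
#' @return wall stress (arbitrary units).
#' @export
afterload_wall_stress <- function(P_es_transmural, V_es) {
  stopifnot(all(V_es >= 0))
  P_es_transmural * V_es^(1 / 3)
}

#' Per-breath summaries (SVV, pulse-pressure variation)
#'
#' Cuts the beat table at inspiration onsets and computes per-breath
#' stroke-volume variation for both ventricles and the pulse-pressure
#' variation, plus the index of the end-expiratory beat.
#'
#' @param beats per-beat data.frame (from [segment_beats()]).
#' @param breath_starts inspiration onset times (s).
#' @return data.frame with one row per complete breath (breaths with
#'   fewer than 2 beats are flagged with NA indices).
#' @export
breath_summaries <- function(beats, breath_starts) {
  if (length(breath_starts) < 2 || !nrow(beats)) return(data.frame())
  out <- lapply(seq_len(length(breath_starts) - 1), function(i) {
    w <- beats[beats$t_start >= breath_starts[i] &
               beats$t_start < breath_starts[i + 1], , drop = FALSE]
    if (nrow(w) < 2)
      return(data.frame(t_start = breath_starts[i],
                        t_end = breath_starts[i + 1], n_beats = nrow(w),
                        SVV_lv = NA_real_, SVV_rv = NA_real_,
                        dPP = NA_real_))
    data.frame(t_start = breath_starts[i], t_end = breath_starts[i + 1],
               n_beats = nrow(w),
               SVV_lv = svv(w$SV_lv), SVV_rv = svv(w$SV_rv),
               dPP = delta_pp(w$PP))
  })
  do.call(rbind, out)
}

#' Phase averages of beat summaries
#'
#' Means of the per-beat quantities over the trailing analysis window of
#' a protocol phase, optionally restricted to end-expiratory beats, with
#' body-surface-area indexing of the volumetric quantities (EDVI, ESVI,
#' SVI in ml/m2, CI in (l/min)/m2).
#'
#' @param beats per-beat data.frame with \code{end_expiratory} flag.
#' @param window analysis window length (s), measured back from the last
#'   beat.
#' @param BSA body surface area (m2).
#' @param end_expiratory_only restrict to end-expiratory beats.
#' @return one-row data.frame of phase means.
#' @export
phase_average <- function(beats, window = Inf, BSA = 1.9,
                          end_expiratory_only = TRUE) {
  if (!nrow(beats)) stop("phase_average: no beats")
  t1 <- max(beats$t_end)
  w <- beats[beats$t_start >= t1 - window, , drop = FALSE]
  if (end_expiratory_only && any(w$end_expiratory))
    w <- w[w$end_expiratory, , drop = FALSE]
  if (!nrow(w)) stop("phase_average: empty analysis window")
  hr <- mean(w$HR)
  data.frame(
    n_beats = nrow(w), HR = hr,
    SVI_lv = mean(w$SV_lv) / BSA, SVI_rv = mean(w$SV_rv) / BSA,
    EDVI_lv = mean(w$EDV_lv) / BSA, ESVI_lv = mean(w$ESV_lv) / BSA,
    EDVI_rv = mean(w$EDV_rv) / BSA, ESVI_rv = mean(w$ESV_rv) / BSA,
    EF_lv = mean(w$EF_lv), EF_rv = mean(w$EF_rv),
    CI = mean(w$SV_lv) * hr / 1000 / BSA,
    P_sa_mean = mean(w$P_sa_mean), PP = mean(w$PP),
    V_spt_mean = mean(w$V_spt_mean),
    P_pl_start = mean(w$P_pl_start))
}
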