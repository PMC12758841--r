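#' Beat-level waveform parameters
#'
#' Ground-truth generator parameters for one synthetic heartbeat template.
#' Each beat is a sum of five Gaussian-bump wave components (P, Q, R, S, T)
#' placed by the interval timings and projected onto the 12 leads by a
#' per-lead gain vector. These parameters are also the ground truth from
#' which structured ECG features are derived, so feature oracles are exact.
#'
#' @param rr_mean Mean RR interval in seconds (> 0).
#' @param rr_jitter_cv Coefficient of variation of beat-to-beat RR jitter.
#' @param pr_interval PR interval in seconds (P onset to QRS onset).
#' @param qrs_duration QRS duration in seconds.
#' @param qt_interval QT interval in seconds (QRS onset to T end).
#' @param wave_amplitudes Named numeric: P, Q, R, S, T amplitudes in mV.
#' @param lead_projection Named numeric of length 12: per-lead gain factors.
#' @return Object of class `beat_params`.
#' @export
beat_params <- function(rr_mean = 0.85,
                        rr_jitter_cv = 0.03,
                        pr_interval = 0.16,
                        qrs_duration = 0.09,
                        qt_interval = 0.40,
                        wave_amplitudes = c(P = 0.15, Q = -0.10, R = 1.10,
                                            S = -0.25, T = 0.30),
                        lead_projection = default_lead_projection()) {
  stopifnot(
    is.numeric(rr_mean), rr_mean > 0,
    rr_jitter_cv >= 0,
    pr_interval > 0, qrs_duration > 0, qt_interval > 0,
    all(c("P", "Q", "R", "S", "T") %in% names(wave_amplitudes)),
    length(lead_projection) == 12, all(is.finite(lead_projection))
  )
  if (pr_interval + qrs_duration + qt_interval >= rr_mean) {
    stop("pr_interval + qrs_duration + qt_interval must be < rr_mean")
  }
  names(lead_projection) <- ecg_leads()
  structure(
    list(rr_mean = rr_mean, rr_jitter_cv = rr_jitter_cv,
         pr_interval = pr_interval, qrs_duration = qrs_duration,
         qt_interval = qt_interval,
         wave_amplitudes = wave_amplitudes[c("P", "Q", "R", "S", "T")],
         lead_projection = lead_projection),
    class = "beat_params"
  )
}

#' Default per-lead gain vector
#'
#' Stylised projection of the common beat template onto the 12 leads;
#' signs follow the usual polarity conventions (aVR predominantly negative,
#' V1 biphasic-negative, tall mid-precordial leads).
#'
#' @return Named numeric of length 12.
#' @export
default_lead_projection <- function() {
  c(I = 0.6, II = 1.0, III = 0.5, aVR = -0.9, aVL = 0.3, aVF = 0.7,
    V1 = -0.4, V2 = 1.2, V3 = 1.1, V4 = 1.0, V5 = 0.9, V6 = 0.8)
}

#' Pathology signature specification
#'
#' A stylised, plantable disease effect applied to the beat template or,
#' for `st_offset`, to a time-localised window of the rendered signal.
#' Magnitudes compose additively on the affected quantity:
#' \describe{
#'   \item{st_offset}{adds `magnitude` mV inside each beat's ST window on
#'     the target leads only (time-localised; used for attention tests).}
#'   \item{rr_irregular}{adds `magnitude` to `rr_jitter_cv`.}
#'   \item{pr_prolong}{adds `magnitude` seconds to `pr_interval`.}
#'   \item{qrs_widen}{adds `magnitude` seconds to `qrs_duration`.}
#'   \item{amplitude_drop}{multiplies the target-lead gains by
#'     `1 - magnitude` (negative magnitude boosts amplitude).}
#'   \item{p_suppress}{multiplies the P amplitude by `1 - magnitude`.}
#' }
#'
#' @param label_name One of [cvd_labels()].
#' @param effect One of the six effect kinds above.
#' @param magnitude Finite numeric, units of the affected quantity.
#' @param target_leads Subset of [ecg_leads()]; defaults to all 12.
#' @param time_window Rule locating affected samples within each beat; only
#'   `"st_segment"` is defined (used by `st_offset`).
#' @return Object of class `signature_spec`.
#' @export
signature_spec <- function(label_name, effect, magnitude,
                           target_leads = ecg_leads(),
                           time_window = "st_segment") {
  effects <- c("st_offset", "rr_irregular", "pr_prolong", "qrs_widen",
               "amplitude_drop", "p_suppress")
  if (!label_name %in% cvd_labels()) {
    stop("label_name must be one of the 13 canonical labels, got: ",
         label_name)
  }
  effect <- match.arg(effect, effects)
  stopifnot(is.finite(magnitude), length(target_leads) >= 1)
  if (!all(target_leads %in% ecg_leads())) {
    stop("unknown lead name(s) in target_leads")
  }
  structure(
    list(label_name = label_name, effect = effect, magnitude = magnitude,
         target_leads = target_leads, time_window = time_window),
    class = "signature_spec"
  )
}

#' Apply pathology signatures to a beat template
#'
#' Parameter-level effects modify the beat; `st_offset` effects are
#' collected for the render stage (they act on the signal, not the
#' template). Two signatures sharing the same effect compose additively
#' with a warning.
#'
#' @param beat A [beat_params()] object.
#' @param signatures List of [signature_spec()] objects.
#' @return List with elements `beat` (modified template) and `st_offsets`
#'   (data.frame with columns lead, magnitude; one row per affected lead).
#' @export
apply_signatures <- function(beat, signatures = list()) {
  stopifnot(inherits(beat, "beat_params"))
  if (inherits(signatures, "signature_spec")) signatures <- list(signatures)
  effects <- vapply(signatures, function(s) s$effect, character(1))
  if (anyDuplicated(effects)) {
    warning("overlapping signatures on the same quantity; ",
            "effects compose additively")
  }
  st <- data.frame(lead = character(0), magnitude = numeric(0))
  for (s in signatures) {
    switch(s$effect,
      st_offset = {
        st <- rbind(st, data.frame(lead = s$target_leads,
                                   magnitude = s$magnitude))
      },
      rr_irregular = beat$rr_jitter_cv <- beat$rr_jitter_cv + s$magnitude,
      pr_prolong   = beat$pr_interval <- beat$pr_interval + s$magnitude,
      qrs_widen    = beat$qrs_duration <- beat$qrs_duration + s$magnitude,
      amplitude_drop = {
        idx <- match(s$target_leads, names(beat$lead_projection))
        beat$lead_projection[idx] <-
          beat$lead_projection[idx] * (1 - s$magnitude)
      },
      p_suppress = beat$wave_amplitudes["P"] <-
        beat$wave_amplitudes["P"] * (1 - s$magnitude)
    )
  }
  list(beat = beat, st_offsets = st)
}

# Wave component placement within one beat: centres (s from beat origin =
# P-wave centre) and Gaussian widths (s). Widths of the QRS components scale
# with qrs_duration so qrs_widen visibly broadens the complex.
beat_wave_table <- function(beat) {
  pr <- beat$pr_interval
  qrs <- beat$qrs_duration
  qt <- beat$qt_interval
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    centre = c(0, pr + 0.25 * qrs, pr + 0.50 * qrs, pr + 0.75 * qrs,
               pr + qt - 0.10),
    sigma = c(0.025, qrs / 10, qrs / 7, qrs / 10, 0.05),
    amp = unname(beat$wave_amplitudes[c("P", "Q", "R", "S", "T")])
  )
}

#' ST-segment window of a beat
#'
#' Interval (seconds, relative to the beat origin at the P-wave centre)
#' between the end of the QRS complex and the onset of the T wave, where
#' `st_offset` signatures act.
#'
#' @param beat A [beat_params()] object.
#' @return Numeric length 2, `c(start, end)`; may be empty (start >= end)
#'   for extreme interval combinations.
#' @export
st_window <- function(beat) {
  c(start = beat$pr_interval + beat$qrs_duration + 0.01,
    end = beat$pr_interval + beat$qt_interval - 0.20)
}
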