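#' Canonical diagnostic label set
#'
#' The 13 diagnostic categories handled by the package: one "Normal" rhythm
#' class plus 12 cardiovascular disease classes. The order returned here is
#' the canonical bit order used by every multihot label vector, logit vector
#' and metrics table in the package; it must never be permuted between
#' training and inference.
#'
#' @return Character vector of length 13.
#' @export
cvd_labels <- function() {
  c(
    "Atrial fibrillation",
    "Aortic stenosis or insufficiency",
    "Atrioventricular block",
    "Cardiac arrest",
    "Hypertrophic cardiomyopathy",
    "Heart failure",
    "Mitral valve prolapse or stenosis",
    "Normal",
    "Pulmonary embolism",
    "Pulmonary hypertension",
    "ST-elevation or non-ST-elevation myocardial infarction",
    "Supraventricular or ventricular tachycardia",
    "Unstable angina"
  )
}

#' Standard 12-lead names
#'
#' Column/row naming convention for all waveform matrices and CSV files.
#'
#' @return Character vector of length 12.
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Encode diagnosis names as a multihot vector
#'
#' Converts a set of diagnostic label names into a 13-bit multihot vector in
#' the canonical order of [cvd_labels()]. An empty set encodes to the all-zero
#' vector (the cohort generator forbids label-free records upstream, but the
#' encoder itself permits them).
#'
#' @param names Character vector of label names (possibly empty).
#' @return Named integer vector of length 13 with entries in \{0, 1\}.
#' @export
encode_labels <- function(names) {
  stopifnot(is.character(names) || length(names) == 0)
  canon <- cvd_labels()
  unknown <- setdiff(names, canon)
  if (length(unknown) > 0) {
    stop("unknown diagnostic label(s): ", paste(unknown, collapse = ", "))
  }
  out <- as.integer(canon %in% names)
  names(out) <- canon
  out
}
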