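#' Synthetic cohort configuration
#'
#' Configuration for the seeded synthetic multimodal ECG cohort generator.
#' Demographic and label-prevalence defaults emulate a large adult hospital
#' ECG population: age mean 64.8 (SD 17) years, 52.4% male, and per-label
#' prevalences led by Normal (39.4%), atrial fibrillation (32.2%) and heart
#' failure (31.9%).
#'
#' @param n_records Number of records to generate.
#' @param prevalence Named numeric of length 13 (order of [cvd_labels()]):
#'   target marginal prevalence per label.
#' @param cooccurrence Optional 12x12 correlation matrix (disease labels
#'   only, canonical order minus "Normal") for a Gaussian-copula coupling
#'   of disease labels; `NULL` for independent labels.
#' @param age_mean,age_sd Age distribution (years); ages are clipped to
#'   `[18, 100]`.
#' @param male_fraction Probability that a record is male.
#' @param missingness_rate Per-feature independent missingness probability.
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @param sampling_rate Hz (default 500).
#' @param record_len Samples per lead (default 5000 = 10 s at 500 Hz).
#' @param noise_sd Additive Gaussian sensor noise, mV.
#' @param signature_map Named list mapping disease labels to lists of
#'   [signature_spec()]s; defaults to [default_signature_map()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_records = 1000,
                          prevalence = default_prevalence(),
                          cooccurrence = NULL,
                          age_mean = 64.8, age_sd = 17,
                          male_fraction = 0.524,
                          missingness_rate = 0.1,
                          seed = 1L,
                          sampling_rate = 500,
                          record_len = 5000,
                          noise_sd = 0.03,
                          signature_map = default_signature_map()) {
  stopifnot(
    n_records >= 1,
    length(prevalence) == 13,
    all(prevalence >= 0 & prevalence <= 1),
    age_sd >= 0, male_fraction >= 0, male_fraction <= 1,
    missingness_rate >= 0, missingness_rate <= 1,
    sampling_rate > 0, record_len > 0
  )
  names(prevalence) <- cvd_labels()
  structure(
    list(n_records = as.integer(n_records), prevalence = prevalence,
         cooccurrence = cooccurrence, age_mean = age_mean, age_sd = age_sd,
         male_fraction = male_fraction,
         missingness_rate = missingness_rate, seed = as.integer(seed),
         sampling_rate = sampling_rate, record_len = as.integer(record_len),
         noise_sd = noise_sd, signature_map = signature_map),
    class = "cohort_config"
  )
}

#' Default label prevalences
#'
#' Marginal prevalence per diagnostic category for a large adult hospital
#' ECG cohort (canonical label order).
#'
#' @return Named numeric of length 13.
#' @export
default_prevalence <- function() {
  p <- c(0.322, 0.051, 0.047, 0.020, 0.056, 0.319, 0.049, 0.394,
         0.022, 0.075, 0.117, 0.065, 0.034)
  names(p) <- cvd_labels()
  p
}

#' Default disease-to-signature map
#'
#' Stylised waveform effects per disease label. These are deliberately
#' simple morphology edits (ST shifts, interval changes, amplitude scaling,
#' RR irregularity), sufficient to make labels recoverable from waveforms
#' and to localise effects in time — not physiologic simulation.
#'
#' @return Named list: disease label -> list of [signature_spec()].
#' @export
default_signature_map <- function() {
  s <- signature_spec
  list(
    "Atrial fibrillation" = list(
      s("Atrial fibrillation", "rr_irregular", 0.25),
      s("Atrial fibrillation", "p_suppress", 1.0)),
    "Aortic stenosis or insufficiency" = list(
      s("Aortic stenosis or insufficiency", "amplitude_drop", -0.35,
        target_leads = c("V5", "V6", "I", "aVL"))),
    "Atrioventricular block" = list(
      s("Atrioventricular block", "pr_prolong", 0.10)),
    "Cardiac arrest" = list(
      s("Cardiac arrest", "amplitude_drop", 0.55),
      s("Cardiac arrest", "rr_irregular", 0.35)),
    "Hypertrophic cardiomyopathy" = list(
      s("Hypertrophic cardiomyopathy", "amplitude_drop", -0.5,
        target_leads = c("V1", "V2", "V3", "V4")),
      s("Hypertrophic cardiomyopathy", "qrs_widen", 0.02)),
    "Heart failure" = list(
      s("Heart failure", "amplitude_drop", 0.35)),
    "Mitral valve prolapse or stenosis" = list(
      s("Mitral valve prolapse or stenosis", "st_offset", -0.06,
        target_leads = c("II", "III", "aVF"))),
    "Pulmonary embolism" = list(
      s("Pulmonary embolism", "st_offset", -0.10,
        target_leads = c("V1", "V2", "V3"))),
    "Pulmonary hypertension" = list(
      s("Pulmonary hypertension", "amplitude_drop", -0.3,
        target_leads = c("V1", "V2"))),
    "ST-elevation or non-ST-elevation myocardial infarction" = list(
      s("ST-elevation or non-ST-elevation myocardial infarction",
        "st_offset", 0.20, target_leads = c("V2", "V3", "V4", "V5"))),
    "Supraventricular or ventricular tachycardia" = list(
      s("Supraventricular or ventricular tachycardia", "qrs_widen", 0.04),
      s("Supraventricular or ventricular tachycardia", "rr_irregular", 0.10)),
    "Unstable angina" = list(
      s("Unstable angina", "st_offset", -0.12,
        target_leads = c("V4", "V5", "V6")))
  )
}

#' Sample ages and sexes
#'
#' Ages are Normal(`age_mean`, `age_sd`) clipped to `[18, 100]` years;
#' sexes are Bernoulli(`male_fraction`) coded "M"/"F".
#'
#' @param n Number of subjects (>= 1).
#' @param config A [cohort_config()].
#' @return List with numeric `ages` and character `sexes`.
#' @export
sample_demographics <- function(n, config = cohort_config()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count")
  }
  n <- as.integer(n)
  ages <- stats::rnorm(n, config$age_mean, config$age_sd)
  ages <- pmin(pmax(ages, 18), 100)
  sexes <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")
  list(ages = ages, sexes = sexes)
}

# Solve adjusted Bernoulli probabilities q so that, conditional on at least
# one disease firing, each disease's marginal equals its target p. Fixed
# point of q = p * (1 - prod(1 - q)).
solve_truncated_bernoulli <- function(p) {
  if (all(p == 0)) return(p)
  q <- pmin(p, 1)
  for (i in 1:200) {
    q_new <- pmin(p * (1 - prod(1 - q)), 1)
    if (max(abs(q_new - q)) < 1e-12) break
    q <- q_new
  }
  q
}

#' Sample multihot diagnostic labels
#'
#' "Normal" is drawn first at its target prevalence and is mutually
#' exclusive with every disease label. Non-Normal records draw disease
#' labels (independently, or via a Gaussian copula when a co-occurrence
#' matrix is configured) conditioned on carrying at least one disease, with
#' per-disease probabilities adjusted so empirical marginals converge to
#' their targets. Every record carries at least one label.
#'
#' @param n Number of records.
#' @param config A [cohort_config()].
#' @return Integer matrix `n x 13`, columns in canonical label order.
#' @export
sample_labels <- function(n, config = cohort_config()) {
  stopifnot(n >= 1)
  n <- as.integer(n)
  prev <- config$prevalence
  if (any(prev < 0 | prev > 1)) stop("prevalence must lie in [0, 1]")
  labels <- matrix(0L, n, 13, dimnames = list(NULL, cvd_labels()))
  p_norm <- prev[["Normal"]]
  is_normal <- stats::runif(n) < p_norm
  labels[is_normal, "Normal"] <- 1L
  n_dis <- sum(!is_normal)
  if (n_dis == 0) return(labels)
  disease <- setdiff(cvd_labels(), "Normal")
  p_cond <- prev[disease] / max(1 - p_norm, 1e-12)
  if (any(p_cond > 1 + 1e-9)) {
    stop("disease prevalence exceeds 1 - Normal prevalence; ",
         "labels cannot be mutually exclusive with Normal at these targets")
  }
  p_cond <- pmin(p_cond, 1)
  if (all(p_cond == 0)) {
    # degenerate: nothing to assign to non-Normal rows
    labels[!is_normal, "Normal"] <- 1L
    return(labels)
  }
  q <- solve_truncated_bernoulli(p_cond)
  draw <- function(m) {
    if (is.null(config$cooccurrence)) {
      matrix(stats::runif(m * 12), m, 12) <
        matrix(q, m, 12, byrow = TRUE)
    } else {
      R <- config$cooccurrence
      stopifnot(is.matrix(R), all(dim(R) == c(12, 12)))
      z <- matrix(stats::rnorm(m * 12), m, 12) %*% chol(R)
      z < matrix(stats::qnorm(q), m, 12, byrow = TRUE)
    }
  }
  rows <- which(!is_normal)
  d <- draw(n_dis)
  # resample all-zero rows until every record has at least one label
  for (i in 1:1000) {
    empty <- rowSums(d) == 0
    if (!any(empty)) break
    d[empty, ] <- draw(sum(empty))
  }
  labels[rows, disease] <- d * 1L
  labels
}

#' Render a 12-lead synthetic waveform
#'
#' Sums Gaussian-bump P/Q/R/S/T components over a jittered beat train,
#' projects the common template onto 12 leads by the beat's per-lead gains,
#' applies time-localised ST offsets from any `st_offset` signatures, and
#' adds Gaussian sensor noise. Beat onsets and per-beat ST windows (sample
#' indices) are attached as attributes `beat_onsets` and `st_windows` for
#' localisation oracles.
#'
#' @param beat A [beat_params()] template.
#' @param signatures List of [signature_spec()]s to plant.
#' @param seed Optional integer seed (set locally); `NULL` uses the current
#'   RNG stream.
#' @param sampling_rate Hz.
#' @param record_len Samples per lead.
#' @param noise_sd Gaussian noise SD in mV (0 for noiseless).
#' @return Numeric matrix `12 x record_len` (mV), rownames = [ecg_leads()].
#' @export
render_waveform <- function(beat, signatures = list(), seed = NULL,
                            sampling_rate = 500, record_len = 5000,
                            noise_sd = 0.03) {
  stopifnot(inherits(beat, "beat_params"))
  if (!is.null(seed)) set.seed(seed)
  ap <- apply_signatures(beat, signatures)
  b <- ap$beat
  dur <- record_len / sampling_rate
  n_beats <- ceiling((dur + 2) / b$rr_mean) + 1
  jit <- stats::rnorm(n_beats, 0, b$rr_jitter_cv)
  jit <- pmin(pmax(jit, -0.45), 0.45)
  rr <- b$rr_mean * (1 + jit)
  onsets <- 0.05 + cumsum(c(0, rr[-n_beats]))
  onsets <- onsets[onsets < dur]
  t_grid <- (seq_len(record_len) - 1) / sampling_rate
  base <- numeric(record_len)
  waves <- beat_wave_table(b)
  for (k in seq_along(onsets)) {
    for (w in seq_len(nrow(waves))) {
      c0 <- onsets[k] + waves$centre[w]
      s0 <- waves$sigma[w]
      i1 <- max(1L, floor((c0 - 4 * s0) * sampling_rate) + 1L)
      i2 <- min(record_len, ceiling((c0 + 4 * s0) * sampling_rate) + 1L)
      if (i1 > i2) next
      idx <- i1:i2
      base[idx] <- base[idx] +
        waves$amp[w] * exp(-((t_grid[idx] - c0)^2) / (2 * s0^2))
    }
  }
  wf <- outer(b$lead_projection, base)
  rownames(wf) <- ecg_leads()
  # time-localised ST offsets
  stw <- st_window(b)
  st_windows <- matrix(integer(0), ncol = 2)
  if (stw["end"] > stw["start"]) {
    st_windows <- cbind(
      pmax(1L, floor((onsets + stw["start"]) * sampling_rate) + 1L),
      pmin(record_len, ceiling((onsets + stw["end"]) * sampling_rate))
    )
    st_windows <- st_windows[st_windows[, 1] <= st_windows[, 2], ,
                             drop = FALSE]
    if (nrow(ap$st_offsets) > 0) {
      samp <- unlist(apply(st_windows, 1,
                           function(r) r[1]:r[2], simplify = FALSE))
      for (j in seq_len(nrow(ap$st_offsets))) {
        wf[ap$st_offsets$lead[j], samp] <-
          wf[ap$st_offsets$lead[j], samp] + ap$st_offsets$magnitude[j]
      }
    }
  }
  if (noise_sd > 0) {
    wf <- wf + matrix(stats::rnorm(12 * record_len, 0, noise_sd),
                      12, record_len)
  }
  attr(wf, "beat_onsets") <- onsets
  attr(wf, "st_windows") <- st_windows
  wf
}

#' Structured feature schema
#'
#' Default names of the 9 machine-measured ECG features, in order:
#' interval timings, the rate-corrected QT, the three electrical axes, and
#' the ventricular rate.
#'
#' @return Character vector of length 9.
#' @export
feature_schema <- function() {
  c("rr_interval", "pr_interval", "qrs_duration", "qt_interval",
    "qtc_interval", "p_axis", "qrs_axis", "t_axis", "ventricular_rate")
}

#' Derive structured features from generator ground truth
#'
#' Computes the 9-feature vector exactly from the (signature-modified) beat
#' parameters, not by re-measuring the rendered signal, so downstream
#' oracles are exact. QTc uses Bazett's correction `qt / sqrt(rr)`;
#' electrical axes come from the frontal-plane projection
#' `atan2(gain_aVF * amp, gain_I * amp)` in degrees per wave.
#'
#' @param beat A [beat_params()] template.
#' @param signatures List of [signature_spec()]s (parameter-level effects
#'   shift the derived features accordingly).
#' @return Named numeric vector of length 9 ([feature_schema()] order).
#' @export
derive_structured_features <- function(beat, signatures = list()) {
  b <- apply_signatures(beat, signatures)$beat
  axis_deg <- function(amp) {
    if (amp == 0) return(0)
    atan2(b$lead_projection[["aVF"]] * amp,
          b$lead_projection[["I"]] * amp) * 180 / pi
  }
  out <- c(
    rr_interval = b$rr_mean,
    pr_interval = b$pr_interval,
    qrs_duration = b$qrs_duration,
    qt_interval = b$qt_interval,
    qtc_interval = b$qt_interval / sqrt(b$rr_mean),
    p_axis = axis_deg(b$wave_amplitudes[["P"]]),
    qrs_axis = axis_deg(b$wave_amplitudes[["R"]]),
    t_axis = axis_deg(b$wave_amplitudes[["T"]]),
    ventricular_rate = 60 / b$rr_mean
  )
  names(out) <- feature_schema()
  out
}

#' Inject independent per-feature missingness
#'
#' Each feature goes missing independently with probability `rate`:
#' missing values become `NA` with validity-mask bit 0; present values are
#' unchanged with mask bit 1.
#'
#' @param features Numeric vector (or matrix, records x features).
#' @param rate Missingness probability in `[0, 1]`.
#' @param seed Optional integer seed (set locally).
#' @return List with `values` and integer `mask` of the same shape.
#' @export
inject_missingness <- function(features, rate, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1) {
    stop("rate must be a probability in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  miss <- stats::runif(length(features)) < rate
  mask <- array(1L, dim = if (is.matrix(features)) dim(features)
                else length(features))
  mask[miss] <- 0L
  values <- features
  values[miss] <- NA_real_
  if (is.matrix(features)) {
    dimnames(mask) <- dimnames(features)
  } else {
    names(mask) <- names(features)
  }
  list(values = values, mask = mask)
}

# Per-record beat template with inter-subject variability; intervals are
# clipped so the beat invariants always hold.
sample_beat <- function() {
  rr <- min(max(stats::rnorm(1, 0.85, 0.07), 0.68), 1.15)
  pr <- min(max(stats::rnorm(1, 0.16, 0.012), 0.11), 0.22)
  qrs <- min(max(stats::rnorm(1, 0.09, 0.008), 0.06), 0.13)
  qt <- min(max(stats::rnorm(1, 0.40, 0.02), 0.33, 0.23 + qrs), 0.46)
  qt <- min(qt, rr - pr - qrs - 0.02)
  amps <- c(P = 0.15, Q = -0.10, R = 1.10, S = -0.25, T = 0.30) *
    exp(stats::rnorm(5, 0, 0.05))
  beat_params(rr_mean = rr, rr_jitter_cv = 0.03, pr_interval = pr,
              qrs_duration = qrs, qt_interval = qt, wave_amplitudes = amps)
}

#' Generate a complete synthetic multimodal ECG cohort
#'
#' Draws demographics, multihot labels and per-record beat templates, plants
#' the label-conditional pathology signatures, renders the 12-lead
#' waveforms, derives ground-truth structured features with injected
#' missingness, and assigns strictly increasing acquisition timestamps.
#' The full bundle is a deterministic function of the config (same seed,
#' bit-identical cohort).
#'
#' @param config A [cohort_config()].
#' @return Object of class `ecg_cohort`: list with `ids`, `timestamps`,
#'   `ages`, `sexes`, `labels` (n x 13), `features` (n x 9), `mask`
#'   (n x 9), `waveforms` (list of 12 x record_len matrices), `meta`
#'   (per-record beat params, signatures and planted ST windows) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_records
  demo <- sample_demographics(n, config)
  labels <- sample_labels(n, config)
  timestamps <- cumsum(sample.int(50, n, replace = TRUE))
  features <- matrix(NA_real_, n, 9,
                     dimnames = list(NULL, feature_schema()))
  waveforms <- vector("list", n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    beat <- sample_beat()
    sigs <- list()
    for (lab in cvd_labels()[labels[i, ] == 1L]) {
      sigs <- c(sigs, config$signature_map[[lab]])
    }
    # comorbid records legitimately stack signatures on one quantity;
    # the duplicate-effect warning is for interactive use only
    wf <- suppressWarnings(
      render_waveform(beat, sigs, seed = NULL,
                      sampling_rate = config$sampling_rate,
                      record_len = config$record_len,
                      noise_sd = config$noise_sd))
    features[i, ] <- suppressWarnings(
      derive_structured_features(beat, sigs))
    meta[[i]] <- list(beat = suppressWarnings(apply_signatures(beat, sigs))$beat,
                      signatures = sigs,
                      beat_onsets = attr(wf, "beat_onsets"),
                      st_windows = attr(wf, "st_windows"))
    attr(wf, "beat_onsets") <- NULL
    attr(wf, "st_windows") <- NULL
    waveforms[[i]] <- wf
  }
  mm <- inject_missingness(features, config$missingness_rate)
  structure(
    list(ids = sprintf("rec%06d", seq_len(n)),
         timestamps = timestamps,
         ages = demo$ages, sexes = demo$sexes,
         labels = labels, features = mm$values, mask = mm$mask,
         waveforms = waveforms, meta = meta, config = config),
    class = "ecg_cohort"
  )
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("<ecg_cohort> %d records, %d x %d waveforms @ %g Hz\n",
              length(x$ids), 12, x$config$record_len,
              x$config$sampling_rate))
  prev <- colMeans(x$labels)
  cat("label prevalence:\n")
  print(round(prev, 3))
  invisible(x)
}
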