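#' Extract the fusion cross-attention distribution
#'
#' Returns the 1 x n_patches cross-attention row captured while the
#' structured-feature query attends to the waveform patch context — the
#' same weights returned by [forward()]; deterministic at inference.
#'
#' @param model A trained `fusion_model`.
#' @param record Preprocessed record (see [forward()]).
#' @param mode Forward mode.
#' @return Numeric vector of length n_patches summing to 1.
#' @export
extract_attention <- function(model, record, mode = "full") {
  forward(record, model, mode = mode)$attention
}

#' Map attention weights to time-anchored waveform segments
#'
#' Patch i covers samples `[(i-1) * patch_len, i * patch_len)` and the
#' corresponding seconds at the sampling rate; segments tile the record
#' exactly without overlap.
#'
#' @param attention Length-n_patches weight vector.
#' @param patch_len Samples per patch.
#' @param sampling_rate Hz.
#' @return Object of class `segment_attribution`: data.frame with patch
#'   index, start/end sample (1-based, inclusive/exclusive), start/end
#'   seconds and weight.
#' @export
attention_to_segments <- function(attention, patch_len = 50,
                                  sampling_rate = 500) {
  np <- length(attention)
  stopifnot(np >= 1, patch_len >= 1, sampling_rate > 0)
  i <- seq_len(np)
  structure(
    data.frame(
      patch = i,
      start_sample = (i - 1L) * patch_len + 1L,
      end_sample = i * patch_len,
      start_sec = (i - 1) * patch_len / sampling_rate,
      end_sec = i * patch_len / sampling_rate,
      weight = as.numeric(attention)
    ),
    class = c("segment_attribution", "data.frame")
  )
}

#' Export heatmap overlay data
#'
#' Emits the per-lead waveform traces together with the highlighted
#' segment list: segments whose attention weight lies in the top
#' `quantile` fraction (default top 20%), or the `top_k` heaviest
#' segments. Ties break towards the earliest patch. Pure data export;
#' plotting is left to the consumer.
#'
#' @param record_waveform 12 x L waveform matrix (original scale).
#' @param attribution A [attention_to_segments()] result.
#' @param top_k Number of segments to highlight (overrides `quantile`).
#' @param quantile Fraction of segments to highlight by weight.
#' @return List with `traces` (long data.frame lead/sample/seconds/value),
#'   `segments` (the attribution with a `highlight` flag) and the rule
#'   used.
#' @export
export_heatmap <- function(record_waveform, attribution, top_k = NULL,
                           quantile = 0.2) {
  stopifnot(inherits(attribution, "segment_attribution"),
            is.matrix(record_waveform), nrow(record_waveform) == 12)
  np <- nrow(attribution)
  k <- if (!is.null(top_k)) as.integer(top_k) else ceiling(quantile * np)
  k <- max(1L, min(k, np))
  ord <- order(-attribution$weight, attribution$patch)
  highlight <- logical(np)
  highlight[ord[seq_len(k)]] <- TRUE
  segments <- attribution
  segments$highlight <- highlight
  L <- ncol(record_waveform)
  sr <- if (max(attribution$end_sec) > 0) {
    max(attribution$end_sample) / max(attribution$end_sec)
  } else 500
  traces <- data.frame(
    lead = rep(rownames(record_waveform), each = L),
    sample = rep(seq_len(L), 12),
    seconds = rep((seq_len(L) - 1) / sr, 12),
    value = as.vector(t(record_waveform))
  )
  list(traces = traces, segments = segments,
       rule = if (!is.null(top_k)) sprintf("top_k=%d", k)
              else sprintf("top %d%% by weight", round(quantile * 100)))
}

#' Patches overlapping the planted ST windows of a record
#'
#' Helper for localization analyses on synthetic cohorts: returns the
#' patch indices whose sample span intersects any planted ST window.
#'
#' @param st_windows Integer matrix (k x 2) of 1-based sample windows, as
#'   stored in a cohort's `meta[[i]]$st_windows`.
#' @param patch_len Samples per patch.
#' @param n_patches Number of patches.
#' @return Integer vector of patch indices.
#' @export
st_window_patches <- function(st_windows, patch_len = 50,
                              n_patches = 100) {
  if (is.null(st_windows) || nrow(st_windows) == 0) return(integer(0))
  hits <- integer(0)
  for (r in seq_len(nrow(st_windows))) {
    p1 <- (st_windows[r, 1] - 1L) %/% patch_len + 1L
    p2 <- (st_windows[r, 2] - 1L) %/% patch_len + 1L
    hits <- c(hits, p1:p2)
  }
  as.integer(sort(unique(pmin(pmax(hits, 1L), n_patches))))
}
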