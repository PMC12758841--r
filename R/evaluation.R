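#' Binary AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed as the Mann-Whitney probability
#' `(#concordant + 0.5 #ties) / (#pos * #neg)` via midranks; exact under
#' ties.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
binary_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("binary_auc undefined: a single class is present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (AUPRC)
#'
#' Step-function average precision
#' `sum_k (R_k - R_{k-1}) P_k` over descending-score thresholds, with
#' tied scores grouped into a single threshold.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return Average precision in `(0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("average_precision undefined: no positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group ties: cumulative counts at each distinct score
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Thresholded confusion metrics
#'
#' F1, recall, precision, accuracy and specificity from the 2x2 confusion
#' table at a decision threshold. Degenerate cells use the conventional
#' fallbacks: precision 0 with no predicted positives, F1 0 when both
#' precision and recall are 0.
#'
#' @param scores Numeric scores (probabilities).
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (predict positive at
#'   `score >= threshold`).
#' @return Named numeric: f1, recall, precision, accuracy, specificity.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), length(scores) >= 1)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(f1 = f1, recall = recall, precision = precision,
    accuracy = (tp + tn) / length(scores),
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0)
}

#' Per-label and macro metrics report
#'
#' Computes AUC, AUPRC and the five thresholded metrics per label, plus a
#' macro row with the arithmetic mean and population SD across the
#' included labels. Labels that are single-class on the evaluated split
#' (undefined AUC) are excluded from the macro of the ranking metrics
#' with a warning and flagged in the report.
#'
#' @param probs n x C probability matrix (canonical label order).
#' @param labels n x C multihot matrix.
#' @param threshold Decision threshold for the confusion metrics.
#' @return Object of class `metrics_report`: list with `per_label`
#'   (data.frame), `macro` (mean and sd data.frame) and `threshold`.
#' @export
macro_report <- function(probs, labels, threshold = 0.5) {
  stopifnot(is.matrix(probs), all(dim(probs) == dim(labels)))
  C <- ncol(probs)
  label_names <- colnames(probs)
  if (is.null(label_names)) label_names <- paste0("label", seq_len(C))
  rows <- vector("list", C)
  for (cix in seq_len(C)) {
    y <- labels[, cix]
    s <- probs[, cix]
    defined <- length(unique(y)) == 2
    if (!defined) {
      warning("label '", label_names[cix],
              "' is single-class; excluded from macro ranking metrics")
    }
    tm <- threshold_metrics(s, y, threshold)
    rows[[cix]] <- data.frame(
      label = label_names[cix],
      auc = if (defined) binary_auc(s, y) else NA_real_,
      auprc = if (sum(y) > 0) average_precision(s, y) else NA_real_,
      f1 = tm[["f1"]], recall = tm[["recall"]],
      precision = tm[["precision"]], accuracy = tm[["accuracy"]],
      specificity = tm[["specificity"]],
      defined = defined
    )
  }
  per_label <- do.call(rbind, rows)
  metric_cols <- c("auc", "auprc", "f1", "recall", "precision",
                   "accuracy", "specificity")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  macro <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(mc) {
      v <- per_label[[mc]][!is.na(per_label[[mc]])]
      mean(v)
    }, numeric(1)),
    sd = vapply(metric_cols, function(mc) {
      v <- per_label[[mc]][!is.na(per_label[[mc]])]
      pop_sd(v)
    }, numeric(1)),
    n_labels = vapply(metric_cols, function(mc) {
      sum(!is.na(per_label[[mc]]))
    }, numeric(1))
  )
  structure(list(per_label = per_label, macro = macro,
                 threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> threshold", x$threshold, "\n")
  tab <- x$per_label
  tab[, -1] <- round(tab[, -1, drop = FALSE]
                     [, vapply(tab[, -1], is.numeric, logical(1)),
                       drop = FALSE], 3)
  print(tab, row.names = FALSE)
  cat("macro:\n")
  m <- x$macro
  m$mean <- round(m$mean, 3)
  m$sd <- round(m$sd, 3)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Fit per-label Platt calibrators
#'
#' Maximum-likelihood logistic recalibration `sigma(a z + b)` of each
#' label's logits on a held-out (validation) split, via [stats::glm()].
#' Single-class labels are skipped with a warning. For `a > 0` the
#' calibrator is monotone, so ranking metrics are unchanged.
#'
#' @param logits n x C matrix of uncalibrated logits.
#' @param labels n x C multihot matrix.
#' @return Object of class `platt_calibration`: data.frame with columns
#'   label, a, b, fitted.
#' @export
fit_platt <- function(logits, labels) {
  stopifnot(is.matrix(logits), all(dim(logits) == dim(labels)))
  C <- ncol(logits)
  label_names <- colnames(logits)
  if (is.null(label_names)) label_names <- paste0("label", seq_len(C))
  out <- data.frame(label = label_names, a = NA_real_, b = NA_real_,
                    fitted = FALSE)
  for (cix in seq_len(C)) {
    y <- labels[, cix]
    if (length(unique(y)) < 2) {
      warning("label '", label_names[cix],
              "' single-class; Platt fit skipped")
      next
    }
    z <- logits[, cix]
    fit <- suppressWarnings(
      stats::glm(y ~ z, family = stats::binomial()))
    out$a[cix] <- unname(stats::coef(fit)[2])
    out$b[cix] <- unname(stats::coef(fit)[1])
    out$fitted[cix] <- TRUE
  }
  structure(out, class = c("platt_calibration", "data.frame"))
}

#' Apply Platt calibrators to logits
#'
#' Labels whose calibrator was not fitted fall back to the raw sigmoid.
#'
#' @param logits n x C matrix of logits.
#' @param calibration A [fit_platt()] result.
#' @return n x C matrix of calibrated probabilities.
#' @export
apply_platt <- function(logits, calibration) {
  stopifnot(inherits(calibration, "platt_calibration"),
            ncol(logits) == nrow(calibration))
  out <- matrix(NA_real_, nrow(logits), ncol(logits),
                dimnames = dimnames(logits))
  for (cix in seq_len(ncol(logits))) {
    if (calibration$fitted[cix]) {
      out[, cix] <- stats::plogis(
        calibration$a[cix] * logits[, cix] + calibration$b[cix])
    } else {
      out[, cix] <- stats::plogis(logits[, cix])
    }
  }
  out
}

#' Calibration curve
#'
#' Equal-width probability bins on `[0, 1]`; per bin the mean predicted
#' probability and the observed positive frequency. Empty bins are
#' reported with count 0. Bin counts always sum to n and
#' `sum(count * observed)` equals the total number of positives.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @param n_bins Number of bins (default 10).
#' @return data.frame: bin, lower, upper, count, mean_pred, obs_freq.
#' @export
calibration_curve <- function(probs, labels, n_bins = 10) {
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(probs, edges, rightmost.closed = TRUE), n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    lower = edges[-(n_bins + 1)], upper = edges[-1],
                    count = 0L, mean_pred = NA_real_, obs_freq = NA_real_)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    out$count[b] <- sum(sel)
    if (any(sel)) {
      out$mean_pred[b] <- mean(probs[sel])
      out$obs_freq[b] <- mean(labels[sel])
    }
  }
  out
}

#' Demographic subgroup metrics
#'
#' Evaluates the full metrics report within sex groups or age quartiles.
#' Quartile boundaries are data-driven from the evaluated cohort by
#' default; the fixed preset cut points `{54, 66, 78}` are available via
#' `age_breaks = "preset"`. Groups partition the evaluated records;
#' empty groups are reported as empty rather than erroring.
#'
#' @param probs n x C probability matrix.
#' @param labels n x C multihot matrix.
#' @param demographics List or data.frame with `ages` and `sexes`
#'   ("M"/"F") aligned with the rows.
#' @param scheme `"sex"` or `"age_quartile"`.
#' @param age_breaks `NULL` (data-driven quartiles), `"preset"` (54, 66,
#'   78), or a numeric vector of 3 interior cut points.
#' @param threshold Decision threshold passed to [macro_report()].
#' @return Object of class `subgroup_report`: named list of groups, each
#'   with `ids` (row indices), `n` and `report` (or NULL when empty),
#'   plus the boundaries used.
#' @export
subgroup_report <- function(probs, labels, demographics,
                            scheme = c("sex", "age_quartile"),
                            age_breaks = NULL, threshold = 0.5) {
  scheme <- match.arg(scheme)
  n <- nrow(probs)
  stopifnot(length(demographics$ages) == n,
            length(demographics$sexes) == n)
  if (scheme == "sex") {
    groups <- list(female = which(demographics$sexes == "F"),
                   male = which(demographics$sexes == "M"))
    breaks <- NULL
  } else {
    if (is.null(age_breaks)) {
      breaks <- unname(stats::quantile(demographics$ages,
                                       c(0.25, 0.5, 0.75)))
    } else if (identical(age_breaks, "preset")) {
      breaks <- c(54, 66, 78)
    } else {
      stopifnot(is.numeric(age_breaks), length(age_breaks) == 3)
      breaks <- sort(age_breaks)
    }
    q <- findInterval(demographics$ages, breaks, left.open = TRUE) + 1L
    groups <- lapply(1:4, function(k) which(q == k))
    names(groups) <- sprintf("Q%d", 1:4)
  }
  out <- lapply(groups, function(idx) {
    if (length(idx) == 0) {
      list(ids = integer(0), n = 0L, report = NULL)
    } else {
      list(ids = idx, n = length(idx),
           report = suppressWarnings(
             macro_report(probs[idx, , drop = FALSE],
                          labels[idx, , drop = FALSE], threshold)))
    }
  })
  structure(list(groups = out, scheme = scheme, breaks = breaks),
            class = "subgroup_report")
}

#' Evaluate a trained model on a cohort split
#'
#' Runs inference over the given record ids and assembles probabilities,
#' metrics report, and optionally Platt-calibrated probabilities when a
#' calibration is supplied.
#'
#' @param model A trained `fusion_model`.
#' @param prep A [preprocess_cohort()] result.
#' @param ids Record ids to evaluate (e.g. `prep$split$test`).
#' @param mode Forward mode (`"full"`, `"feature_masked"`,
#'   `"without_age_sex"`).
#' @param calibration Optional [fit_platt()] result.
#' @param threshold Decision threshold.
#' @return List with `probs`, `logits`, `labels`, `attention`, `report`
#'   and (if calibrated) `probs_calibrated`, `report_calibrated`.
#' @export
evaluate_model <- function(model, prep, ids, mode = "full",
                           calibration = NULL, threshold = 0.5) {
  idx <- match(ids, prep$ids)
  stopifnot(!anyNA(idx))
  pc <- predict_cohort(model, prep, ids, mode = mode)
  logits <- stats::qlogis(pmin(pmax(pc$probs, 1e-12), 1 - 1e-12))
  colnames(logits) <- colnames(pc$probs)
  out <- list(probs = pc$probs, logits = logits, labels = pc$labels,
              attention = pc$attention,
              report = suppressWarnings(
                macro_report(pc$probs, pc$labels, threshold)))
  if (!is.null(calibration)) {
    out$probs_calibrated <- apply_platt(logits, calibration)
    out$report_calibrated <- suppressWarnings(
      macro_report(out$probs_calibrated, pc$labels, threshold))
  }
  out
}
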