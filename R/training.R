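#' Adaptive class weights from training-set prevalence
#'
#' Per-label positive weight `w_c = (N - n_c) / (n_c + eps)`, where `N` is
#' the training record count and `n_c` the positive count of label c.
#' Rare labels receive large positive weights; an all-positive label gets
#' weight 0. Computed from the training split only.
#'
#' @param labels Training multihot label matrix (N x C).
#' @param eps Smoothing constant guarding empty labels (must be > 0 when
#'   any label has no positives).
#' @return Object of class `class_weights`: list with `w`, `N`, `n_c`,
#'   `eps`.
#' @export
compute_class_weights <- function(labels, eps = 1e-6) {
  stopifnot(is.matrix(labels), nrow(labels) >= 1)
  N <- nrow(labels)
  n_c <- colSums(labels)
  if (any(n_c == 0) && eps <= 0) {
    stop("a label has no positive training examples; eps must be > 0")
  }
  w <- (N - n_c) / (n_c + eps)
  structure(list(w = w, N = N, n_c = n_c, eps = eps),
            class = "class_weights")
}

#' Class-imbalance-aware weighted binary cross-entropy
#'
#' Mean over labels (and over the batch) of
#' `-[w_c y_c log sigma(z_c) + (1 - y_c) log(1 - sigma(z_c))]`, with log
#' arguments clamped at 1e-12. With all weights 1 this reduces to plain
#' mean binary cross-entropy.
#'
#' @param logits Numeric vector (C) or matrix (B x C) of pre-sigmoid
#'   logits.
#' @param labels Matching 0/1 labels.
#' @param weights A [compute_class_weights()] result, or a numeric vector
#'   of per-label positive weights.
#' @return Scalar loss.
#' @export
weighted_bce <- function(logits, labels, weights) {
  w <- if (inherits(weights, "class_weights")) weights$w else weights
  if (any(!is.finite(logits))) stop("non-finite logits")
  if (!is.matrix(logits)) logits <- matrix(logits, 1)
  if (!is.matrix(labels)) labels <- matrix(labels, 1)
  stopifnot(all(dim(logits) == dim(labels)),
            ncol(logits) == length(w))
  s <- stats::plogis(logits)
  s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  wm <- matrix(w, nrow(logits), ncol(logits), byrow = TRUE)
  per <- -(wm * labels * log(s) + (1 - labels) * log(1 - s))
  mean(rowMeans(per))
}

# Gradient of weighted_bce w.r.t. the logits (same reduction): B x C.
weighted_bce_grad <- function(logits, labels, weights) {
  w <- if (inherits(weights, "class_weights")) weights$w else weights
  if (!is.matrix(logits)) logits <- matrix(logits, 1)
  if (!is.matrix(labels)) labels <- matrix(labels, 1)
  s <- stats::plogis(logits)
  wm <- matrix(w, nrow(logits), ncol(logits), byrow = TRUE)
  (s * (wm * labels + 1 - labels) - wm * labels) /
    (nrow(logits) * ncol(logits))
}

#' Combined validation metric
#'
#' `0.5 * macro AUC + 0.5 * macro accuracy` (accuracy thresholded at 0.5
#' per label), the scalar that steers learning-rate decay, early stopping
#' and best-checkpoint selection. Labels with a single class on the split
#' are skipped from the AUC macro with a warning.
#'
#' @param probs n x C matrix of predicted probabilities.
#' @param labels n x C multihot matrix.
#' @param threshold Decision threshold for the accuracy half.
#' @return Scalar in `[0, 1]`.
#' @export
combined_metric <- function(probs, labels, threshold = 0.5) {
  if (!is.matrix(probs) || nrow(probs) == 0) {
    stop("probs must be a non-empty matrix")
  }
  stopifnot(all(dim(probs) == dim(labels)))
  aucs <- numeric(0)
  for (cix in seq_len(ncol(probs))) {
    y <- labels[, cix]
    if (length(unique(y)) < 2) {
      warning("label ", cix, " single-class on this split; ",
              "skipped from macro AUC")
      next
    }
    aucs <- c(aucs, binary_auc(probs[, cix], y))
  }
  acc <- mean(colMeans((probs >= threshold) == (labels == 1)))
  0.5 * mean(aucs) + 0.5 * acc
}

#' Training configuration
#'
#' Optimiser and schedule settings: AdamW-style adaptive gradients with
#' global-norm clipping, plateau learning-rate decay with a relative
#' improvement threshold and cooldown, early stopping, and retention of
#' the best-validation checkpoint.
#'
#' @param max_epochs Epoch cap.
#' @param batch_size Minibatch size.
#' @param lr Base learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param clip_norm Global gradient-norm clip.
#' @param plateau_patience Non-improving epochs before a decay fires.
#' @param decay_factor Multiplier applied to the LR at a plateau.
#' @param rel_threshold Relative improvement needed to reset the plateau
#'   counter.
#' @param cooldown Epochs after a decay during which the counter is held.
#' @param early_stop_patience Epochs without meaningful improvement before
#'   training stops.
#' @param feature_dropout Probability, per record and step, of masking the
#'   entire structured-feature modality (values and validity bits zeroed)
#'   during training. This modality dropout makes the feature-masked
#'   inference mode in-distribution and forces the waveform path to carry
#'   diagnostic signal on its own, the property probed by the
#'   feature-masking ablation.
#' @param seed Seed for init, shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(max_epochs = 200, batch_size = 32, lr = 1e-4,
                         weight_decay = 0.01, clip_norm = 1.0,
                         plateau_patience = 5, decay_factor = 0.5,
                         rel_threshold = 1e-3, cooldown = 2,
                         early_stop_patience = 10, feature_dropout = 0.25,
                         seed = 1L) {
  stopifnot(max_epochs >= 1, batch_size >= 1, lr > 0, clip_norm > 0,
            plateau_patience >= 1, decay_factor > 0, decay_factor < 1,
            rel_threshold >= 0, cooldown >= 0, early_stop_patience >= 1,
            feature_dropout >= 0, feature_dropout < 1)
  structure(as.list(environment()), class = "train_config")
}

#' Plateau learning-rate scheduler (stepper)
#'
#' Stateful plateau schedule over a maximised metric: an epoch improves
#' when the metric exceeds the best so far by more than `rel_threshold`
#' relatively; after `patience` consecutive non-improving epochs the LR is
#' multiplied by `decay_factor` and a `cooldown` period follows during
#' which the plateau counter is frozen. A separate counter triggers early
#' stop after `early_stop_patience` epochs without improvement.
#'
#' @param lr Initial learning rate.
#' @param patience,factor,rel_threshold,cooldown Plateau parameters.
#' @param early_stop_patience Early-stopping patience.
#' @return A scheduler state list; advance it with [scheduler_step()].
#' @export
scheduler_init <- function(lr, patience = 5, factor = 0.5,
                           rel_threshold = 1e-3, cooldown = 2,
                           early_stop_patience = 10) {
  list(lr = lr, patience = patience, factor = factor,
       rel_threshold = rel_threshold, cooldown = cooldown,
       early_stop_patience = early_stop_patience,
       best = -Inf, num_bad = 0L, cooldown_left = 0L,
       since_best = 0L, decayed = FALSE, stop = FALSE)
}

#' Advance the plateau scheduler by one epoch
#'
#' @param state State from [scheduler_init()] or a previous step.
#' @param metric This epoch's validation metric (higher is better).
#' @return Updated state; fields `lr`, `decayed` (did a decay fire this
#'   epoch), `stop` (early-stop trigger).
#' @export
scheduler_step <- function(state, metric) {
  improved <- metric > state$best +
    state$rel_threshold * max(abs(state$best), 1e-12)
  state$decayed <- FALSE
  if (is.infinite(state$best)) improved <- TRUE
  if (improved) {
    state$best <- metric
    state$num_bad <- 0L
    state$since_best <- 0L
  } else {
    state$since_best <- state$since_best + 1L
    if (state$cooldown_left > 0L) {
      state$cooldown_left <- state$cooldown_left - 1L
      state$num_bad <- 0L
    } else {
      state$num_bad <- state$num_bad + 1L
    }
  }
  if (state$num_bad >= state$patience) {
    state$lr <- state$lr * state$factor
    state$decayed <- TRUE
    state$cooldown_left <- state$cooldown
    state$num_bad <- 0L
  }
  if (state$since_best >= state$early_stop_patience) state$stop <- TRUE
  state
}

# Adam with decoupled weight decay over a flat named parameter list.
adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * gnm
    state$v[[nm]] <- state$beta2 * state$v[[nm]] +
      (1 - state$beta2) * gnm^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
    params[[nm]] <- params[[nm]] - lr * upd -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

# Global-norm gradient clipping.
clip_gradients <- function(grads, clip_norm) {
  total <- sqrt(sum(vapply(grads, function(x) sum(x^2), numeric(1))))
  if (is.finite(total) && total > clip_norm) {
    grads <- lapply(grads, function(x) x * (clip_norm / total))
  }
  grads
}

# Validation-set probabilities in fixed order (inference mode).
predict_cohort <- function(model, prep, ids, mode = "full",
                           batch_size = 64) {
  idx <- match(ids, prep$ids)
  out <- matrix(NA_real_, length(idx), model$config$n_labels)
  att <- matrix(NA_real_, length(idx), model$config$n_patches)
  starts <- seq(1, length(idx), by = batch_size)
  for (s in starts) {
    sel <- s:min(s + batch_size - 1, length(idx))
    fb <- model_forward_batch(model, make_batch(prep, idx[sel]),
                              mode = mode)
    out[sel, ] <- stats::plogis(fb$logits)
    att[sel, ] <- fb$attention
  }
  colnames(out) <- colnames(prep$labels)
  list(probs = out, attention = att,
       labels = prep$labels[idx, , drop = FALSE])
}

#' Train the fusion model
#'
#' Minibatch AdamW on the weighted binary cross-entropy with per-step
#' global-norm gradient clipping; after every epoch the combined metric
#' (0.5 AUC + 0.5 accuracy) on the validation split drives plateau LR
#' decay, early stopping and best-checkpoint retention. The returned
#' model is always the checkpoint with the best validation metric, never
#' simply the last epoch. Fully seeded: identical config + data give an
#' identical history.
#'
#' @param model An [init_model()] result.
#' @param prep A [preprocess_cohort()] result.
#' @param config A [train_config()].
#' @param mode Training mode: `"full"` or `"without_age_sex"`.
#' @param class_weights Optional [compute_class_weights()] override;
#'   `NULL` computes them from the training split.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint), `history` (data.frame:
#'   epoch, loss, lr, metric), `class_weights` and `best_epoch`.
#' @export
train_model <- function(model, prep, config = train_config(),
                        mode = "full", class_weights = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  # force promises before seeding: a lazily evaluated init_model(...)
  # argument would otherwise reset the RNG mid-setup
  force(model)
  force(prep)
  force(class_weights)
  set.seed(config$seed)
  train_idx <- match(prep$split$train, prep$ids)
  if (is.null(class_weights)) {
    class_weights <- compute_class_weights(
      prep$labels[train_idx, , drop = FALSE])
  }
  sched <- scheduler_init(config$lr, config$plateau_patience,
                          config$decay_factor, config$rel_threshold,
                          config$cooldown, config$early_stop_patience)
  opt <- adam_init(model$params)
  best_params <- model$params
  best_metric <- -Inf
  best_epoch <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        lr = numeric(0), metric = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    starts <- seq(1, length(ord), by = config$batch_size)
    epoch_loss <- 0
    n_seen <- 0
    for (s in starts) {
      sel <- ord[s:min(s + config$batch_size - 1, length(ord))]
      batch <- make_batch(prep, sel)
      if (config$feature_dropout > 0) {
        drop_rec <- stats::runif(batch$B) < config$feature_dropout
        if (any(drop_rec)) {
          batch$feat[drop_rec, ] <- 0
          batch$mask[drop_rec, ] <- 0
        }
      }
      fb <- model_forward_batch(model, batch, mode = mode,
                                dropout_p = model$config$dropout,
                                keep_cache = TRUE)
      loss <- weighted_bce(fb$logits, batch$labels, class_weights)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; aborting (check learning rate / clipping)")
      }
      dlogits <- weighted_bce_grad(fb$logits, batch$labels, class_weights)
      grads <- model_backward_batch(model, fb$cache, dlogits)
      grads <- clip_gradients(grads, config$clip_norm)
      stepped <- adam_step(model$params, grads, opt, sched$lr,
                           config$weight_decay)
      model$params <- stepped$params
      opt <- stepped$state
      epoch_loss <- epoch_loss + loss * length(sel)
      n_seen <- n_seen + length(sel)
    }
    val <- suppressWarnings(
      predict_cohort(model, prep, prep$split$validation, mode = mode))
    metric <- suppressWarnings(combined_metric(val$probs, val$labels))
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epoch_loss / n_seen,
                                lr = sched$lr, metric = metric))
    if (metric > best_metric) {
      best_metric <- metric
      best_params <- model$params
      best_epoch <- epoch
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  lr %.2e  metric %.4f%s",
                      epoch, epoch_loss / n_seen, sched$lr, metric,
                      if (metric == best_metric) " *" else ""))
    }
    sched <- scheduler_step(sched, metric)
    if (sched$stop) break
  }
  model$params <- best_params
  list(model = model, history = history, class_weights = class_weights,
       best_epoch = best_epoch, best_metric = best_metric)
}
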