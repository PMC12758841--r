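#' Model architecture configuration
#'
#' Hyperparameters of the multimodal fusion transformer. Defaults follow
#' the ViT/BERT-scale reference configuration: 768-dimensional embeddings,
#' 50-sample non-overlapping patches (100 per 5000-sample record), a
#' 6-layer encoder with 8 self-attention heads, and two metadata tokens
#' (age, sex). Tests and desk-scale training use a reduced configuration
#' (`embed_dim = 64`, 2 layers, 2 heads) on the same code path.
#'
#' @param embed_dim Token dimension D; must be divisible by `n_heads`.
#' @param patch_len Samples per waveform patch.
#' @param n_patches Patches per record; `patch_len * n_patches` must equal
#'   the fixed record length.
#' @param n_layers Encoder depth (0 allowed: identity encoder, test-only).
#' @param n_heads Self-attention heads per encoder layer.
#' @param n_features Structured feature count (9).
#' @param n_labels Output label count (13).
#' @param metadata_tokens 2 (separate age and sex tokens), 1 (joint
#'   demographic token) or 0 (demographics-free variant).
#' @param dropout Dropout rate on the residual branches during training.
#' @param ffn_mult Hidden-width multiplier of the encoder feed-forward
#'   blocks.
#' @param n_leads Waveform leads (12).
#' @return Object of class `model_config`.
#' @export
model_config <- function(embed_dim = 768, patch_len = 50, n_patches = 100,
                         n_layers = 6, n_heads = 8, n_features = 9,
                         n_labels = 13, metadata_tokens = 2, dropout = 0.1,
                         ffn_mult = 4, n_leads = 12) {
  stopifnot(
    embed_dim >= 1, patch_len >= 1, n_patches >= 1, n_layers >= 0,
    n_heads >= 1, embed_dim %% n_heads == 0,
    n_features >= 1, n_labels >= 1,
    metadata_tokens %in% 0:2,
    dropout >= 0, dropout < 1, ffn_mult >= 1
  )
  structure(
    list(embed_dim = as.integer(embed_dim),
         patch_len = as.integer(patch_len),
         n_patches = as.integer(n_patches),
         n_layers = as.integer(n_layers),
         n_heads = as.integer(n_heads),
         n_features = as.integer(n_features),
         n_labels = as.integer(n_labels),
         metadata_tokens = as.integer(metadata_tokens),
         dropout = dropout,
         ffn_mult = as.integer(ffn_mult),
         n_leads = as.integer(n_leads),
         seq_len = 2L + as.integer(n_patches) + as.integer(metadata_tokens)),
    class = "model_config"
  )
}

#' Initialise model parameters
#'
#' Truncated-normal (sd 0.02) weight init, zero biases, unit layer-norm
#' gains, and learned per-position embeddings over the full assembled
#' sequence (CLS, fusion, patches, metadata).
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialisation draw.
#' @return Object of class `fusion_model`: list with `params` (flat named
#'   list of arrays) and `config`.
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  D <- config$embed_dim
  dn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
  p <- list(
    W_patch = dn(config$n_leads * config$patch_len, D),
    b_patch = numeric(D),
    W_feat1 = dn(2L * config$n_features, D), b_feat1 = numeric(D),
    W_feat2 = dn(D, D), b_feat2 = numeric(D),
    Wq = dn(D, D), Wk = dn(D, D), Wv = dn(D, D),
    Ff1 = dn(D, D), fb1 = numeric(D),
    Ff2 = dn(D, D), fb2 = numeric(D),
    fus_g = rep(1, D), fus_b = numeric(D),
    cls = stats::rnorm(D, 0, 0.02),
    pos = dn(config$seq_len, D),
    W_head = dn(D, config$n_labels), b_head = numeric(config$n_labels)
  )
  if (config$metadata_tokens == 2L) {
    p$W_age <- dn(1, D); p$b_age <- numeric(D)
    p$W_sex <- dn(1, D); p$b_sex <- numeric(D)
  } else if (config$metadata_tokens == 1L) {
    p$W_meta <- dn(2, D); p$b_meta <- numeric(D)
  }
  H <- config$ffn_mult * D
  for (l in seq_len(config$n_layers)) {
    pre <- sprintf("L%d.", l)
    p[[paste0(pre, "ln1_g")]] <- rep(1, D)
    p[[paste0(pre, "ln1_b")]] <- numeric(D)
    p[[paste0(pre, "Wqkv")]] <- dn(D, 3L * D)
    p[[paste0(pre, "bqkv")]] <- numeric(3L * D)
    p[[paste0(pre, "Wo")]] <- dn(D, D)
    p[[paste0(pre, "bo")]] <- numeric(D)
    p[[paste0(pre, "ln2_g")]] <- rep(1, D)
    p[[paste0(pre, "ln2_b")]] <- numeric(D)
    p[[paste0(pre, "Wf1")]] <- dn(D, H)
    p[[paste0(pre, "bf1")]] <- numeric(H)
    p[[paste0(pre, "Wf2")]] <- dn(H, D)
    p[[paste0(pre, "bf2")]] <- numeric(D)
  }
  structure(list(params = p, config = config), class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<fusion_model> D=%d, %d layers x %d heads, %d patches (len %d), %s\n",
    cfg$embed_dim, cfg$n_layers, cfg$n_heads, cfg$n_patches, cfg$patch_len,
    format(n_par, big.mark = ",")))
  invisible(x)
}

# ---- numerical primitives ----------------------------------------------

# GELU, tanh approximation (forward and input derivative). The *_cached
# variants reuse the forward tanh in the backward pass (training hot path).
gelu <- function(x) {
  xx <- x * x
  u <- sqrt(2 / pi) * x * (1 + 0.044715 * xx)
  0.5 * x * (1 + tanh(u))
}

gelu_fwd <- function(x) {
  xx <- x * x
  u <- sqrt(2 / pi) * x * (1 + 0.044715 * xx)
  th <- tanh(u)
  list(y = 0.5 * x * (1 + th), th = th)
}

gelu_grad <- function(x) {
  gelu_grad_cached(x, gelu_fwd(x)$th)
}

gelu_grad_cached <- function(x, th) {
  a <- sqrt(2 / pi)
  xx <- x * x
  0.5 * (1 + th) +
    0.5 * x * (1 - th * th) * a * (1 + 3 * 0.044715 * xx)
}

# row-wise softmax with max subtraction
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# add a length-ncol vector to every row / multiply every row by it
addrow <- function(x, b) x + rep(b, each = nrow(x))
mulrow <- function(x, g) x * rep(g, each = nrow(x))

# row-wise layer normalization; returns y plus backward cache
ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = addrow(mulrow(xhat, g), b), xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  dxhat <- mulrow(dy, g)
  xhat <- cache$xhat
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx,
       dg = colSums(dy * xhat),
       db = colSums(dy))
}

# ---- single-record operation surface -----------------------------------

#' Embed waveform patches
#'
#' Maps each non-overlapping 12-lead x `patch_len` window to one
#' D-dimensional token through the learned convolutional projection
#' (kernel width = stride = `patch_len`, realised as a linear map on the
#' flattened window). Token order is time order.
#'
#' @param waveform Preprocessed 12 x (patch_len * n_patches) matrix.
#' @param model A [init_model()] result.
#' @return `n_patches` x D matrix of patch tokens.
#' @export
embed_patches <- function(waveform, model) {
  cfg <- model$config
  if (!is.matrix(waveform) || nrow(waveform) != cfg$n_leads) {
    stop("waveform must have ", cfg$n_leads, " lead rows")
  }
  if (ncol(waveform) != cfg$patch_len * cfg$n_patches) {
    stop("record length ", ncol(waveform), " does not equal patch_len * ",
         "n_patches = ", cfg$patch_len * cfg$n_patches)
  }
  P <- waveform_to_patches(waveform, cfg$patch_len)
  sweep(P %*% model$params$W_patch, 2, model$params$b_patch, "+")
}

#' Embed the structured feature token
#'
#' The 9 standardized values concatenated with their 9 validity-mask bits
#' pass through a feed-forward network (one GELU hidden layer) to a single
#' D-token. The all-zero values / all-zero mask input (feature-masked
#' inference) is valid and maps to the learned bias image.
#'
#' @param values Standardized feature values (length 9).
#' @param mask Validity mask bits (length 9).
#' @param model A [init_model()] result.
#' @return 1 x D matrix.
#' @export
embed_feature_token <- function(values, mask, model) {
  cfg <- model$config
  if (length(values) != cfg$n_features || length(mask) != cfg$n_features) {
    stop("expected ", cfg$n_features, " feature values and mask bits")
  }
  x <- matrix(c(values, mask), 1)
  h <- gelu(sweep(x %*% model$params$W_feat1, 2, model$params$b_feat1, "+"))
  sweep(h %*% model$params$W_feat2, 2, model$params$b_feat2, "+")
}

#' Embed demographic metadata tokens
#'
#' Age and sex each map through their own linear embedding to one D-token
#' (default two tokens; one joint token or none are configurable). Returns
#' a zero-row matrix for the demographics-free variant.
#'
#' @param age_n Normalized age (scalar).
#' @param sex Binary sex code: 1 = male, 0 = female.
#' @param model A [init_model()] result.
#' @return `metadata_tokens` x D matrix.
#' @export
embed_metadata <- function(age_n, sex, model) {
  cfg <- model$config
  if (!sex %in% c(0, 1)) stop("sex code must be 0 (F) or 1 (M)")
  p <- model$params
  D <- cfg$embed_dim
  if (cfg$metadata_tokens == 0L) {
    return(matrix(numeric(0), 0, D))
  }
  if (cfg$metadata_tokens == 1L) {
    return(sweep(matrix(c(age_n, sex), 1) %*% p$W_meta, 2, p$b_meta, "+"))
  }
  rbind(
    age_n * p$W_age[1, ] + p$b_age,
    sex * p$W_sex[1, ] + p$b_sex
  )
}

#' Query-conditioned cross-attention fusion
#'
#' The structured feature token is the query; patch tokens provide the
#' key-value context. Single-head scaled dot-product attention
#' (`softmax(Q K' / sqrt(D))`) retrieves a context vector Z, which passes
#' through a GELU feed-forward block and is combined with the feature
#' token by a layer-normalized residual, yielding the fusion token.
#'
#' @param feature_token 1 x D matrix (the query).
#' @param patch_tokens n_patches x D matrix (the context).
#' @param model A [init_model()] result.
#' @return List with `token` (1 x D fusion token) and `attention`
#'   (length-n_patches weight vector summing to 1).
#' @export
cross_attention_fuse <- function(feature_token, patch_tokens, model) {
  p <- model$params
  D <- model$config$embed_dim
  if (ncol(feature_token) != D || ncol(patch_tokens) != D) {
    stop("token dimension mismatch: expected D = ", D)
  }
  Q <- feature_token %*% p$Wq
  K <- patch_tokens %*% p$Wk
  V <- patch_tokens %*% p$Wv
  scores <- as.vector(K %*% t(Q)) / sqrt(D)
  A <- exp(scores - max(scores))
  A <- A / sum(A)
  Z <- matrix(A, 1) %*% V
  h <- gelu(sweep(Z %*% p$Ff1, 2, p$fb1, "+"))
  ffn_out <- sweep(h %*% p$Ff2, 2, p$fb2, "+")
  fused <- ln_forward(feature_token + ffn_out, p$fus_g, p$fus_b)$y
  list(token = fused, attention = A)
}

#' Assemble the encoder input sequence
#'
#' Fixed order `[CLS, fusion, patch_1..patch_Np, metadata...]`, with the
#' learned positional embedding added index-wise. The classifier reads
#' position 1 (CLS) downstream.
#'
#' @param fusion_token 1 x D matrix.
#' @param patch_tokens n_patches x D matrix.
#' @param metadata_tokens m x D matrix (possibly zero rows).
#' @param model A [init_model()] result.
#' @return (2 + n_patches + m) x D matrix.
#' @export
assemble_sequence <- function(fusion_token, patch_tokens, metadata_tokens,
                              model) {
  seq <- rbind(matrix(model$params$cls, 1), fusion_token, patch_tokens,
               metadata_tokens)
  seq + model$params$pos[seq_len(nrow(seq)), , drop = FALSE]
}

#' Transformer encoding
#'
#' `n_layers` pre-norm blocks (multi-head self-attention + GELU
#' feed-forward, both residual) over the assembled sequence; shape
#' preserving, identity at zero depth. Inference mode (no dropout).
#'
#' @param sequence T x D matrix from [assemble_sequence()].
#' @param model A [init_model()] result.
#' @return T x D matrix.
#' @export
encode <- function(sequence, model) {
  cfg <- model$config
  p <- model$params
  Tn <- nrow(sequence)
  D <- cfg$embed_dim
  nh <- cfg$n_heads
  dh <- D %/% nh
  X <- sequence
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d.", l)
    Xn <- ln_forward(X, p[[paste0(pre, "ln1_g")]],
                     p[[paste0(pre, "ln1_b")]])$y
    QKV <- sweep(Xn %*% p[[paste0(pre, "Wqkv")]], 2,
                 p[[paste0(pre, "bqkv")]], "+")
    O <- matrix(0, Tn, D)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Qh <- QKV[, cols, drop = FALSE]
      Kh <- QKV[, D + cols, drop = FALSE]
      Vh <- QKV[, 2 * D + cols, drop = FALSE]
      A <- softmax_rows(Qh %*% t(Kh) / sqrt(dh))
      O[, cols] <- A %*% Vh
    }
    X <- X + sweep(O %*% p[[paste0(pre, "Wo")]], 2,
                   p[[paste0(pre, "bo")]], "+")
    Xn2 <- ln_forward(X, p[[paste0(pre, "ln2_g")]],
                      p[[paste0(pre, "ln2_b")]])$y
    H <- gelu(sweep(Xn2 %*% p[[paste0(pre, "Wf1")]], 2,
                    p[[paste0(pre, "bf1")]], "+"))
    X <- X + sweep(H %*% p[[paste0(pre, "Wf2")]], 2,
                   p[[paste0(pre, "bf2")]], "+")
  }
  X
}

#' Multilabel classification head
#'
#' Single linear map from the encoded CLS state (sequence position 1) to
#' the 13 logits in canonical label order.
#'
#' @param encoded T x D matrix from [encode()].
#' @param model A [init_model()] result.
#' @return Named numeric vector of `n_labels` logits.
#' @export
classify <- function(encoded, model) {
  logits <- drop(encoded[1, , drop = FALSE] %*% model$params$W_head) +
    model$params$b_head
  names(logits) <- if (model$config$n_labels == 13L) cvd_labels() else NULL
  logits
}

#' Full single-record forward pass
#'
#' Composes the embedding, fusion, assembly, encoding and classification
#' stages for one preprocessed record. Modes: `"full"` uses every
#' modality; `"feature_masked"` zeroes the structured feature values and
#' mask bits at inference (weights untouched); `"without_age_sex"` drops
#' the metadata tokens (the demographics-free variant, also usable on a
#' metadata-trained model for ablation probes). Deterministic at
#' inference.
#'
#' @param record List with `waveform` (preprocessed 12 x L), `features`
#'   (standardized, 9), `mask` (9), `age_n` (scalar) and `sex01` (0/1).
#' @param model A [init_model()] result.
#' @param mode One of `"full"`, `"feature_masked"`, `"without_age_sex"`.
#' @return List with `logits` (length n_labels) and `attention`
#'   (length n_patches fusion attention).
#' @export
forward <- function(record, model,
                    mode = c("full", "feature_masked", "without_age_sex")) {
  mode <- match.arg(mode)
  values <- record$features
  mask <- record$mask
  if (mode == "feature_masked") {
    values <- numeric(model$config$n_features)
    mask <- numeric(model$config$n_features)
  }
  patch_tok <- embed_patches(record$waveform, model)
  feat_tok <- embed_feature_token(values, mask, model)
  fus <- cross_attention_fuse(feat_tok, patch_tok, model)
  meta_tok <- if (mode == "without_age_sex" ||
                  model$config$metadata_tokens == 0L) {
    matrix(numeric(0), 0, model$config$embed_dim)
  } else {
    embed_metadata(record$age_n, record$sex01, model)
  }
  seq <- assemble_sequence(fus$token, patch_tok, meta_tok, model)
  enc <- encode(seq, model)
  list(logits = classify(enc, model), attention = fus$attention)
}

#' Sigmoid label probabilities
#'
#' Element-wise logistic transform of the multilabel logits.
#'
#' @param logits Numeric vector or matrix of logits.
#' @return Probabilities in (0, 1), same shape.
#' @export
predict_proba <- function(logits) {
  if (any(!is.finite(logits))) stop("logits must be finite")
  stats::plogis(logits)
}
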