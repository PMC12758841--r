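# Batched forward/backward passes over stacked record matrices.
#
# Layout convention: a batch of B records with Np patches each stacks its
# patch rows record-major, patch-fastest: row (b-1)*Np + j is patch j of
# record b. Assembled sequences stack the same way with T = 2 + Np + m
# rows per record. The single-record operation surface in model.R is the
# reference semantics; equality of the two paths is covered by tests.

# Build a batch structure from a preprocessed cohort and record indices.
make_batch <- function(prep, idx) {
  list(
    P = do.call(rbind, prep$patches[idx]),
    feat = prep$features[idx, , drop = FALSE],
    mask = prep$mask[idx, , drop = FALSE],
    age_n = prep$age_n[idx],
    sex01 = prep$sex01[idx],
    labels = prep$labels[idx, , drop = FALSE],
    B = length(idx)
  )
}

# Full batched forward pass. Returns logits (B x C), attention (B x Np)
# and, when keep_cache, every intermediate needed by the backward pass.
# dropout_p > 0 draws inverted-dropout masks from the current RNG stream.
model_forward_batch <- function(model, batch,
                                mode = "full",
                                dropout_p = 0,
                                keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  D <- cfg$embed_dim
  Np <- cfg$n_patches
  B <- batch$B
  nh <- cfg$n_heads
  dh <- D %/% nh
  use_meta <- cfg$metadata_tokens > 0L && mode != "without_age_sex"
  m_tok <- if (use_meta) cfg$metadata_tokens else 0L
  Tn <- 2L + Np + m_tok

  feat <- batch$feat
  mask <- batch$mask
  if (mode == "feature_masked") {
    feat <- matrix(0, B, cfg$n_features)
    mask <- matrix(0, B, cfg$n_features)
  }

  # patch tokens
  Xp <- addrow(batch$P %*% p$W_patch, p$b_patch)

  # feature token
  Xin_f <- cbind(feat, mask)
  pre_f <- addrow(Xin_f %*% p$W_feat1, p$b_feat1)
  gf <- gelu_fwd(pre_f)
  H_f <- gf$y
  th_f <- gf$th
  Xs <- addrow(H_f %*% p$W_feat2, p$b_feat2)

  # metadata tokens
  if (use_meta) {
    if (cfg$metadata_tokens == 2L) {
      age_tok <- outer(batch$age_n, p$W_age[1, ]) +
        matrix(p$b_age, B, D, byrow = TRUE)
      sex_tok <- outer(batch$sex01, p$W_sex[1, ]) +
        matrix(p$b_sex, B, D, byrow = TRUE)
    } else {
      meta_in <- cbind(batch$age_n, batch$sex01)
      meta_tok <- addrow(meta_in %*% p$W_meta, p$b_meta)
    }
  }

  # cross-attention fusion (query = feature token, context = patches)
  grp <- rep(seq_len(B), each = Np)
  Q <- Xs %*% p$Wq
  K <- Xp %*% p$Wk
  V <- Xp %*% p$Wv
  scores <- rowSums(K * Q[grp, , drop = FALSE]) / sqrt(D)
  Smat <- matrix(scores, Np, B)
  Smat <- sweep(Smat, 2, apply(Smat, 2, max))
  Amat <- exp(Smat)
  Amat <- sweep(Amat, 2, colSums(Amat), "/")   # Np x B, columns sum to 1
  Avec <- as.vector(Amat)
  Z <- rowsum(V * Avec, grp)                   # B x D
  pre_z <- addrow(Z %*% p$Ff1, p$fb1)
  gz <- gelu_fwd(pre_z)
  H_z <- gz$y
  th_z <- gz$th
  ffn_z <- addrow(H_z %*% p$Ff2, p$fb2)
  fus_in <- Xs + ffn_z
  fus_ln <- ln_forward(fus_in, p$fus_g, p$fus_b)
  Xfus <- fus_ln$y

  # sequence assembly + positional embeddings
  idx_cls <- (seq_len(B) - 1L) * Tn + 1L
  idx_fus <- idx_cls + 1L
  idx_patch <- as.vector(outer(seq_len(Np) + 2L, (seq_len(B) - 1L) * Tn,
                               "+"))
  X <- matrix(0, B * Tn, D)
  X[idx_cls, ] <- matrix(p$cls, B, D, byrow = TRUE)
  X[idx_fus, ] <- Xfus
  X[idx_patch, ] <- Xp
  if (use_meta) {
    idx_meta1 <- idx_cls + 2L + Np
    if (cfg$metadata_tokens == 2L) {
      idx_meta2 <- idx_meta1 + 1L
      X[idx_meta1, ] <- age_tok
      X[idx_meta2, ] <- sex_tok
    } else {
      X[idx_meta1, ] <- meta_tok
    }
  }
  pos_rep <- p$pos[rep(seq_len(Tn), B), , drop = FALSE]
  X <- X + pos_rep

  # encoder
  layer_caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d.", l)
    lc <- list(X_in = X)
    ln1 <- ln_forward(X, p[[paste0(pre, "ln1_g")]],
                      p[[paste0(pre, "ln1_b")]])
    QKV <- addrow(ln1$y %*% p[[paste0(pre, "Wqkv")]],
                  p[[paste0(pre, "bqkv")]])
    O <- matrix(0, B * Tn, D)
    Pcache <- if (keep_cache) array(0, c(Tn, Tn, B, nh)) else NULL
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        Qh <- QKV[rows, cols, drop = FALSE]
        Kh <- QKV[rows, D + cols, drop = FALSE]
        Vh <- QKV[rows, 2L * D + cols, drop = FALSE]
        A <- softmax_rows(tcrossprod(Qh, Kh) / sqrt(dh))
        O[rows, cols] <- A %*% Vh
        if (keep_cache) Pcache[, , b, h] <- A
      }
    }
    attn_out <- addrow(O %*% p[[paste0(pre, "Wo")]],
                       p[[paste0(pre, "bo")]])
    if (dropout_p > 0) {
      dm1 <- matrix((stats::runif(length(attn_out)) >= dropout_p) /
                      (1 - dropout_p), nrow(attn_out), ncol(attn_out))
      attn_out <- attn_out * dm1
    } else dm1 <- NULL
    X <- X + attn_out
    ln2 <- ln_forward(X, p[[paste0(pre, "ln2_g")]],
                      p[[paste0(pre, "ln2_b")]])
    pre_h <- addrow(ln2$y %*% p[[paste0(pre, "Wf1")]],
                    p[[paste0(pre, "bf1")]])
    gh <- gelu_fwd(pre_h)
    Hh <- gh$y
    ffn_out <- addrow(Hh %*% p[[paste0(pre, "Wf2")]],
                      p[[paste0(pre, "bf2")]])
    if (dropout_p > 0) {
      dm2 <- matrix((stats::runif(length(ffn_out)) >= dropout_p) /
                      (1 - dropout_p), nrow(ffn_out), ncol(ffn_out))
      ffn_out <- ffn_out * dm2
    } else dm2 <- NULL
    if (keep_cache) {
      lc$ln1 <- ln1; lc$QKV <- QKV; lc$P <- Pcache
      lc$O <- O; lc$dm1 <- dm1
      lc$ln2 <- ln2; lc$pre_h <- pre_h; lc$th_h <- gh$th
      lc$H <- Hh; lc$dm2 <- dm2
      layer_caches[[l]] <- lc
    }
    X <- X + ffn_out
  }

  cls_states <- X[idx_cls, , drop = FALSE]
  logits <- addrow(cls_states %*% p$W_head, p$b_head)
  colnames(logits) <- if (cfg$n_labels == 13L) cvd_labels() else NULL

  cache <- NULL
  if (keep_cache) {
    cache <- list(
      mode = mode, B = B, Tn = Tn, m_tok = m_tok, use_meta = use_meta,
      grp = grp,
      idx_cls = idx_cls, idx_fus = idx_fus, idx_patch = idx_patch,
      P_in = batch$P, Xin_f = Xin_f, pre_f = pre_f, th_f = th_f,
      H_f = H_f, Xs = Xs,
      age_n = batch$age_n, sex01 = batch$sex01,
      Xp = Xp, Q = Q, K = K, V = V, Amat = Amat, Z = Z,
      pre_z = pre_z, th_z = th_z, H_z = H_z, fus_ln = fus_ln,
      layers = layer_caches,
      cls_states = cls_states
    )
  }
  list(logits = logits, attention = t(Amat), cache = cache)
}

# Batched backward pass. dlogits is B x C; returns the gradient as a flat
# named list matching model$params.
model_backward_batch <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  D <- cfg$embed_dim
  Np <- cfg$n_patches
  B <- cache$B
  Tn <- cache$Tn
  nh <- cfg$n_heads
  dh <- D %/% nh
  g <- list()

  # head
  g$W_head <- crossprod(cache$cls_states, dlogits)
  g$b_head <- colSums(dlogits)
  dX <- matrix(0, B * Tn, D)
  dX[cache$idx_cls, ] <- tcrossprod(dlogits, p$W_head)

  # encoder layers, reversed
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("L%d.", l)
    lc <- cache$layers[[l]]
    # FFN sublayer: X_out = X_after_attn + dropout(ffn_out)
    dffn <- dX
    if (!is.null(lc$dm2)) dffn <- dffn * lc$dm2
    g[[paste0(pre, "Wf2")]] <- crossprod(lc$H, dffn)
    g[[paste0(pre, "bf2")]] <- colSums(dffn)
    dH <- tcrossprod(dffn, p[[paste0(pre, "Wf2")]])
    dpre_h <- dH * gelu_grad_cached(lc$pre_h, lc$th_h)
    g[[paste0(pre, "Wf1")]] <- crossprod(lc$ln2$y, dpre_h)
    g[[paste0(pre, "bf1")]] <- colSums(dpre_h)
    dXn2 <- tcrossprod(dpre_h, p[[paste0(pre, "Wf1")]])
    lb2 <- ln_backward(dXn2, lc$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_b")]] <- lb2$db
    dX <- dX + lb2$dx

    # attention sublayer: X_after_attn = X_in + dropout(attn_out)
    dattn <- dX
    if (!is.null(lc$dm1)) dattn <- dattn * lc$dm1
    g[[paste0(pre, "Wo")]] <- crossprod(lc$O, dattn)
    g[[paste0(pre, "bo")]] <- colSums(dattn)
    dO <- tcrossprod(dattn, p[[paste0(pre, "Wo")]])
    dQKV <- matrix(0, B * Tn, 3L * D)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- cache$layers[[l]]$P[, , b, h]
        Qh <- lc$QKV[rows, cols, drop = FALSE]
        Kh <- lc$QKV[rows, D + cols, drop = FALSE]
        Vh <- lc$QKV[rows, 2L * D + cols, drop = FALSE]
        dOh <- dO[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dVh <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dQh <- dS %*% Kh / sqrt(dh)
        dKh <- crossprod(dS, Qh) / sqrt(dh)
        dQKV[rows, cols] <- dQh
        dQKV[rows, D + cols] <- dKh
        dQKV[rows, 2L * D + cols] <- dVh
      }
    }
    g[[paste0(pre, "Wqkv")]] <- crossprod(lc$ln1$y, dQKV)
    g[[paste0(pre, "bqkv")]] <- colSums(dQKV)
    dXn1 <- tcrossprod(dQKV, p[[paste0(pre, "Wqkv")]])
    lb1 <- ln_backward(dXn1, lc$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_b")]] <- lb1$db
    dX <- dX + lb1$dx
  }

  # positional embeddings and sequence disassembly
  g$pos <- rowsum(dX, rep(seq_len(Tn), B))
  dimnames(g$pos) <- NULL
  if (Tn < nrow(p$pos)) {
    pad <- matrix(0, nrow(p$pos) - Tn, D)
    g$pos <- rbind(g$pos, pad)
  }
  g$cls <- colSums(dX[cache$idx_cls, , drop = FALSE])
  dXfus <- dX[cache$idx_fus, , drop = FALSE]
  dXp <- dX[cache$idx_patch, , drop = FALSE]

  if (cache$use_meta) {
    idx_meta1 <- cache$idx_cls + 2L + Np
    if (cfg$metadata_tokens == 2L) {
      dage <- dX[idx_meta1, , drop = FALSE]
      dsex <- dX[idx_meta1 + 1L, , drop = FALSE]
      g$W_age <- matrix(colSums(dage * cache$age_n), 1)
      g$b_age <- colSums(dage)
      g$W_sex <- matrix(colSums(dsex * cache$sex01), 1)
      g$b_sex <- colSums(dsex)
    } else {
      dmeta <- dX[idx_meta1, , drop = FALSE]
      g$W_meta <- crossprod(cbind(cache$age_n, cache$sex01), dmeta)
      g$b_meta <- colSums(dmeta)
    }
  } else if (cfg$metadata_tokens == 2L) {
    g$W_age <- matrix(0, 1, D); g$b_age <- numeric(D)
    g$W_sex <- matrix(0, 1, D); g$b_sex <- numeric(D)
  } else if (cfg$metadata_tokens == 1L) {
    g$W_meta <- matrix(0, 2, D); g$b_meta <- numeric(D)
  }

  # fusion layer norm and FFN
  flb <- ln_backward(dXfus, cache$fus_ln, p$fus_g)
  g$fus_g <- flb$dg
  g$fus_b <- flb$db
  dXs <- flb$dx          # residual into the feature token
  dffn_z <- flb$dx
  g$Ff2 <- crossprod(cache$H_z, dffn_z)
  g$fb2 <- colSums(dffn_z)
  dH_z <- tcrossprod(dffn_z, p$Ff2)
  dpre_z <- dH_z * gelu_grad_cached(cache$pre_z, cache$th_z)
  g$Ff1 <- crossprod(cache$Z, dpre_z)
  g$fb1 <- colSums(dpre_z)
  dZ <- tcrossprod(dpre_z, p$Ff1)

  # Z = sum_j A_j V_j per record
  grp <- cache$grp
  Avec <- as.vector(cache$Amat)
  dZexp <- dZ[grp, , drop = FALSE]
  dV <- dZexp * Avec
  dAvec <- rowSums(cache$V * dZexp)
  dAmat <- matrix(dAvec, Np, B)
  # softmax backward per record (columns of Amat)
  dSmat <- cache$Amat * sweep(dAmat, 2, colSums(dAmat * cache$Amat))
  dSvec <- as.vector(dSmat) / sqrt(D)
  dK <- dSvec * cache$Q[grp, , drop = FALSE]
  dQ <- rowsum(dSvec * cache$K, grp)
  g$Wq <- crossprod(cache$Xs, dQ)
  g$Wk <- crossprod(cache$Xp, dK)
  g$Wv <- crossprod(cache$Xp, dV)
  dXs <- dXs + tcrossprod(dQ, p$Wq)
  dXp <- dXp + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)

  # feature embedding
  g$W_feat2 <- crossprod(cache$H_f, dXs)
  g$b_feat2 <- colSums(dXs)
  dH_f <- tcrossprod(dXs, p$W_feat2)
  dpre_f <- dH_f * gelu_grad_cached(cache$pre_f, cache$th_f)
  g$W_feat1 <- crossprod(cache$Xin_f, dpre_f)
  g$b_feat1 <- colSums(dpre_f)

  # patch embedding
  g$W_patch <- crossprod(cache$P_in, dXp)
  g$b_patch <- colSums(dXp)

  g[names(model$params)]
}
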