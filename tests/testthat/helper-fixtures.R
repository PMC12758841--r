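# Shared fixtures, all generated in code at test time.

# Small cohort with short records: fast to render and to push through the
# model at reduced scale (20 patches of 50 samples).
tiny_cohort <- function(n = 40, seed = 11, record_len = 1000,
                        missingness_rate = 0.1) {
  generate_cohort(cohort_config(
    n_records = n, seed = seed, record_len = record_len,
    missingness_rate = missingness_rate))
}

# Reduced model configuration matching tiny_cohort record length.
tiny_model_config <- function(n_labels = 13, metadata_tokens = 2,
                              dropout = 0, n_layers = 2, n_heads = 2,
                              embed_dim = 32) {
  model_config(embed_dim = embed_dim, patch_len = 50, n_patches = 20,
               n_layers = n_layers, n_heads = n_heads,
               n_labels = n_labels, metadata_tokens = metadata_tokens,
               dropout = dropout)
}

# A single preprocessed record ready for forward().
tiny_record <- function(prep, i = 1, cohort, target_len = 1000) {
  list(
    waveform = zscore_leads(fix_length(cohort$waveforms[[i]], target_len)),
    features = prep$features[i, ],
    mask = prep$mask[i, ],
    age_n = prep$age_n[i],
    sex01 = prep$sex01[i]
  )
}

# Random batch of raw model inputs (no cohort needed).
random_batch <- function(B, cfg, seed = 1) {
  set.seed(seed)
  list(
    P = matrix(stats::rnorm(B * cfg$n_patches * cfg$n_leads *
                              cfg$patch_len),
               B * cfg$n_patches, cfg$n_leads * cfg$patch_len),
    feat = matrix(stats::rnorm(B * cfg$n_features), B, cfg$n_features),
    mask = matrix(stats::rbinom(B * cfg$n_features, 1, 0.8), B,
                  cfg$n_features),
    age_n = stats::rnorm(B),
    sex01 = stats::rbinom(B, 1, 0.5),
    labels = matrix(stats::rbinom(B * cfg$n_labels, 1, 0.3), B,
                    cfg$n_labels),
    B = B
  )
}

# Brute-force AUC oracle: explicit pairwise comparison.
brute_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) +
        0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# Brute-force average precision oracle: walk distinct thresholds.
brute_ap <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
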