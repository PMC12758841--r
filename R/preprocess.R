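#' Fix waveform length by truncation or zero-padding
#'
#' Non-finite samples are replaced by zero first; records longer than
#' `target_len` are truncated at the end, shorter ones zero-padded at the
#' end. No sampling-rate conversion is performed.
#'
#' @param waveform Numeric matrix with 12 lead rows.
#' @param target_len Target samples per lead (default 5000).
#' @return 12 x `target_len` matrix.
#' @export
fix_length <- function(waveform, target_len = 5000) {
  if (!is.matrix(waveform) || nrow(waveform) != 12) {
    stop("waveform must be a matrix with 12 lead rows, got ",
         if (is.matrix(waveform)) nrow(waveform) else "non-matrix")
  }
  waveform[!is.finite(waveform)] <- 0
  len <- ncol(waveform)
  if (len >= target_len) {
    out <- waveform[, seq_len(target_len), drop = FALSE]
  } else {
    out <- cbind(waveform,
                 matrix(0, 12, target_len - len))
  }
  rownames(out) <- rownames(waveform)
  out
}

#' Per-lead z-score normalization
#'
#' Each lead is independently centred and scaled to mean 0, population
#' (1/N) SD 1. A constant lead maps to all zeros.
#'
#' @param waveform 12 x L numeric matrix.
#' @return Matrix of the same shape.
#' @export
zscore_leads <- function(waveform) {
  mu <- rowMeans(waveform)
  centred <- waveform - mu
  sd_pop <- sqrt(rowMeans(centred^2))
  sd_pop[sd_pop < 1e-12] <- Inf  # constant lead -> all zeros
  centred / sd_pop
}

#' Fit feature and age statistics on the training split
#'
#' Per-feature mean and population SD over valid (mask = 1) entries only,
#' plus age normalization constants, tagged with the split they were fit
#' on so leakage is detectable downstream. A zero-SD feature gets SD 1;
#' a feature with no valid entries gets mean 0 / SD 1 with a warning.
#'
#' @param features n x 9 numeric matrix (may contain NA at masked entries).
#' @param mask n x 9 binary validity mask.
#' @param ages Numeric vector of training ages (years).
#' @param split_id Identifier of the split the stats are fit on.
#' @return Object of class `train_stats`.
#' @export
fit_feature_stats <- function(features, mask, ages, split_id = "train") {
  stopifnot(is.matrix(features), is.matrix(mask),
            all(dim(features) == dim(mask)), nrow(features) >= 1)
  k <- ncol(features)
  mean_f <- numeric(k)
  sd_f <- numeric(k)
  for (j in seq_len(k)) {
    v <- features[mask[, j] == 1, j]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      warning("feature ", j, " has no valid training entries; ",
              "using mean 0 / SD 1")
      mean_f[j] <- 0
      sd_f[j] <- 1
    } else {
      mean_f[j] <- mean(v)
      s <- sqrt(mean((v - mean_f[j])^2))
      sd_f[j] <- if (s < 1e-12) 1 else s
    }
  }
  names(mean_f) <- names(sd_f) <- colnames(features)
  age_mean <- mean(ages)
  age_sd <- sqrt(mean((ages - age_mean)^2))
  if (age_sd < 1e-12) age_sd <- 1
  structure(
    list(mean = mean_f, sd = sd_f,
         age_mean = age_mean, age_sd = age_sd,
         split_id = split_id, n = nrow(features)),
    class = "train_stats"
  )
}

#' Standardize structured features
#'
#' Valid entries map to `(x - mean) / sd` using train-fit stats; missing
#' entries are imputed with zero and keep mask bit 0. Output is always the
#' 9 standardized values plus the 9 mask bits.
#'
#' @param features Numeric vector (9) or matrix (n x 9).
#' @param mask Matching binary validity mask.
#' @param stats A [fit_feature_stats()] result.
#' @return List with `values` and `mask`, same shape as the input.
#' @export
standardize_features <- function(features, mask, stats) {
  stopifnot(inherits(stats, "train_stats"))
  vec <- !is.matrix(features)
  if (vec) {
    features <- matrix(features, 1)
    mask <- matrix(mask, 1)
  }
  z <- sweep(sweep(features, 2, stats$mean), 2, stats$sd, "/")
  z[mask == 0] <- 0
  z[!is.finite(z)] <- 0
  if (vec) {
    z <- drop(z)
    mask <- drop(mask)
    names(z) <- names(stats$mean)
  }
  list(values = z, mask = mask)
}

#' Invert feature standardization
#'
#' Recovers the original scale of valid entries (`x = z * sd + mean`).
#' Masked entries stay zero.
#'
#' @inheritParams standardize_features
#' @param values Standardized values.
#' @return Numeric of the same shape as `values`.
#' @export
unstandardize_features <- function(values, mask, stats) {
  stopifnot(inherits(stats, "train_stats"))
  vec <- !is.matrix(values)
  if (vec) {
    values <- matrix(values, 1)
    mask <- matrix(mask, 1)
  }
  x <- sweep(sweep(values, 2, stats$sd, "*"), 2, stats$mean, "+")
  x[mask == 0] <- 0
  if (vec) x <- drop(x)
  x
}

#' Normalize age
#'
#' Z-scores age against the training-cohort age statistics stored in
#' `stats`, keeping the demographic channel on the same scale as the
#' standardized features.
#'
#' @param age Age(s) in years, >= 0.
#' @param stats A [fit_feature_stats()] result.
#' @return Normalized age(s).
#' @export
normalize_age <- function(age, stats) {
  stopifnot(inherits(stats, "train_stats"))
  if (any(age < 0)) stop("age must be non-negative")
  (age - stats$age_mean) / stats$age_sd
}

#' Chronological development / temporal-test split
#'
#' Reserves the most recent `ceiling(temporal_frac * n)` records (by
#' timestamp, ties broken by record id) as a temporally separated test
#' cohort; the rest form the development set.
#'
#' @param cohort An `ecg_cohort` (or any list with `ids` and `timestamps`).
#' @param temporal_frac Fraction reserved for the temporal test (default
#'   0.10).
#' @return List with character vectors `development` and `temporal_test`.
#' @export
chronological_split <- function(cohort, temporal_frac = 0.10) {
  ids <- cohort$ids
  ts <- cohort$timestamps
  stopifnot(length(ids) == length(ts), length(ids) >= 2)
  ord <- order(ts, ids)
  n <- length(ids)
  n_temp <- ceiling(temporal_frac * n)
  dev <- ids[ord[seq_len(n - n_temp)]]
  temp <- ids[ord[seq(n - n_temp + 1, n)]]
  list(development = dev, temporal_test = temp)
}

#' Random 7:1:1 split of the development set
#'
#' Seeded shuffle of the development ids into train / validation /
#' internal-test at 7/9 : 1/9 : 1/9 (validation and test sizes rounded to
#' nearest; the remainder goes to train). Combined with
#' [chronological_split()] this yields the full four-way split.
#'
#' @param development_ids Character vector of development record ids.
#' @param seed Integer seed for the shuffle.
#' @param temporal_test_ids Optional temporal-test ids carried into the
#'   returned spec.
#' @return Object of class `split_spec` with `train`, `validation`, `test`
#'   and `temporal_test` id vectors and the seed used.
#' @export
random_split_711 <- function(development_ids, seed = 1L,
                             temporal_test_ids = character(0)) {
  n <- length(development_ids)
  stopifnot(n >= 3)
  set.seed(seed)
  shuffled <- sample(development_ids)
  n_val <- round(n / 9)
  n_test <- round(n / 9)
  n_train <- n - n_val - n_test
  structure(
    list(train = sort(shuffled[seq_len(n_train)]),
         validation = sort(shuffled[seq(n_train + 1, n_train + n_val)]),
         test = sort(shuffled[seq(n_train + n_val + 1, n)]),
         temporal_test = temporal_test_ids,
         seed = as.integer(seed)),
    class = "split_spec"
  )
}

#' Split a cohort into the four standard subsets
#'
#' Convenience wrapper: chronological 90/10 split, then a seeded 7:1:1
#' random split of the development portion.
#'
#' @param cohort An `ecg_cohort`.
#' @param seed Seed for the random development split.
#' @param temporal_frac Fraction for the temporal test cohort.
#' @return A `split_spec`.
#' @export
split_cohort <- function(cohort, seed = 1L, temporal_frac = 0.10) {
  chron <- chronological_split(cohort, temporal_frac)
  random_split_711(chron$development, seed = seed,
                   temporal_test_ids = chron$temporal_test)
}

#' Preprocess a cohort for the model
#'
#' Applies the full deterministic input pipeline: per-record length fixing
#' and per-lead z-scoring of waveforms, train-split-only feature/age
#' statistics, feature standardization with zero imputation and validity
#' masks, age normalization and binary sex coding (M = 1, F = 0).
#' Waveforms are stored as patch-ready matrices (one row per patch,
#' lead-interleaved samples) to feed the patch embedding directly.
#'
#' @param cohort An `ecg_cohort`.
#' @param split A `split_spec` from [split_cohort()].
#' @param patch_len Patch length in samples used for the patch matrices.
#' @param target_len Fixed record length.
#' @return List with `patches` (list of Np x (12*patch_len) matrices),
#'   `features`, `mask`, `age_n`, `sex01`, `labels`, `ids`, `stats`
#'   and `split`.
#' @export
preprocess_cohort <- function(cohort, split, patch_len = 50,
                              target_len = 5000) {
  stopifnot(inherits(split, "split_spec"))
  idx_train <- match(split$train, cohort$ids)
  stats <- fit_feature_stats(cohort$features[idx_train, , drop = FALSE],
                             cohort$mask[idx_train, , drop = FALSE],
                             cohort$ages[idx_train])
  sf <- standardize_features(cohort$features, cohort$mask, stats)
  n <- length(cohort$ids)
  np <- target_len %/% patch_len
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    wf <- zscore_leads(fix_length(cohort$waveforms[[i]], target_len))
    patches[[i]] <- waveform_to_patches(wf, patch_len)
  }
  list(patches = patches,
       features = sf$values, mask = sf$mask,
       age_n = normalize_age(cohort$ages, stats),
       sex01 = as.integer(cohort$sexes == "M"),
       labels = cohort$labels,
       ids = cohort$ids,
       n_patches = np,
       patch_len = patch_len,
       stats = stats,
       split = split)
}

#' Reshape a fixed-length waveform into patch rows
#'
#' Row i holds the lead-interleaved samples of the i-th non-overlapping
#' `patch_len`-sample window (all 12 leads), the input layout expected by
#' the patch embedding.
#'
#' @param waveform 12 x L matrix, L divisible by `patch_len`.
#' @param patch_len Samples per patch.
#' @return (L / patch_len) x (12 * patch_len) matrix.
#' @export
waveform_to_patches <- function(waveform, patch_len = 50) {
  L <- ncol(waveform)
  if (L %% patch_len != 0) {
    stop("record length ", L, " is not divisible by patch_len ", patch_len)
  }
  np <- L %/% patch_len
  arr <- array(waveform, c(12, patch_len, np))
  t(matrix(arr, 12 * patch_len, np))
}
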