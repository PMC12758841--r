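#' Read a 12-lead waveform CSV
#'
#' Parses a waveform file with rows = samples and columns = the 12
#' canonical lead names (any column order; extra columns rejected).
#' Non-finite cells are replaced by zero with a logged count; lengths
#' other than 5000 are handled downstream by [fix_length()].
#'
#' @param path CSV file path.
#' @return 12 x n_samples numeric matrix, rows in canonical lead order.
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty waveform file: ", path)
  missing_leads <- setdiff(ecg_leads(), names(df))
  if (length(missing_leads) > 0) {
    stop("waveform file is missing lead column(s): ",
         paste(missing_leads, collapse = ", "))
  }
  extra <- setdiff(names(df), ecg_leads())
  if (length(extra) > 0) {
    stop("unexpected column(s) in waveform file: ",
         paste(extra, collapse = ", "))
  }
  bad_col <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad_col) > 0) {
    stop("non-numeric values in lead column(s): ",
         paste(bad_col, collapse = ", "))
  }
  m <- t(as.matrix(df[, ecg_leads()]))
  n_bad <- sum(!is.finite(m))
  if (n_bad > 0) {
    message("replaced ", n_bad, " non-finite sample(s) with zero")
    m[!is.finite(m)] <- 0
  }
  rownames(m) <- ecg_leads()
  m
}

#' Write a 12-lead waveform CSV
#'
#' Inverse of [read_waveform_csv()]: rows = samples, columns = canonical
#' lead names.
#'
#' @param waveform 12 x n matrix.
#' @param path Output path.
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(is.matrix(waveform), nrow(waveform) == 12)
  df <- as.data.frame(t(waveform))
  names(df) <- ecg_leads()
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort bundle to disk
#'
#' One waveform CSV per record, a cohort table CSV (id, timestamp, age,
#' sex, 9 features, 9 mask bits, 13 label bits) and a key-value manifest
#' recording the generating configuration and seed.
#'
#' @param cohort An `ecg_cohort`.
#' @param dir Output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wf_dir <- file.path(dir, "waveforms")
  dir.create(wf_dir, showWarnings = FALSE)
  for (i in seq_along(cohort$ids)) {
    write_waveform_csv(cohort$waveforms[[i]],
                       file.path(wf_dir, paste0(cohort$ids[i], ".csv")))
  }
  feat <- cohort$features
  feat[is.na(feat)] <- 0
  tab <- data.frame(id = cohort$ids, timestamp = cohort$timestamps,
                    age = cohort$ages, sex = cohort$sexes,
                    check.names = FALSE)
  colnames(feat) <- feature_schema()
  maskdf <- as.data.frame(cohort$mask)
  names(maskdf) <- paste0("mask_", feature_schema())
  labdf <- as.data.frame(cohort$labels)
  names(labdf) <- paste0("label_", seq_len(13))
  tab <- cbind(tab, as.data.frame(feat), maskdf, labdf)
  utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  cfg <- cohort$config
  manifest <- c(
    n_records = cfg$n_records, seed = cfg$seed,
    sampling_rate = cfg$sampling_rate, record_len = cfg$record_len,
    age_mean = cfg$age_mean, age_sd = cfg$age_sd,
    male_fraction = cfg$male_fraction,
    missingness_rate = cfg$missingness_rate, noise_sd = cfg$noise_sd,
    stats::setNames(cfg$prevalence,
                    paste0("prevalence_", seq_len(13)))
  )
  writeLines(paste0(names(manifest), "=", manifest),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a cohort bundle from disk
#'
#' Reconstructs an `ecg_cohort` written by [write_cohort()] (waveform
#' CSVs, cohort table and manifest). Per-record generator metadata
#' (ground-truth beat parameters) is not round-tripped.
#'
#' @param dir Bundle directory.
#' @return An `ecg_cohort`.
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "cohort.csv"),
                         check.names = FALSE)
  man <- read_config_file(file.path(dir, "manifest.txt"),
                          known_keys = NULL)
  feat <- as.matrix(tab[, feature_schema()])
  mask <- as.matrix(tab[, paste0("mask_", feature_schema())])
  colnames(mask) <- feature_schema()
  feat[mask == 0] <- NA_real_
  labels <- as.matrix(tab[, paste0("label_", seq_len(13))])
  colnames(labels) <- cvd_labels()
  waveforms <- lapply(tab$id, function(id) {
    read_waveform_csv(file.path(dir, "waveforms", paste0(id, ".csv")))
  })
  cfg <- cohort_config(
    n_records = nrow(tab),
    age_mean = man$age_mean, age_sd = man$age_sd,
    male_fraction = man$male_fraction,
    missingness_rate = man$missingness_rate,
    seed = man$seed, sampling_rate = man$sampling_rate,
    record_len = man$record_len, noise_sd = man$noise_sd
  )
  structure(
    list(ids = tab$id, timestamps = tab$timestamp, ages = tab$age,
         sexes = tab$sex, labels = labels * 1L, features = feat,
         mask = mask * 1L, waveforms = waveforms,
         meta = vector("list", nrow(tab)), config = cfg),
    class = "ecg_cohort"
  )
}

#' Save a self-describing checkpoint
#'
#' Serializes the weights together with the model configuration, the
#' train-split statistics and the canonical label list, so inference
#' needs nothing but the checkpoint file. A version field guards format
#' drift.
#'
#' @param model A `fusion_model`.
#' @param path Output path (.rds).
#' @param train_stats The [fit_feature_stats()] object used in training.
#' @param extra Optional named list stored alongside (e.g. history,
#'   calibration).
#' @export
save_checkpoint <- function(model, path, train_stats = NULL,
                            extra = list()) {
  obj <- c(list(version = "ecgfusion-checkpoint-1",
                config = model$config, params = model$params,
                train_stats = train_stats, labels = cvd_labels()),
           extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint
#'
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return List with `model`, `train_stats`, `labels` and any extras.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$version, "ecgfusion-checkpoint-1")) {
    stop("unrecognised checkpoint version: ", obj$version)
  }
  model <- structure(list(params = obj$params, config = obj$config),
                     class = "fusion_model")
  c(list(model = model), obj[setdiff(names(obj),
                                     c("version", "config", "params"))])
}

#' Read a key-value configuration file
#'
#' Plain `key=value` lines; blank lines and `#` comments ignored. Values
#' are coerced to numeric where possible. When `known_keys` is given,
#' unknown keys are rejected.
#'
#' @param path File path.
#' @param known_keys Character vector of permitted keys, or NULL to
#'   accept any.
#' @return Named list.
#' @export
read_config_file <- function(path, known_keys = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="),
                 character(1))
  if (!is.null(known_keys)) {
    unknown <- setdiff(keys, known_keys)
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
  }
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}
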