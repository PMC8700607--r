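# File formats: wide chromatogram CSV (time axis + one intensity column per
# injection, one file per channel), injection-sequence metadata CSV, and a
# YAML run configuration. Errors carry condition classes so callers can
# distinguish grid, id and metadata problems.

chromauth_error <- function(code, msg) {
  stop(structure(class = c(paste0("chromauth_error_", code),
                           "chromauth_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Write one channel's chromatogram set as a wide CSV
#'
#' Column 1 is `time_min`; every further column is one injection, named by
#' its sample id, ordered by injection index. Intensities are written with 9
#' significant digits.
#'
#' @param x A [fingerprint_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromatogram_set <- function(x, path) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  df <- data.frame(time_min = formatC(x$time_min, digits = 9, format = "g"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  mat <- t(x$intensity)
  for (j in seq_len(ncol(mat))) {
    df[[x$metadata$sample_id[j]]] <- formatC(mat[, j], digits = 9,
                                             format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the injection-sequence metadata CSV
#'
#' @param metadata Data frame with `sample_id`, `class_label`,
#'   `injection_index`, `role`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequence_metadata <- function(metadata, path) {
  utils::write.csv(metadata[, c("sample_id", "class_label",
                                "injection_index", "role")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chromatogram set plus its metadata
#'
#' Restores a [fingerprint_matrix()] from the wide CSV dialect, ordering
#' rows by injection index regardless of the CSV column order and enforcing
#' grid and id consistency.
#'
#' @param path Chromatogram CSV ([write_chromatogram_set()] dialect).
#' @param metadata_path Metadata CSV ([write_sequence_metadata()] dialect).
#' @param channel Detection channel of the file.
#' @return A [fingerprint_matrix()].
#' @export
read_chromatogram_set <- function(path, metadata_path,
                                  channel = c("uv", "fld")) {
  channel <- match.arg(channel)
  if (!file.exists(path) || !file.exists(metadata_path)) {
    chromauth_error("missing_file", "input file does not exist")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_min") {
    chromauth_error("schema", "first column must be time_min")
  }
  time_min <- df$time_min
  steps <- diff(time_min)
  if (any(steps <= 0) || diff(range(steps)) > 1e-6 * max(steps)) {
    chromauth_error("grid", "time_min is not a uniform increasing grid")
  }
  ids <- names(df)[-1]
  if (anyDuplicated(ids)) {
    chromauth_error("duplicate_id", "duplicate sample ids in chromatogram file")
  }
  meta <- utils::read.csv(metadata_path, colClasses = c(
    sample_id = "character", class_label = "character",
    injection_index = "integer", role = "character"), na.strings = NULL)
  if (anyDuplicated(meta$injection_index)) {
    chromauth_error("duplicate_id", "duplicate injection_index in metadata")
  }
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing)) {
    chromauth_error("missing_metadata",
                    paste("missing metadata for:",
                          paste(missing, collapse = ", ")))
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  fingerprint_matrix(mat, time_min, meta, channel)
}

#' Write a generated dataset to a directory
#'
#' Emits `uv.csv`, `fld.csv`, `metadata.csv` and `truth.csv`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "chrom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_chromatogram_set(dataset$uv, file.path(dir, "uv.csv"))
  write_chromatogram_set(dataset$fld, file.path(dir, "fld.csv"))
  write_sequence_metadata(dataset$uv$metadata, file.path(dir, "metadata.csv"))
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `seed`, `class_counts`, `grid` (`t_max`, `step`),
#' `drift` (`slope`, `walk_sd`), `amp_cv`, `rt_jitter_sd`, `noise_frac`,
#' `baseline_frac`, `qc_every`, `preprocess` (any [preprocess_config()]
#' argument), `cv` (`n_splits`, `max_lv`, `rel_tol`). Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return List with `config` ([run_config()]), `preprocess`
#'   ([preprocess_config()]), `cv` settings and `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "class_counts", "grid", "drift", "amp_cv",
             "rt_jitter_sd", "noise_frac", "baseline_frac", "qc_every",
             "preprocess", "cv")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    chromauth_error("schema", paste("unknown configuration keys:",
                                    paste(unknown, collapse = ", ")))
  }
  grid <- if (!is.null(raw$grid)) {
    do.call(default_grid, raw$grid)
  } else {
    default_grid()
  }
  drift <- if (!is.null(raw$drift)) {
    do.call(drift_model, raw$drift)
  } else {
    drift_model()
  }
  args <- list(grid = grid, drift = drift)
  for (key in c("amp_cv", "rt_jitter_sd", "noise_frac", "baseline_frac",
                "qc_every")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$class_counts)) {
    args$class_counts <- unlist(raw$class_counts)
  }
  pre <- do.call(preprocess_config,
                 if (is.null(raw$preprocess)) list() else raw$preprocess)
  cv <- utils::modifyList(list(n_splits = 10L, max_lv = 8L, rel_tol = 0.02),
                          if (is.null(raw$cv)) list() else raw$cv)
  list(config = do.call(run_config, args), preprocess = pre, cv = cv,
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}
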