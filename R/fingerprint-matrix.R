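#' Chromatogram of one injection
#'
#' @param time_min Retention-time grid (minutes, uniform step, increasing).
#' @param intensity Intensity trace, same length as `time_min`.
#' @param channel Detection channel, `"uv"` or `"fld"`.
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(time_min, intensity, channel = c("uv", "fld")) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(time_min), is.numeric(intensity),
            length(time_min) == length(intensity))
  steps <- diff(time_min)
  if (length(steps) && (any(steps <= 0) ||
                        diff(range(steps)) > 1e-9 * max(steps))) {
    stop("time_min must be a uniform increasing grid", call. = FALSE)
  }
  structure(list(time_min = time_min, intensity = as.numeric(intensity),
                 channel = channel),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> channel=%s, %d points, %.2f-%.2f min, max=%.4g\n",
              x$channel, length(x$time_min), min(x$time_min),
              max(x$time_min), max(x$intensity)))
  invisible(x)
}

#' Fingerprint matrix
#'
#' The central data container: one row per injection (intensity trace on a
#' shared retention-time grid) plus injection metadata aligned row-by-row.
#'
#' @param intensity Numeric matrix, injections x time points.
#' @param time_min Shared retention-time grid (length = `ncol(intensity)`).
#' @param metadata Data frame with columns `sample_id`, `class_label`,
#'   `injection_index` (1-based), `role` (`sample`, `qc` or `blank`), one row
#'   per matrix row, ordered by `injection_index`.
#' @param channel Detection channel of the traces.
#' @return A `fingerprint_matrix` object.
#' @export
fingerprint_matrix <- function(intensity, time_min, metadata,
                               channel = c("uv", "fld")) {
  channel <- match.arg(channel)
  intensity <- as.matrix(intensity)
  stopifnot(ncol(intensity) == length(time_min),
            nrow(intensity) == nrow(metadata))
  required <- c("sample_id", "class_label", "injection_index", "role")
  if (!all(required %in% names(metadata))) {
    stop("metadata must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(metadata$injection_index)) {
    stop("injection_index values must be unique", call. = FALSE)
  }
  if (nrow(metadata) && is.unsorted(metadata$injection_index)) {
    ord <- order(metadata$injection_index)
    metadata <- metadata[ord, , drop = FALSE]
    intensity <- intensity[ord, , drop = FALSE]
  }
  if (!all(metadata$role %in% c("sample", "qc", "blank"))) {
    stop("role must be one of sample, qc, blank", call. = FALSE)
  }
  rownames(intensity) <- metadata$sample_id
  rownames(metadata) <- NULL
  structure(list(intensity = intensity, time_min = time_min,
                 metadata = metadata, channel = channel),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  roles <- table(x$metadata$role)
  cat(sprintf("<fingerprint_matrix> channel=%s, %d injections x %d points (%s)\n",
              x$channel, nrow(x$intensity), ncol(x$intensity),
              paste(sprintf("%s=%d", names(roles), roles), collapse = ", ")))
  invisible(x)
}

#' Subset a fingerprint matrix by row
#'
#' @param x A [fingerprint_matrix()].
#' @param i Row indices or logical mask over injections.
#' @return A `fingerprint_matrix` with the selected injections.
#' @export
fpm_subset <- function(x, i) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  fingerprint_matrix(x$intensity[i, , drop = FALSE], x$time_min,
                     x$metadata[i, , drop = FALSE], x$channel)
}

#' Extract one injection as a chromatogram
#'
#' @param x A [fingerprint_matrix()].
#' @param i Single row index or sample id.
#' @return A [chromatogram()].
#' @export
fpm_trace <- function(x, i) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  if (is.character(i)) i <- match(i, x$metadata$sample_id)
  chromatogram(x$time_min, x$intensity[i, ], x$channel)
}
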