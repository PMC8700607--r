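# Fingerprint pretreatment chain, applied in fixed order:
# smoothing -> baseline correction -> alignment -> (optional) nearest-QC
# division -> autoscaling. Autoscaling is exposed separately so model code
# can restrict it to calibration rows (no leakage into prediction sets).

#' Preprocessing configuration
#'
#' @param smooth_window Savitzky-Golay window (odd, points; default 11).
#' @param smooth_polyorder Savitzky-Golay polynomial order (default 3, must
#'   be `< smooth_window`).
#' @param baseline_lambda Asymmetric-least-squares smoothness penalty
#'   (default 1e5).
#' @param baseline_p Asymmetry weight in (0, 1) (default 0.01).
#' @param align_segments Number of alignment segments (default 10).
#' @param align_max_shift Maximum integer shift per segment, in points
#'   (default 5, i.e. 0.05 min on the default grid). The bound should cover
#'   the injection-to-injection retention variation (a few grid points) but
#'   stay below the distance between neighbouring peaks of different
#'   compounds: with a generous bound, a segment holding a single
#'   class-specific peak gets pulled onto the nearest feature of the pooled
#'   reference, relocating distinct compounds onto each other.
#' @param align_min_signal Fraction of the reference trace's overall
#'   standard deviation below which a segment is considered signal-free and
#'   left unshifted (default 0.01). Shifting noise-only segments would inject
#'   arbitrary lags driven entirely by the noise realization.
#' @param qc_epsilon_frac Fraction of each QC-trace maximum used as the
#'   division floor (default 0.05). The floor must exceed the most negative
#'   post-correction excursion of a QC trace (white noise plus baseline
#'   undershoot, a few percent of the trace maximum); a floor below that
#'   level lets denominators cross zero and the ratio features degenerate
#'   into heavy-tailed noise.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(smooth_window = 11L, smooth_polyorder = 3L,
                              baseline_lambda = 1e5, baseline_p = 0.01,
                              align_segments = 10L, align_max_shift = 5L,
                              align_min_signal = 0.01,
                              qc_epsilon_frac = 0.05) {
  if (smooth_window %% 2L == 0L) {
    stop("smooth_window must be odd", call. = FALSE)
  }
  if (smooth_polyorder >= smooth_window) {
    stop("smooth_polyorder must be < smooth_window", call. = FALSE)
  }
  if (baseline_p <= 0 || baseline_p >= 1) {
    stop("baseline_p must lie strictly in (0, 1)", call. = FALSE)
  }
  if (align_max_shift < 0) {
    stop("align_max_shift must be >= 0", call. = FALSE)
  }
  structure(list(smooth_window = as.integer(smooth_window),
                 smooth_polyorder = as.integer(smooth_polyorder),
                 baseline_lambda = baseline_lambda, baseline_p = baseline_p,
                 align_segments = as.integer(align_segments),
                 align_max_shift = as.integer(align_max_shift),
                 align_min_signal = align_min_signal,
                 qc_epsilon_frac = qc_epsilon_frac),
            class = "preprocess_config")
}

#' Savitzky-Golay smoothing of one trace
#'
#' Local polynomial smoothing; length preserved, polynomials up to the filter
#' order reproduced exactly.
#'
#' @param trace Numeric intensity trace.
#' @param config A [preprocess_config()].
#' @return Smoothed trace of the same length.
#' @export
smooth_trace <- function(trace, config = preprocess_config()) {
  if (config$smooth_window %% 2L == 0L) {
    stop("smooth_window must be odd", call. = FALSE)
  }
  if (config$smooth_window > length(trace)) {
    stop("smooth_window exceeds trace length", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(trace, p = config$smooth_polyorder,
                                n = config$smooth_window))
}

# Cached penta-diagonal penalty matrix t(D2) %*% D2 for a trace length.
asls_penalty <- local({
  cache <- new.env(parent = emptyenv())
  function(n, lambda) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      d2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                               diagonals = list(rep(1, n - 2L),
                                                rep(-2, n - 2L),
                                                rep(1, n - 2L)))
      cache[[key]] <- Matrix::crossprod(d2)
    }
    lambda * cache[[key]]
  }
})

#' Asymmetric least squares baseline estimation
#'
#' Estimates a smooth baseline `z` minimizing
#' `sum(w * (x - z)^2) + lambda * sum(diff(z, 2)^2)` with asymmetric weights
#' (`p` above the baseline, `1 - p` below), the standard whole-fingerprint
#' baseline model for chromatograms: peaks sit above the baseline, so
#' positive residuals are down-weighted.
#'
#' @param trace Numeric trace (length >= 10, finite).
#' @param config A [preprocess_config()].
#' @param max_iter Weight-update iterations (default 10).
#' @return List with `corrected` (trace - baseline) and `baseline`;
#'   `corrected + baseline` reconstructs the input exactly.
#' @export
baseline_correct <- function(trace, config = preprocess_config(),
                             max_iter = 10L) {
  if (length(trace) < 10L) {
    stop("trace too short for baseline estimation", call. = FALSE)
  }
  if (!all(is.finite(trace))) {
    stop("trace contains non-finite values", call. = FALSE)
  }
  n <- length(trace)
  pen <- asls_penalty(n, config$baseline_lambda)
  w <- rep(1, n)
  z <- trace
  for (it in seq_len(max_iter)) {
    lhs <- pen + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(lhs, w * trace))
    w_new <- ifelse(trace > z, config$baseline_p, 1 - config$baseline_p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  list(corrected = trace - z, baseline = z)
}

# Best integer lag (|lag| <= max_shift) aligning `segment` of `trace` to the
# reference segment, by cross-correlation; ties prefer the smallest |lag|.
best_lag <- function(trace, ref_seg, start, end, max_shift) {
  lags <- order(abs(seq(-max_shift, max_shift)))  # 0, -1, 1, -2, 2, ...
  lags <- seq(-max_shift, max_shift)[lags]
  n <- length(trace)
  best <- 0L
  best_score <- -Inf
  for (l in lags) {
    idx <- (start + l):(end + l)
    idx <- pmin(pmax(idx, 1L), n)  # edge padding with boundary values
    score <- sum(trace[idx] * ref_seg)
    if (score - best_score > 1e-12 * max(1, abs(score))) {
      best_score <- score
      best <- l
    }
  }
  best
}

#' Segmented integer-shift alignment of a fingerprint matrix
#'
#' Splits each trace into `align_segments` contiguous segments and shifts
#' each segment by the integer lag (up to `align_max_shift` points) that
#' maximizes its cross-correlation with the corresponding reference segment;
#' out-of-range positions are filled with the trace's boundary values.
#'
#' @param x A [fingerprint_matrix()] or plain matrix (rows = injections).
#' @param reference Reference trace (e.g. the mean QC fingerprint).
#' @param config A [preprocess_config()].
#' @return Object of the same type with aligned rows, plus a `"shifts"`
#'   attribute (injections x segments matrix of applied lags).
#' @export
align_traces <- function(x, reference, config = preprocess_config()) {
  mat <- if (inherits(x, "fingerprint_matrix")) x$intensity else as.matrix(x)
  n_pts <- ncol(mat)
  if (length(reference) != n_pts) {
    stop("reference length must match the trace grid", call. = FALSE)
  }
  if (all(reference == 0)) {
    stop("alignment reference must be non-zero", call. = FALSE)
  }
  bounds <- floor(seq(0, n_pts, length.out = config$align_segments + 1L))
  seg_len <- diff(bounds)
  if (config$align_max_shift >= min(seg_len)) {
    stop("align_max_shift must be smaller than the segment length",
         call. = FALSE)
  }
  shifts <- matrix(0L, nrow = nrow(mat), ncol = config$align_segments)
  out <- mat
  ref_sd <- stats::sd(reference)
  for (s in seq_len(config$align_segments)) {
    start <- bounds[s] + 1L
    end <- bounds[s + 1L]
    ref_seg <- reference[start:end]
    # signal-free segments: any lag preference would be pure noise
    if (stats::sd(ref_seg) < config$align_min_signal * ref_sd) next
    for (i in seq_len(nrow(mat))) {
      l <- best_lag(mat[i, ], ref_seg, start, end, config$align_max_shift)
      shifts[i, s] <- l
      if (l != 0L) {
        idx <- pmin(pmax((start + l):(end + l), 1L), n_pts)
        out[i, start:end] <- mat[i, idx]
      }
    }
  }
  res <- if (inherits(x, "fingerprint_matrix")) {
    fingerprint_matrix(out, x$time_min, x$metadata, x$channel)
  } else {
    out
  }
  attr(res, "shifts") <- shifts
  res
}

#' Nearest-QC division drift correction
#'
#' Divides every injection's trace point-wise by the trace of the QC nearest
#' in injection order (ties broken toward the preceding QC; a QC always opens
#' the sequence). Division uses `(x + eps) / (q + eps)` with
#' `eps = qc_epsilon_frac * max(q)` so near-zero baseline regions do not
#' explode. Every QC row becomes exactly all-ones, and multiplicative
#' sensitivity drift shared by a sample and its QC cancels.
#'
#' @param x A [fingerprint_matrix()] whose metadata carries roles and
#'   injection indices.
#' @param config A [preprocess_config()] (uses `qc_epsilon_frac`).
#' @return Corrected [fingerprint_matrix()].
#' @export
qc_correct <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  meta <- x$metadata
  qc_rows <- which(meta$role == "qc")
  if (length(qc_rows) == 0L) {
    stop("no QC injections in the sequence", call. = FALSE)
  }
  qc_idx <- meta$injection_index[qc_rows]
  out <- x$intensity
  for (i in seq_len(nrow(out))) {
    d <- abs(qc_idx - meta$injection_index[i])
    nearest <- which(d == min(d))
    if (length(nearest) > 1L) {  # tie: take the preceding QC
      nearest <- nearest[qc_idx[nearest] <= meta$injection_index[i]][1L]
    }
    q <- x$intensity[qc_rows[nearest], ]
    eps <- config$qc_epsilon_frac * max(q)
    out[i, ] <- (out[i, ] + eps) / (q + eps)
  }
  fingerprint_matrix(out, x$time_min, meta, x$channel)
}

#' Autoscale a data matrix
#'
#' Mean-centers every column and divides by its sample standard deviation so
#' all retention-time variables carry the same weight; columns with
#' (near-)zero variance are set to all-zeros. The returned means and s.d.s
#' are applied to prediction rows with [apply_autoscale()].
#'
#' @param x Numeric matrix (>= 2 rows) or [fingerprint_matrix()].
#' @return List with `scaled`, `center`, `scale` and the logical mask
#'   `constant` of degenerate columns.
#' @export
autoscale <- function(x) {
  mat <- if (inherits(x, "fingerprint_matrix")) x$intensity else as.matrix(x)
  if (nrow(mat) < 2L) {
    stop("autoscaling requires at least two rows", call. = FALSE)
  }
  ctr <- colMeans(mat)
  sds <- apply(mat, 2, stats::sd)
  constant <- sds < 1e-12
  scl <- ifelse(constant, 1, sds)
  scaled <- sweep(sweep(mat, 2, ctr), 2, scl, "/")
  scaled[, constant] <- 0
  list(scaled = scaled, center = ctr, scale = scl, constant = constant)
}

#' Apply stored autoscaling to new rows
#'
#' @param x New data matrix (same variables as the training set).
#' @param scaling The list returned by [autoscale()].
#' @return Scaled matrix.
#' @export
apply_autoscale <- function(x, scaling) {
  mat <- if (inherits(x, "fingerprint_matrix")) x$intensity else
    matrix(x, ncol = length(scaling$center))
  if (ncol(mat) != length(scaling$center)) {
    stop("variable count does not match the stored scaling", call. = FALSE)
  }
  scaled <- sweep(sweep(mat, 2, scaling$center), 2, scaling$scale, "/")
  scaled[, scaling$constant] <- 0
  scaled
}

#' Full fingerprint pretreatment chain
#'
#' Applies, in order: Savitzky-Golay smoothing, asymmetric-least-squares
#' baseline correction, segmented alignment against the mean (smoothed,
#' baseline-corrected) QC trace, and optionally the nearest-QC division.
#' Autoscaling is left to the modelling step so that prediction rows can be
#' scaled with calibration statistics only.
#'
#' @param x A [fingerprint_matrix()].
#' @param config A [preprocess_config()].
#' @param qc_divide Apply the nearest-QC division (default `TRUE` when QCs
#'   are present).
#' @param reference Optional alignment reference trace; default is the mean
#'   QC trace after smoothing/baseline correction (mean of all traces if the
#'   sequence holds no QC).
#' @return Preprocessed [fingerprint_matrix()] with a `"stages"` attribute
#'   logging each applied stage and its parameters.
#' @export
preprocess_fingerprints <- function(x, config = preprocess_config(),
                                    qc_divide = NULL, reference = NULL) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  mat <- x$intensity
  for (i in seq_len(nrow(mat))) {
    sm <- smooth_trace(mat[i, ], config)
    mat[i, ] <- baseline_correct(sm, config)$corrected
  }
  qc_rows <- which(x$metadata$role == "qc")
  if (is.null(reference)) {
    reference <- if (length(qc_rows)) {
      colMeans(mat[qc_rows, , drop = FALSE])
    } else {
      colMeans(mat)
    }
  }
  aligned <- align_traces(mat, reference, config)
  shifts <- attr(aligned, "shifts")
  out <- fingerprint_matrix(aligned, x$time_min, x$metadata, x$channel)
  if (is.null(qc_divide)) qc_divide <- length(qc_rows) > 0L
  if (qc_divide) out <- qc_correct(out, config)
  attr(out, "stages") <- list(
    smooth = list(window = config$smooth_window,
                  polyorder = config$smooth_polyorder),
    baseline = list(lambda = config$baseline_lambda, p = config$baseline_p),
    align = list(segments = config$align_segments,
                 max_shift = config$align_max_shift,
                 mean_abs_shift = mean(abs(shifts))),
    qc_divide = qc_divide)
  out
}
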