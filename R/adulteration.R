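# Adulteration quantitation: six-level calibration / five-level external
# validation mixture design (n = 5 each), venetian-blind latent-variable
# selection, and prediction on mixtures of unseen extracts at 15/50/85%.

#' Mixture design of the adulteration studies
#'
#' Default levels follow the study design: calibration at 0/20/40/60/80/100%
#' chicory, external validation at 15/25/50/75/85%, prediction (with
#' different extracts) at 15/50/85%, all in quintuplicate.
#'
#' @param calibration_pcts,validation_pcts,prediction_pcts Adulterant
#'   percentage levels, each in `[0, 100]`.
#' @param replicates Replicates per level (default 5).
#' @return A `mixture_design` list.
#' @export
mixture_design <- function(calibration_pcts = c(0, 20, 40, 60, 80, 100),
                           validation_pcts = c(15, 25, 50, 75, 85),
                           prediction_pcts = c(15, 50, 85),
                           replicates = 5L) {
  pcts <- c(calibration_pcts, validation_pcts, prediction_pcts)
  if (any(pcts < 0 | pcts > 100)) {
    stop("all adulterant percentages must lie in [0, 100]", call. = FALSE)
  }
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  structure(list(calibration_pcts = calibration_pcts,
                 validation_pcts = validation_pcts,
                 prediction_pcts = prediction_pcts,
                 replicates = as.integer(replicates)),
            class = "mixture_design")
}

extract_id <- function(x) {
  id <- attr(x, "sample_id")
  if (is.null(id)) NA_character_ else id
}

# One block of mixture rows: levels x replicates, fresh baseline + noise per
# replicate, seeded per row. Noise and baseline amplitudes are detector
# properties, constant across the block: they scale with the study's
# maximum extract amplitude, not with the individual mixture level.
mixture_block <- function(tea, chicory, pcts, replicates, seed, stream,
                          noise_frac, baseline_frac) {
  grid <- tea$time_min
  n_rows <- length(pcts) * replicates
  mat <- matrix(0, n_rows, length(grid))
  y <- numeric(n_rows)
  ref_amp <- max(abs(tea$intensity), abs(chicory$intensity))
  r <- 0L
  for (p in pcts) {
    pure <- mix_fingerprints(tea, chicory, p)$intensity
    for (rep_i in seq_len(replicates)) {
      r <- r + 1L
      row_seed <- derive_seed(seed, r, stream)
      trace <- pure +
        make_baseline(grid, baseline_frac * ref_amp,
                      derive_seed(row_seed, 1L, 50L))
      if (noise_frac > 0) {
        trace <- trace + with_seed(derive_seed(row_seed, 2L, 51L),
          stats::rnorm(length(grid), sd = noise_frac * ref_amp))
      }
      mat[r, ] <- trace
      y[r] <- p
    }
  }
  list(x = mat, y = y)
}

#' Build the calibration and external-validation mixture sets
#'
#' In-silico analogue of physically blending one tea extract with one
#' chicory extract: linear mixing at the design levels, each replicate with
#' a fresh baseline and noise realization.
#'
#' @param tea_extract,chicory_extract [chromatogram()] objects (ideal,
#'   drift-free extract traces) on the same grid and channel.
#' @param design A [mixture_design()].
#' @param seed Integer seed.
#' @param noise_frac,baseline_frac Per-replicate noise and baseline
#'   amplitudes as fractions of the mixed-trace maximum.
#' @return List with `cal`/`val` intensity matrices, `y_cal`/`y_val` true
#'   adulterant percentages, `grid`, `channel`, `extract_ids`.
#' @export
build_mixture_sets <- function(tea_extract, chicory_extract,
                               design = mixture_design(), seed = 1L,
                               noise_frac = 0.005, baseline_frac = 0.02) {
  stopifnot(inherits(design, "mixture_design"))
  cal <- mixture_block(tea_extract, chicory_extract,
                       design$calibration_pcts, design$replicates,
                       seed, 60L, noise_frac, baseline_frac)
  val <- mixture_block(tea_extract, chicory_extract,
                       design$validation_pcts, design$replicates,
                       seed, 61L, noise_frac, baseline_frac)
  list(cal = cal$x, val = val$x, y_cal = cal$y, y_val = val$y,
       grid = tea_extract$time_min, channel = tea_extract$channel,
       extract_ids = c(tea = extract_id(tea_extract),
                       chicory = extract_id(chicory_extract)))
}

#' Build the prediction set from unseen extracts
#'
#' Mixtures at the prediction levels using tea and chicory extracts distinct
#' from the ones the calibration model was built on.
#'
#' @param other_tea_extract,other_chicory_extract [chromatogram()] objects.
#' @param design A [mixture_design()].
#' @param seed Integer seed.
#' @param exclude_ids Extract ids used in calibration; an overlap with the
#'   ids of the supplied extracts (when both carry `sample_id` attributes)
#'   is an error.
#' @param noise_frac,baseline_frac As in [build_mixture_sets()].
#' @return List with `pred` intensity matrix and `y_pred`.
#' @export
build_prediction_set <- function(other_tea_extract, other_chicory_extract,
                                 design = mixture_design(), seed = 1L,
                                 exclude_ids = NULL, noise_frac = 0.005,
                                 baseline_frac = 0.02) {
  stopifnot(inherits(design, "mixture_design"))
  ids <- c(extract_id(other_tea_extract), extract_id(other_chicory_extract))
  if (!is.null(exclude_ids) && any(stats::na.omit(ids) %in% exclude_ids)) {
    stop("prediction extracts must differ from the calibration extracts",
         call. = FALSE)
  }
  block <- mixture_block(other_tea_extract, other_chicory_extract,
                         design$prediction_pcts, design$replicates,
                         seed, 62L, noise_frac, baseline_frac)
  list(pred = block$x, y_pred = block$y, extract_ids = ids)
}

#' Root-mean-square error in adulterant percentage points
#'
#' @param y_true,y_pred Equal-length non-empty numeric vectors.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse_percent <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination
#'
#' @param y_true Observed values (non-constant).
#' @param y_fitted Fitted values.
#' @return `1 - SS_res / SS_tot`.
#' @export
r_squared <- function(y_true, y_fitted) {
  if (stats::var(y_true) <= 0) {
    stop("y_true is constant; R-squared undefined", call. = FALSE)
  }
  1 - sum((y_true - y_fitted)^2) / sum((y_true - mean(y_true))^2)
}

# Pick calibration and prediction extract ids for one study. White tea draws
# its calibration extract from one sub-type and its prediction extract from
# the other, reflecting the two distinct white-tea productions.
pick_extracts <- function(truth, tea_class, seed) {
  pick <- function(ids, n) with_seed(seed, sample(ids, n))
  if (tea_class == "white") {
    a <- truth$sample_id[truth$template_class == "white_a"]
    b <- truth$sample_id[truth$template_class == "white_b"]
    if (!length(a) || !length(b)) {
      stop("white-tea study needs both white sub-types", call. = FALSE)
    }
    tea_ids <- c(pick(a, 1L), pick(b, 1L))
  } else {
    ids <- truth$sample_id[truth$class_label == tea_class]
    if (length(ids) < 2L) {
      stop("need at least two extracts of ", tea_class, call. = FALSE)
    }
    tea_ids <- pick(ids, 2L)
  }
  chic <- truth$sample_id[truth$class_label == "chicory"]
  if (length(chic) < 2L) {
    stop("need at least two chicory extracts", call. = FALSE)
  }
  list(tea = tea_ids, chicory = pick(chic, 2L))
}

# Smooth + baseline-correct + align a plain mixture matrix; the reference
# defaults to the mean corrected calibration trace and is reused for the
# validation and prediction rows.
preprocess_mixture_matrix <- function(mat, config, reference = NULL) {
  for (i in seq_len(nrow(mat))) {
    sm <- smooth_trace(mat[i, ], config)
    mat[i, ] <- baseline_correct(sm, config)$corrected
  }
  if (is.null(reference)) reference <- colMeans(mat)
  list(x = align_traces(mat, reference, config), reference = reference)
}

#' Run one adulteration study
#'
#' For one tea variety and channel: picks one tea and one chicory extract
#' (ideal drift-free traces) from the dataset, builds the calibration and
#' external-validation mixture sets, preprocesses them (smoothing, baseline,
#' alignment -- no QC division: the standalone mixture design carries no
#' QCs), selects the latent-variable count by venetian-blind
#' cross-validation, fits the PLS model, and evaluates calibration,
#' cross-validation, external-validation (same extracts) and prediction
#' (different extracts, 15/50/85%) errors.
#'
#' @param dataset A [generate_dataset()] result with at least two extracts
#'   of the tea class and of chicory.
#' @param tea_class One of `black`, `green`, `oolong`, `red`, `white`.
#' @param channel `"uv"` or `"fld"`.
#' @param seed Integer seed (extract choice, replicate noise).
#' @param design A [mixture_design()].
#' @param config A [preprocess_config()].
#' @param max_lv Largest latent-variable count evaluated (default 8).
#' @param n_splits Venetian blinds (default 10).
#' @param rel_tol Latent-variable selection tolerance (default 0.02).
#' @param noise_frac,baseline_frac Replicate noise/baseline amplitudes.
#' @return An `adulteration_report` data-frame row: `tea_class`, `channel`,
#'   `n_lv`, `r2`, `rmsec`, `rmsecv`, `rmsev_external`, `rmsep_prediction`.
#' @export
run_adulteration_study <- function(dataset, tea_class,
                                   channel = c("uv", "fld"), seed = 1L,
                                   design = mixture_design(),
                                   config = preprocess_config(),
                                   max_lv = 8L, n_splits = 10L,
                                   rel_tol = 0.02, noise_frac = 0.005,
                                   baseline_frac = 0.02) {
  channel <- match.arg(channel)
  tea_class <- match.arg(tea_class,
                         c("black", "green", "oolong", "red", "white"))
  stopifnot(inherits(dataset, "chrom_dataset"))
  picks <- pick_extracts(dataset$truth, tea_class,
                         derive_seed(seed, 0L, 70L))
  ideal <- dataset$ideal[[channel]]
  grid <- dataset$config$grid
  extract_trace <- function(id) {
    tr <- chromatogram(grid, ideal[id, ], channel)
    attr(tr, "sample_id") <- id
    tr
  }
  sets <- build_mixture_sets(extract_trace(picks$tea[1]),
                             extract_trace(picks$chicory[1]),
                             design, seed = derive_seed(seed, 1L, 71L),
                             noise_frac = noise_frac,
                             baseline_frac = baseline_frac)
  pred <- build_prediction_set(extract_trace(picks$tea[2]),
                               extract_trace(picks$chicory[2]),
                               design, seed = derive_seed(seed, 2L, 72L),
                               exclude_ids = sets$extract_ids,
                               noise_frac = noise_frac,
                               baseline_frac = baseline_frac)
  cal_pp <- preprocess_mixture_matrix(sets$cal, config)
  val_pp <- preprocess_mixture_matrix(sets$val, config, cal_pp$reference)
  pred_pp <- preprocess_mixture_matrix(pred$pred, config, cal_pp$reference)

  cv <- cross_validate_pls(cal_pp$x, sets$y_cal, max_lv = max_lv,
                           n_splits = n_splits)
  n_lv <- select_lv(cv, rel_tol = rel_tol)
  fit <- pls_fit(cal_pp$x, sets$y_cal, n_lv = n_lv)
  y_hat_cal <- as.numeric(fit$fitted)
  out <- data.frame(
    tea_class = tea_class, channel = channel, n_lv = fit$n_lv,
    r2 = r_squared(sets$y_cal, y_hat_cal),
    rmsec = rmse_percent(sets$y_cal, y_hat_cal),
    rmsecv = cv$rmsecv_by_lv[n_lv],
    rmsev_external = rmse_percent(sets$y_val,
                                  as.numeric(pls_predict(fit, val_pp$x))),
    rmsep_prediction = rmse_percent(pred$y_pred,
                                    as.numeric(pls_predict(fit, pred_pp$x))),
    stringsAsFactors = FALSE)
  class(out) <- c("adulteration_report", "data.frame")
  out
}

#' Run all adulteration studies (five teas x both channels)
#'
#' @param dataset A [generate_dataset()] result.
#' @param seed Integer seed.
#' @param channels Channels to run (default both).
#' @param ... Passed to [run_adulteration_study()].
#' @return An `adulteration_report` data frame, one row per study.
#' @export
run_all_adulteration_studies <- function(dataset, seed = 1L,
                                         channels = c("uv", "fld"), ...) {
  teas <- c("red", "green", "black", "oolong", "white")
  rows <- list()
  for (ch in channels) {
    for (tea in teas) {
      rows[[paste(tea, ch)]] <-
        run_adulteration_study(dataset, tea, ch,
                               seed = derive_seed(seed, length(rows), 80L),
                               ...)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("adulteration_report", "data.frame")
  out
}
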