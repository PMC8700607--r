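# PLS-DA workflows: stratified 70/30 calibration/prediction validation,
# one-hot PLS-DA fits with misassignment-rate-driven latent-variable
# selection, and classification-rate reporting.

#' Stratified calibration/prediction split
#'
#' Draws `ceiling(frac_cal * n_c)` seeded samples per class into the
#' calibration set; the remainder forms the prediction set. Stratification
#' guarantees that small classes appear in both sets.
#'
#' @param labels Class label per sample.
#' @param frac_cal Calibration fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `cal` and `pred` (disjoint,
#'   exhaustive).
#' @export
split_calibration_prediction <- function(labels, frac_cal = 0.7, seed = 1L) {
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("every class needs at least 2 members to split", call. = FALSE)
  }
  cal <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      sample(idx, ceiling(frac_cal * length(idx)))
    }), use.names = FALSE)
  })
  cal <- sort(cal)
  list(cal = cal, pred = setdiff(seq_along(labels), cal))
}

one_hot <- function(labels, class_labels) {
  y <- matrix(0, length(labels), length(class_labels),
              dimnames = list(NULL, class_labels))
  y[cbind(seq_along(labels), match(labels, class_labels))] <- 1
  y
}

#' Fit a PLS-DA model
#'
#' Regresses a one-hot class matrix on the fingerprint matrix by NIPALS PLS.
#' The latent-variable count is chosen by venetian-blind cross-validation of
#' the misassignment rate (not RMSECV), mirroring how classification models
#' are reported; the first count whose CV misassignment rate is within
#' `rel_tol` of anything achievable with more latent variables wins.
#'
#' For two-class (paired) models the assignment rule is a 0.5 threshold on
#' the adulterant-class response, with ties going to the tea class so that
#' adulterant calls are conservative; with more classes, argmax.
#'
#' @param x_cal Calibration matrix (preprocessed, unscaled; autoscaling
#'   happens inside the PLS fit on calibration rows only).
#' @param labels_cal Class label per calibration row (>= 2 classes).
#' @param max_lv Largest latent-variable count considered (default 10,
#'   capped by the data).
#' @param n_splits Venetian blinds (default 10).
#' @param rel_tol Selection tolerance on the misassignment rate
#'   (default 0.02).
#' @return A `plsda_model`: the underlying `pls` model, `class_labels`,
#'   `assignment_rule`, `positive_class` (two-class rule), `n_lv`,
#'   `cv_misassignment`.
#' @export
plsda_fit <- function(x_cal, labels_cal, max_lv = 10L, n_splits = 10L,
                      rel_tol = 0.02) {
  x_cal <- as.matrix(x_cal)
  class_labels <- sort(unique(labels_cal))
  if (length(class_labels) < 2L) {
    stop("PLS-DA needs at least two classes", call. = FALSE)
  }
  y <- one_hot(labels_cal, class_labels)
  max_lv <- min(max_lv, nrow(x_cal) - 2L, ncol(x_cal))
  rule <- if (length(class_labels) == 2L) "threshold_0.5" else "argmax"
  positive <- if (rule == "threshold_0.5") {
    if ("chicory" %in% class_labels) "chicory" else class_labels[2L]
  } else {
    NA_character_
  }
  cv <- cross_validate_pls(x_cal, y, max_lv = max_lv, n_splits = n_splits)
  miss <- vapply(seq_len(max_lv), function(a) {
    assigned <- assign_from_responses(cv$predictions[, , a, drop = FALSE][, , 1],
                                      class_labels, rule, positive)
    mean(assigned != labels_cal)
  }, numeric(1))
  n_lv <- select_lv(miss, rel_tol = rel_tol)
  fit <- pls_fit(x_cal, y, n_lv = n_lv)
  structure(list(pls = fit, class_labels = class_labels,
                 assignment_rule = rule, positive_class = positive,
                 n_lv = fit$n_lv, cv_misassignment = miss),
            class = "plsda_model")
}

assign_from_responses <- function(resp, class_labels, rule, positive) {
  resp <- matrix(resp, ncol = length(class_labels),
                 dimnames = list(NULL, class_labels))
  if (rule == "threshold_0.5") {
    other <- setdiff(class_labels, positive)
    ifelse(resp[, positive] > 0.5, positive, other)  # tie -> tea class
  } else {
    class_labels[max.col(resp, ties.method = "first")]
  }
}

#' Assign class labels to new rows
#'
#' @param model A [plsda_fit()] model.
#' @param x_new Matrix of preprocessed rows.
#' @return Character vector of assigned labels.
#' @export
plsda_assign <- function(model, x_new) {
  stopifnot(inherits(model, "plsda_model"))
  resp <- pls_predict(model$pls, x_new)
  assign_from_responses(resp, model$class_labels, model$assignment_rule,
                        model$positive_class)
}

#' Classification rate in percent
#'
#' @param truth,assigned Equal-length label vectors.
#' @return `100 * matches / total`, rounded to 2 decimals.
#' @export
classification_rate <- function(truth, assigned) {
  if (length(truth) == 0L) stop("empty label vector", call. = FALSE)
  if (length(truth) != length(assigned)) {
    stop("truth and assigned lengths differ", call. = FALSE)
  }
  round(100 * mean(truth == assigned), 2)
}

classification_report <- function(set_name, truth, assigned, class_labels,
                                  n_lv) {
  confusion <- table(factor(truth, levels = class_labels),
                     factor(assigned, levels = class_labels),
                     dnn = c("truth", "assigned"))
  structure(list(set_name = set_name,
                 rate_pct = classification_rate(truth, assigned),
                 confusion = confusion, n_lv = n_lv),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s: %.2f%% correct (%d LVs)\n",
              x$set_name, x$rate_pct, x$n_lv))
  print(x$confusion)
  invisible(x)
}

#' Preprocessed sample-only feature matrix of one channel
#'
#' Runs the full pretreatment chain (smoothing, baseline, alignment,
#' nearest-QC division) on a generated dataset and drops the QC/blank rows,
#' yielding the matrix the classification and PCA workflows consume.
#'
#' @param dataset A [generate_dataset()] result.
#' @param channel `"uv"` or `"fld"`.
#' @param config A [preprocess_config()].
#' @return A [fingerprint_matrix()] of sample injections only.
#' @export
dataset_features <- function(dataset, channel = c("uv", "fld"),
                             config = preprocess_config()) {
  channel <- match.arg(channel)
  stopifnot(inherits(dataset, "chrom_dataset"))
  pre <- preprocess_fingerprints(dataset[[channel]], config)
  fpm_subset(pre, pre$metadata$role == "sample")
}

#' Paired tea-vs-chicory PLS-DA study
#'
#' Subsets one tea variety plus chicory, splits 70/30 (stratified, seeded),
#' fits a paired PLS-DA model on the calibration rows and reports
#' calibration and prediction classification rates.
#'
#' @param x A `chrom_dataset` (preprocessed internally on `channel`) or an
#'   already-preprocessed sample-only [fingerprint_matrix()].
#' @param tea_class One of `black`, `green`, `oolong`, `red`, `white`.
#' @param channel Detection channel (used when `x` is a dataset).
#' @param seed Seed for the 70/30 split.
#' @param config Preprocessing configuration (dataset input only).
#' @param ... Passed to [plsda_fit()].
#' @return List with `calibration` and `prediction`
#'   [`classification_report`]s and the fitted `model`.
#' @export
paired_plsda_study <- function(x, tea_class, channel = c("uv", "fld"),
                               seed = 1L, config = preprocess_config(), ...) {
  tea_class <- match.arg(tea_class,
                         c("black", "green", "oolong", "red", "white"))
  features <- if (inherits(x, "chrom_dataset")) {
    dataset_features(x, channel, config)
  } else {
    stopifnot(inherits(x, "fingerprint_matrix"))
    x
  }
  labels <- features$metadata$class_label
  if (!all(c(tea_class, "chicory") %in% labels)) {
    stop("dataset lacks the requested tea class or chicory", call. = FALSE)
  }
  keep <- labels %in% c(tea_class, "chicory")
  sub <- fpm_subset(features, keep)
  sub_labels <- sub$metadata$class_label
  split <- split_calibration_prediction(sub_labels, seed = seed)
  model <- plsda_fit(sub$intensity[split$cal, , drop = FALSE],
                     sub_labels[split$cal], ...)
  cal_assigned <- plsda_assign(model, sub$intensity[split$cal, , drop = FALSE])
  pred_assigned <- plsda_assign(model, sub$intensity[split$pred, , drop = FALSE])
  list(calibration = classification_report("calibration",
                                           sub_labels[split$cal],
                                           cal_assigned, model$class_labels,
                                           model$n_lv),
       prediction = classification_report("prediction",
                                          sub_labels[split$pred],
                                          pred_assigned, model$class_labels,
                                          model$n_lv),
       model = model)
}
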