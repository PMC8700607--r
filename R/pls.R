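# NIPALS partial least squares with venetian-blind cross-validation and
# latent-variable selection. This is the numerical engine of the package;
# everything downstream (PLS-DA, adulteration quantitation) calls into it.

#' Fit a PLS model by NIPALS
#'
#' Classical NIPALS PLS2: per latent variable, iterate
#' `w = X'u / u'u` (normalized), `t = X w`, `q = Y't / t't`,
#' `u = Y q / q'q` to convergence, then deflate `X` by `t p'`
#' (`p = X't / t't`) and `Y` by `t q'`. With a univariate response the loop
#' converges in a single pass. X is autoscaled internally (columns with
#' near-zero variance are zeroed) and Y is mean-centered; the stored scaling
#' is applied to prediction rows, and the regression coefficients act on the
#' autoscaled variable space.
#'
#' Sign convention: each weight vector is flipped so its largest-magnitude
#' element is positive (scores and loadings flip with it; predictions are
#' unaffected).
#'
#' @param x Predictor matrix (samples x variables).
#' @param y Response vector or matrix (same row count).
#' @param n_lv Number of latent variables, `<= min(dim(x))`.
#' @param scale_x Autoscale X (default) or use it as given (centering only).
#' @param tol Convergence tolerance on the relative change of the score
#'   vector (default 1e-10).
#' @param max_iter Iteration cap per latent variable (default 500).
#' @return A `pls_model`: `x_weights` (W), `x_loadings` (P), `y_loadings`
#'   (Q), `x_scores` (T), `coefficients` (autoscaled-X space), `y_mean`,
#'   `scaling`, `n_lv`, `fitted`.
#' @export
pls_fit <- function(x, y, n_lv, scale_x = TRUE, tol = 1e-10,
                    max_iter = 500L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  p <- ncol(x)
  q_dim <- ncol(y)
  if (nrow(y) != n) stop("x and y row counts differ", call. = FALSE)
  if (n_lv < 1 || n_lv > min(n, p)) {
    stop("n_lv must lie in [1, min(dim(x))]", call. = FALSE)
  }
  if (all(apply(y, 2, stats::sd) < 1e-12)) {
    stop("y has zero variance", call. = FALSE)
  }
  scaling <- if (scale_x) {
    autoscale(x)
  } else {
    ctr <- colMeans(x)
    list(scaled = sweep(x, 2, ctr), center = ctr, scale = rep(1, p),
         constant = rep(FALSE, p))
  }
  xs <- scaling$scaled
  y_mean <- colMeans(y)
  ys <- sweep(y, 2, y_mean)

  w_mat <- matrix(0, p, n_lv)
  p_mat <- matrix(0, p, n_lv)
  q_mat <- matrix(0, q_dim, n_lv)
  t_mat <- matrix(0, n, n_lv)
  xr <- xs
  yr <- ys
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    if (sum(xr^2) < 1e-12 || sum(yr^2) < 1e-24) break  # rank exhausted
    u <- yr[, which.max(apply(yr, 2, function(v) sum(v^2)))]
    t_old <- rep(Inf, n)
    tvec <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(xr, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      tvec <- xr %*% w
      qvec <- crossprod(yr, tvec) / sum(tvec^2)
      u <- yr %*% qvec / sum(qvec^2)
      if (sqrt(sum((tvec - t_old)^2)) <= tol * sqrt(sum(tvec^2))) {
        converged <- TRUE
        break
      }
      t_old <- tvec
    }
    if (!converged) {
      stop(sprintf("NIPALS did not converge for latent variable %d", a),
           call. = FALSE)
    }
    flip <- sign(w[which.max(abs(w))])
    if (flip < 0) {
      w <- -w
      tvec <- -tvec
      qvec <- -qvec
    }
    pvec <- crossprod(xr, tvec) / sum(tvec^2)
    w_mat[, a] <- w
    p_mat[, a] <- pvec
    q_mat[, a] <- qvec
    t_mat[, a] <- tvec
    xr <- xr - tvec %*% t(pvec)
    yr <- yr - tvec %*% t(qvec)
    a_used <- a
  }
  if (a_used == 0L) stop("x has no usable variance", call. = FALSE)
  w_mat <- w_mat[, seq_len(a_used), drop = FALSE]
  p_mat <- p_mat[, seq_len(a_used), drop = FALSE]
  q_mat <- q_mat[, seq_len(a_used), drop = FALSE]
  t_mat <- t_mat[, seq_len(a_used), drop = FALSE]
  coef <- pls_coefficients_internal(w_mat, p_mat, q_mat, a_used)
  fitted <- xs %*% coef + matrix(y_mean, n, q_dim, byrow = TRUE)
  structure(list(n_lv = a_used, x_weights = w_mat, x_loadings = p_mat,
                 y_loadings = q_mat, x_scores = t_mat, coefficients = coef,
                 y_mean = y_mean, scaling = scaling[c("center", "scale",
                                                      "constant")],
                 fitted = fitted, y_dim = q_dim),
            class = "pls_model")
}

pls_coefficients_internal <- function(w_mat, p_mat, q_mat, a) {
  wa <- w_mat[, seq_len(a), drop = FALSE]
  pa <- p_mat[, seq_len(a), drop = FALSE]
  qa <- q_mat[, seq_len(a), drop = FALSE]
  wa %*% solve(crossprod(pa, wa), t(qa))
}

#' Regression coefficients truncated to the first latent variables
#'
#' @param model A [pls_fit()] model.
#' @param n_lv Latent-variable count (default: all fitted).
#' @return Coefficient matrix (variables x responses) in autoscaled-X space.
#' @export
pls_coefficients <- function(model, n_lv = model$n_lv) {
  stopifnot(inherits(model, "pls_model"), n_lv >= 1, n_lv <= model$n_lv)
  pls_coefficients_internal(model$x_weights, model$x_loadings,
                            model$y_loadings, n_lv)
}

#' Predict responses for new rows
#'
#' Applies the stored autoscaling (training means and s.d.s) and the
#' regression coefficients; an all-zero autoscaled row therefore predicts the
#' training response mean.
#'
#' @param model A [pls_fit()] model.
#' @param x_new Matrix of new rows (variables must match training).
#' @param n_lv Latent-variable count to use (default: all fitted).
#' @return Predicted response matrix (rows x responses).
#' @export
pls_predict <- function(model, x_new, n_lv = model$n_lv) {
  stopifnot(inherits(model, "pls_model"))
  x_new <- if (is.matrix(x_new)) x_new else matrix(x_new, nrow = 1)
  if (ncol(x_new) != length(model$scaling$center)) {
    stop("x_new column count does not match the training variables",
         call. = FALSE)
  }
  xs <- apply_autoscale(x_new, model$scaling)
  coef <- if (n_lv == model$n_lv) model$coefficients else
    pls_coefficients(model, n_lv)
  xs %*% coef + matrix(model$y_mean, nrow(x_new), model$y_dim, byrow = TRUE)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d variables, %d response(s)\n",
              x$n_lv, nrow(x$x_weights), x$y_dim))
  invisible(x)
}

#' Venetian-blind cross-validation splits
#'
#' Test fold `k` collects samples at positions `k, k + n_splits,
#' k + 2 n_splits, ...`; the folds partition the sample set.
#'
#' @param n_samples Number of samples.
#' @param n_splits Number of blinds, `2 <= n_splits <= n_samples`.
#' @return List of `list(train, test)` index pairs.
#' @export
venetian_blind_splits <- function(n_samples, n_splits) {
  if (n_splits < 2L || n_splits > n_samples) {
    stop("n_splits must lie in [2, n_samples]", call. = FALSE)
  }
  lapply(seq_len(n_splits), function(k) {
    test <- as.integer(seq.int(k, n_samples, by = n_splits))
    list(train = setdiff(seq_len(n_samples), test), test = test)
  })
}

#' Venetian-blind cross-validation of a PLS model
#'
#' For every candidate latent-variable count, pools squared prediction errors
#' over the venetian-blind folds into one RMSECV (response units). Each fold
#' is autoscaled on its training rows only; per-LV predictions come from one
#' NIPALS fit per fold at `max_lv` (PLS coefficient sequences are nested in
#' the latent-variable count).
#'
#' @param x Predictor matrix.
#' @param y Response vector or matrix.
#' @param max_lv Largest latent-variable count to evaluate.
#' @param n_splits Number of blinds (default 10, capped at `nrow(x)`).
#' @return A `cv_result`: `rmsecv_by_lv`, `predictions` (samples x responses
#'   x LV array of held-out predictions), `splits`, and `chosen_lv` (filled
#'   by [select_lv()]).
#' @export
cross_validate_pls <- function(x, y, max_lv, n_splits = 10L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (max_lv < 1L) stop("max_lv must be >= 1", call. = FALSE)
  n <- nrow(x)
  n_splits <- min(n_splits, n)
  splits <- venetian_blind_splits(n, n_splits)
  preds <- array(NA_real_, dim = c(n, ncol(y), max_lv))
  for (fold in splits) {
    if (length(fold$train) < 2L) {
      stop("cross-validation fold with fewer than 2 training rows",
           call. = FALSE)
    }
    a_max <- min(max_lv, length(fold$train), ncol(x))
    fit <- pls_fit(x[fold$train, , drop = FALSE],
                   y[fold$train, , drop = FALSE], n_lv = a_max)
    for (a in seq_len(max_lv)) {
      preds[fold$test, , a] <-
        pls_predict(fit, x[fold$test, , drop = FALSE],
                    n_lv = min(a, fit$n_lv))
    }
  }
  rmsecv <- vapply(seq_len(max_lv), function(a) {
    sqrt(mean((preds[, , a] - y)^2))
  }, numeric(1))
  structure(list(rmsecv_by_lv = rmsecv, predictions = preds,
                 splits = splits, chosen_lv = NULL),
            class = "cv_result")
}

#' Select the latent-variable count at the first important CV minimum
#'
#' Returns the smallest count `L` whose error is within `rel_tol` of the best
#' error achievable with more latent variables, i.e.
#' `err(L) <= (1 + rel_tol) * min(err(L'), L' > L)`; if no such `L` exists
#' the global argmin (earliest on ties) is returned. This operationalizes
#' "the first important minimum of the cross-validation error".
#'
#' @param cv A `cv_result` or a numeric vector of per-LV errors.
#' @param rel_tol Relative tolerance (default 0.02).
#' @return Chosen latent-variable count (integer).
#' @export
select_lv <- function(cv, rel_tol = 0.02) {
  err <- if (inherits(cv, "cv_result")) cv$rmsecv_by_lv else as.numeric(cv)
  stopifnot(length(err) >= 1L)
  k <- length(err)
  for (a in seq_len(k - 1L)) {
    later_best <- min(err[(a + 1L):k])
    if (err[a] <= (1 + rel_tol) * later_best) return(a)
  }
  which.min(err)[[1L]]
}
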