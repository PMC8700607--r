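#' Principal component analysis of a (pre-scaled) data matrix
#'
#' Thin wrapper over the singular value decomposition: loadings are the
#' leading right singular vectors, scores the data projected onto them, and
#' explained variance the squared singular values over the total. The input
#' is expected to be autoscaled (or at least centered) already, as in the
#' rest of the pipeline.
#'
#' @param x Numeric matrix (>= 2 rows) or [fingerprint_matrix()].
#' @param n_components Number of components to keep (default
#'   `min(dim(x))`).
#' @return A `pca_model`: `scores` (samples x components), `loadings`
#'   (variables x components, orthonormal), `explained_var` (fraction per
#'   kept component), `singular_values`.
#' @export
pca_fit <- function(x, n_components = NULL) {
  mat <- if (inherits(x, "fingerprint_matrix")) x$intensity else as.matrix(x)
  if (nrow(mat) < 2L) stop("PCA requires at least two rows", call. = FALSE)
  k_max <- min(dim(mat))
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max) {
    stop("n_components exceeds min(dim(x))", call. = FALSE)
  }
  sv <- svd(mat, nu = n_components, nv = n_components)
  total <- sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(mat)
  structure(list(scores = scores,
                 loadings = sv$v,
                 explained_var = if (total > 0) {
                   sv$d[seq_len(n_components)]^2 / total
                 } else {
                   rep(0, n_components)
                 },
                 singular_values = sv$d),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; explained variance: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_var), collapse = " ")))
  invisible(x)
}
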