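# Accept either a bucket_table or a plain matrix throughout the modelling
# functions.
as_X <- function(X) {
  if (inherits(X, "bucket_table")) X$matrix else as.matrix(X)
}

#' Principal component analysis with mean-center scaling
#'
#' PCA on the column-centered matrix via singular value decomposition, used
#' to examine group clustering and flag outliers before supervised
#' modelling. Component signs are fixed by forcing the largest-magnitude
#' loading element of each component positive, so results are deterministic.
#'
#' @param X A `bucket_table` or numeric matrix (samples x variables).
#' @param n_components Number of components to retain; at most
#'   `min(n - 1, p)`.
#' @return A `pca_model`: `scores` (samples x k), `loadings` (variables x k,
#'   orthonormal), `explained_variance` (fraction per component, relative to
#'   total variance), `center`.
#' @export
fit_pca <- function(X, n_components = 3) {
  M <- as_X(X)
  n <- nrow(M); p <- ncol(M)
  kmax <- min(n - 1L, p)
  assert_that(n_components >= 1 && n_components <= kmax,
              sprintf("n_components must be in 1..%d", kmax))
  center <- colMeans(M)
  Mc <- sweep(M, 2, center)
  total <- sum(Mc^2)
  if (total <= 0) stop2("matrix has zero variance; PCA undefined")
  sv <- svd(Mc, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  loadings <- sv$v
  scores <- sv$u %*% diag(d, n_components)
  for (k in seq_len(n_components)) {   # deterministic sign
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = sv$d[seq_len(n_components)]^2 / sum(sv$d^2),
                 center = center,
                 n_components = n_components),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; explained variance: %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}
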