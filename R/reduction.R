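# Training-fold PCA: the three dimension-reduction stages of the pipeline.
# PCA is always fit on training rows only and applied unchanged to test rows.

#' Fit a PCA model on a training matrix
#'
#' Centering by training column means, no variance scaling. Components are
#' ordered by explained variance with a deterministic sign convention (the
#' largest-magnitude loading entry of each component is positive). When the
#' training rank is below `k`, the remaining components are zero-padded and a
#' warning is raised so downstream shapes hold.
#'
#' @param X numeric training matrix (n_train x p).
#' @param k number of components to retain, `k <= min(n_train - 1, p)`.
#' @return A `pca_model`: list with `center`, `loadings` (p x k),
#'   `explained_variance` (length k, non-increasing), `k`.
#' @export
fit_pca <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (!all(is.finite(X))) stop_config("PCA input contains non-finite values")
  if (k > min(n - 1, p))
    stop_config("k = %d exceeds min(n_train - 1, p) = %d", k, min(n - 1, p))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (all(abs(Xc) < 1e-12))
    stop_config("PCA stage received a zero-variance training matrix")
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  kk <- min(k, rank)
  if (kk < k)
    warning(sprintf("training rank %d < k = %d; zero-padding components",
                    rank, k), call. = FALSE)
  L <- matrix(0, p, k)
  L[, seq_len(kk)] <- sv$v[, seq_len(kk), drop = FALSE]
  evs <- c(ev[seq_len(kk)], rep(0, k - kk))
  for (j in seq_len(kk)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  structure(list(center = ctr, loadings = L, explained_variance = evs,
                 k = as.integer(k)),
            class = "pca_model")
}

#' Project a matrix through a fitted PCA model
#'
#' @param model a `pca_model` from [fit_pca()].
#' @param X m x p matrix with `p` matching the model.
#' @return m x k score matrix.
#' @export
apply_pca <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center))
    stop_config("matrix has %d columns, PCA model expects %d",
                ncol(X), length(model$center))
  sweep(X, 2, model$center) %*% model$loadings
}

#' Equalize a multi-valued feature to one value per electrode
#'
#' Stage-3 reduction: PCA fit on training rows over all `e * f` columns,
#' retaining `e` components, so multi- and single-valued features enter the
#' classifier with the same `n x e` shape. Single-valued input (`f = 1`)
#' passes through unchanged.
#'
#' @param values trial x (e*f) matrix for one window.
#' @param train_idx training-row indices (PCA is fit on these only).
#' @param e number of electrodes (components to retain).
#' @return trial x e matrix.
#' @export
equalize_multivalued <- function(values, train_idx, e) {
  if (ncol(values) == e) return(values)
  pca_reduce_to(values, train_idx, e)
}

# Fit PCA on train rows with k clamped to the feasible maximum, zero-padding
# the score matrix back to `k` columns when necessary (warned in fit_pca).
pca_reduce_to <- function(values, train_idx, k) {
  kk <- min(k, length(train_idx) - 1, ncol(values))
  if (kk < k)
    warning(sprintf("only %d components estimable for k = %d; zero-padding",
                    kk, k), call. = FALSE)
  model <- fit_pca(values[train_idx, , drop = FALSE], kk)
  scores <- apply_pca(model, values)
  if (kk < k) scores <- cbind(scores, matrix(0, nrow(scores), k - kk))
  scores
}

#' Scalarize a feature for selection scoring
#'
#' Stage-4 reduction: first principal component (fit on training rows) of an
#' `n x e` feature matrix, giving one value per trial. Used only to score
#' and rank features, never fed to the classifier.
#'
#' @param values trial x e matrix.
#' @param train_idx training-row indices.
#' @return n x 1 matrix.
#' @export
scalarize_for_selection <- function(values, train_idx) {
  model <- fit_pca(values[train_idx, , drop = FALSE], 1)
  apply_pca(model, values)
}

#' Combine selected features and equalize dimension
#'
#' Stages 6-7: column-concatenate the selected `n x e` feature matrices
#' (giving `n x k*e`) and reduce back to `n x e` with a training-fold PCA so
#' the combined space is directly comparable to any individual feature.
#'
#' @param mats list of trial x e matrices (the selected features).
#' @param train_idx training-row indices.
#' @param e number of electrodes.
#' @return trial x e matrix.
#' @export
combine_selected <- function(mats, train_idx, e) {
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || any(dims[2, ] != e))
    stop_config("selected feature matrices must all be n x e")
  concat <- do.call(cbind, mats)
  pca_reduce_to(concat, train_idx, e)
}
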