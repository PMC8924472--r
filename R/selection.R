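# Feature-selection scorers. Each scorer maps an n_train x p matrix of
# scalarized features (one column per candidate feature) to p scores with
# higher = more informative; supervised scorers additionally take binary
# class labels. A registry keeps the set open for plug-ins.

.fs_registry <- new.env(parent = emptyenv())

#' Register a feature-selection scorer
#'
#' Plug-in point for additional selection algorithms. A scorer is a function
#' `function(X, y, seed)` (unsupervised scorers may ignore `y`) returning one
#' finite score per column, higher = better.
#'
#' @param name method name.
#' @param fun scoring function.
#' @param supervised does the scorer use labels?
#' @export
register_fs_method <- function(name, fun, supervised = TRUE) {
  stopifnot(is.function(fun))
  assign(name, list(fun = fun, supervised = supervised), envir = .fs_registry)
  invisible(name)
}

#' Available feature-selection methods
#' @return Character vector of registered scorer names.
#' @export
available_fs_methods <- function() sort(ls(.fs_registry))

# -- mutual information with equal-frequency binning ------------------------

equal_freq_bin <- function(x, bins = 8) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
}

mi_discrete <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

mi_score <- function(x, y, bins = 8) {
  if (sd(x) == 0) return(0)
  mi_discrete(equal_freq_bin(x, bins), y)
}

# -- individual scorers ------------------------------------------------------

fisher_score <- function(X, y, seed = NULL) {
  cls <- sort(unique(y))
  a <- X[y == cls[1], , drop = FALSE]
  b <- X[y == cls[2], , drop = FALSE]
  num <- (colMeans(a) - colMeans(b))^2
  den <- apply(a, 2, var) + apply(b, 2, var)
  ifelse(apply(X, 2, sd) == 0, 0, num / (den + 1e-12))
}

mutinffs_score <- function(X, y, seed = NULL)
  apply(X, 2, mi_score, y = y)

mrmr_score <- function(X, y, seed = NULL) {
  p <- ncol(X)
  binned <- apply(X, 2, equal_freq_bin)
  rel <- vapply(seq_len(p), function(j) {
    if (sd(X[, j]) == 0) 0 else mi_discrete(binned[, j], y)
  }, numeric(1))
  chosen <- integer(0)
  remaining <- seq_len(p)
  order_out <- integer(p)
  for (step in seq_len(p)) {
    if (length(chosen) == 0) {
      pick <- remaining[which.max(rel[remaining])]
    } else {
      crit <- vapply(remaining, function(j) {
        red <- mean(vapply(chosen, function(c0)
          mi_discrete(binned[, j], binned[, c0]), numeric(1)))
        rel[j] - red
      }, numeric(1))
      pick <- remaining[which.max(crit)]
    }
    order_out[step] <- pick
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
  }
  scores <- numeric(p)
  scores[order_out] <- rev(seq_len(p))   # first picked = highest score
  scores
}

relief_score <- function(X, y, seed = NULL, n_samples = 50, n_neighbors = 10) {
  n <- nrow(X); p <- ncol(X)
  rng <- range(X)
  span <- apply(X, 2, function(v) diff(range(v)))
  span[span == 0] <- 1
  Xs <- sweep(X, 2, apply(X, 2, min))
  Xs <- sweep(Xs, 2, span, "/")
  picks <- if (is.null(seed)) sample.int(n, min(n_samples, n), replace = FALSE)
           else with_seed(seed, sample.int(n, min(n_samples, n),
                                           replace = FALSE))
  Wt <- numeric(p)
  for (i in picks) {
    d <- rowSums(abs(sweep(Xs, 2, Xs[i, ])))
    d[i] <- Inf
    hit_i <- which(y == y[i]); miss_i <- which(y != y[i])
    hits <- hit_i[order(d[hit_i])][seq_len(min(n_neighbors,
                                               length(hit_i) - 1))]
    misses <- miss_i[order(d[miss_i])][seq_len(min(n_neighbors,
                                                   length(miss_i)))]
    Wt <- Wt - colMeans(abs(sweep(Xs[hits, , drop = FALSE], 2, Xs[i, ]))) +
      colMeans(abs(sweep(Xs[misses, , drop = FALSE], 2, Xs[i, ])))
  }
  Wt / length(picks)
}

lasso_score <- function(X, y, seed = NULL, lambda = 10^seq(-3, 1,
                                                           length.out = 7)) {
  yb <- as.integer(y == max(y))
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) return(numeric(ncol(X)))
  lambda <- sort(lambda, decreasing = TRUE)
  folds3 <- if (is.null(seed)) make_folds(yb, 3, seed = 0L)
            else make_folds(yb, 3, seed = seed)
  dev <- matrix(NA_real_, 3, length(lambda))
  for (fd in 1:3) {
    tr <- folds3$fold != fd
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], yb[tr], family = "binomial",
                          alpha = 1, lambda = lambda)
    pr <- predict(fit, X[!tr, , drop = FALSE], type = "response")
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    for (li in seq_len(ncol(pr)))
      dev[fd, li] <- -mean(yb[!tr] * log(pr[, li]) +
                             (1 - yb[!tr]) * log(1 - pr[, li]))
  }
  best <- which.min(colMeans(dev, na.rm = TRUE))
  fit <- glmnet::glmnet(X, yb, family = "binomial", alpha = 1,
                        lambda = lambda)
  co <- abs(as.numeric(coef(fit)[-1, min(best, ncol(coef(fit)) - 0)]))
  # break exact ties (incl. all-zero coefficients) by Fisher score
  co + 1e-9 * rank(fisher_score(X, y))
}

laplacian_score <- function(X, y = NULL, seed = NULL, knn = 5) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  W <- matrix(0, n, n)
  t_heat <- mean(D2[upper.tri(D2)])
  if (t_heat == 0) t_heat <- 1
  for (i in seq_len(n)) {
    nb <- order(D2[i, ])[2:(min(knn, n - 1) + 1)]
    W[i, nb] <- exp(-D2[i, nb] / t_heat)
  }
  W <- pmax(W, t(W))
  Dg <- rowSums(W)
  scores <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (sd(x) == 0) return(Inf)
    xt <- x - sum(x * Dg) / sum(Dg)
    denom <- sum(xt^2 * Dg)
    if (denom == 0) return(Inf)
    num <- sum(W * outer(xt, xt, function(a, b) (a - b)^2)) / 2
    num / denom
  }, numeric(1))
  -scores                                 # lower Laplacian score = better
}

cfs_score <- function(X, y = NULL, seed = NULL) {
  p <- ncol(X)
  sds <- apply(X, 2, sd)
  C <- matrix(0, p, p)
  ok <- sds > 0
  if (sum(ok) >= 2) C[ok, ok] <- abs(cor(X[, ok, drop = FALSE]))
  diag(C) <- 0
  scores <- 1 - rowSums(C) / (p - 1)
  scores[!ok] <- -1                       # constant columns are worst
  scores
}

local({
  register_fs_method("fisher", fisher_score, TRUE)
  register_fs_method("mutinffs", mutinffs_score, TRUE)
  register_fs_method("mrmr", mrmr_score, TRUE)
  register_fs_method("relief", relief_score, TRUE)
  register_fs_method("lasso", lasso_score, TRUE)
  register_fs_method("laplacian", laplacian_score, FALSE)
  register_fs_method("cfs", cfs_score, FALSE)
})

#' Score candidate features for selection
#'
#' Runs one registered scorer on the scalarized training-fold feature matrix.
#' Supervised methods (`fisher`, `mutinffs`, `mrmr`, `relief`, `lasso`)
#' require binary labels; unsupervised ones (`laplacian`, `cfs`) ignore them.
#'
#' @param X n_train x p matrix, one column per candidate feature.
#' @param y binary labels (supervised methods only).
#' @param method registered scorer name.
#' @param seed integer seed for stochastic scorers (ReliefF sampling, lasso
#'   internal folds).
#' @return Numeric scores, one per column; higher = better.
#' @export
score_features <- function(X, y = NULL, method, seed = NULL) {
  entry <- .fs_registry[[method]]
  if (is.null(entry))
    stop_config("unknown FS method '%s'; registered: %s", method,
                paste(available_fs_methods(), collapse = ", "))
  X <- as.matrix(X)
  if (entry$supervised) {
    if (is.null(y)) stop_config("method '%s' is supervised and needs labels",
                                method)
    if (length(unique(y)) != 2)
      stop_config("supervised scorers need exactly 2 classes in training data")
    if (nrow(X) < 10) stop_config("need at least 10 training rows")
  }
  s <- entry$fun(X, y, seed)
  if (length(s) != ncol(X)) stop_config("scorer returned wrong length")
  s
}

#' Select the top-k features by score
#'
#' Descending score, deterministic tie-break by feature index.
#'
#' @param scores numeric score per feature.
#' @param k number of features to keep (default 5).
#' @return Integer indices of the chosen features, best first.
#' @export
select_top_k <- function(scores, k = 5) {
  if (any(is.na(scores))) stop_config("NaN/NA feature score")
  k <- min(k, length(scores))
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Merit time course of features
#'
#' Merit of a feature at a window is the fraction of selection events (folds
#' and category pairs) at that window in which the feature was among the
#' chosen top-k; per window the merits sum to k.
#'
#' @param selections list (one element per window) of lists of chosen index
#'   vectors, one per selection event.
#' @param n_features total number of candidate features.
#' @param feature_names optional row names.
#' @return features x windows merit matrix in `[0, 1]`.
#' @export
merit_timecourse <- function(selections, n_features, feature_names = NULL) {
  M <- vapply(selections, function(events) {
    if (!length(events)) stop_config("window without selection events")
    counts <- tabulate(unlist(events), nbins = n_features)
    counts / length(events)
  }, numeric(n_features))
  M <- matrix(M, nrow = n_features)
  if (!is.null(feature_names)) rownames(M) <- feature_names
  M
}
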