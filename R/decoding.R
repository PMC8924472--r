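# Pairwise, 10-fold cross-validated, time-resolved LDA decoding.

#' Build a stratified cross-validation fold plan
#'
#' Every trial lands in exactly one test fold; folds are stratified by
#' category so class proportions per fold stay within one trial of the
#' global proportions. Deterministic given the seed. The same plan is reused
#' across all features within a cross-validation run.
#'
#' @param labels per-trial category labels.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return A `fold_plan`: list with `fold` (fold id per trial) and `n_folds`.
#' @export
make_folds <- function(labels, n_folds = 10, seed = 1L) {
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < n_folds))
    stop_config("every class needs >= %d trials for %d folds (min is %d)",
                n_folds, n_folds, min(counts))
  fold <- integer(n)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  structure(list(fold = fold, n_folds = as.integer(n_folds)),
            class = "fold_plan")
}

#' Shrinkage-regularized LDA: fit on training rows, predict test rows
#'
#' Two-class linear discriminant with the pooled within-class covariance
#' shrunk toward the scaled identity,
#' `S* = (1 - gamma) S + gamma * mean(diag(S)) I`, which keeps the
#' discriminant well-defined even when dimensionality approaches the
#' per-fold trial count. Equal priors (midpoint threshold); deterministic.
#'
#' @param train n_train x p matrix.
#' @param y_train training labels (exactly two classes).
#' @param test n_test x p matrix.
#' @param gamma shrinkage intensity in `[0, 1]` (default 0.05).
#' @return Predicted labels for the test rows.
#' @export
lda_fit_predict <- function(train, y_train, test, gamma = 0.05) {
  cls <- sort(unique(y_train))
  if (length(cls) != 2) stop_config("LDA training set must contain 2 classes")
  a <- train[y_train == cls[1], , drop = FALSE]
  b <- train[y_train == cls[2], , drop = FALSE]
  mu1 <- colMeans(a); mu2 <- colMeans(b)
  Sa <- crossprod(sweep(a, 2, mu1))
  Sb <- crossprod(sweep(b, 2, mu2))
  S <- (Sa + Sb) / (nrow(train) - 2)
  p <- ncol(train)
  S <- (1 - gamma) * S + gamma * mean(diag(S)) * diag(p)
  wvec <- solve(S, mu1 - mu2)
  thr <- sum(wvec * (mu1 + mu2)) / 2
  proj <- as.numeric(test %*% wvec)
  ifelse(proj > thr, cls[1], cls[2])
}

# Stage 3/4/5/6/7/8 for one window and one fold; returns predictions for the
# test rows. `mats` is a named list of trial x (e*f) matrices restricted to
# the pair's trials.
decode_window_fold <- function(mats, fs_method, labels, train_idx, test_idx,
                               e, k_select, gamma, seed) {
  if (is.null(fs_method)) {
    m <- mats[[1]]
    if (ncol(m) > e) m <- equalize_multivalued(m, train_idx, e)
    return(lda_fit_predict(m[train_idx, , drop = FALSE], labels[train_idx],
                           m[test_idx, , drop = FALSE], gamma))
  }
  eq <- lapply(mats, equalize_multivalued, train_idx = train_idx, e = e)
  scal <- vapply(eq, function(m)
    as.numeric(scalarize_for_selection(m, train_idx)),
    numeric(nrow(eq[[1]])))
  scores <- score_features(scal[train_idx, , drop = FALSE],
                           labels[train_idx], fs_method, seed = seed)
  chosen <- select_top_k(scores, k_select)
  comb <- combine_selected(eq[chosen], train_idx, e)
  list(pred = lda_fit_predict(comb[train_idx, , drop = FALSE],
                              labels[train_idx],
                              comb[test_idx, , drop = FALSE], gamma),
       chosen = chosen)
}

#' Decode one category pair across all windows
#'
#' For every window and cross-validation fold: equalize multi-valued features
#' to `n x e` (training-fold PCA), optionally scalarize, score and select the
#' top-k features and recombine them to `n x e` (combination mode), then
#' classify with shrinkage LDA. Accuracy is the pooled proportion of correct
#' test-trial predictions over all folds.
#'
#' @param tensors a single `feature_tensor` (individual-feature mode) or a
#'   named list of them (combination mode).
#' @param pair length-2 vector of category ids.
#' @param folds a `fold_plan` over the pair's trials (see [make_folds()]), or
#'   `NULL` to build one from `seed`.
#' @param fs_method registered FS method name for combination mode, or `NULL`
#'   for individual-feature mode.
#' @param n_folds,k_select,gamma,seed pipeline parameters.
#' @return List with `accuracy` (per window), `centers_ms`, and (combination
#'   mode) `selections`: per window, a list of chosen-index vectors, one per
#'   fold.
#' @export
decode_pair <- function(tensors, pair, folds = NULL, fs_method = NULL,
                        n_folds = 10, k_select = 5, gamma = 0.05, seed = 1L) {
  single <- inherits(tensors, "feature_tensor")
  tlist <- if (single) list(tensors) else tensors
  if (!single && is.null(fs_method))
    stop_config("a list of tensors requires an fs_method")
  labels <- tlist[[1]]$labels
  e <- tlist[[1]]$e
  centers <- tlist[[1]]$centers_ms
  if (length(pair) != 2 || !all(pair %in% labels))
    stop_config("pair must name two categories present in the data")
  idx_pair <- which(labels %in% pair)
  y <- labels[idx_pair]
  if (is.null(folds)) folds <- make_folds(y, n_folds, seed)
  stopifnot(length(folds$fold) == length(idx_pair))

  n_w <- length(centers)
  acc <- numeric(n_w)
  selections <- if (is.null(fs_method)) NULL else vector("list", n_w)
  for (wi in seq_len(n_w)) {
    mats <- lapply(tlist, function(tt)
      tt$values[[wi]][idx_pair, , drop = FALSE])
    correct <- 0L
    sel_events <- list()
    for (fd in seq_len(folds$n_folds)) {
      test_idx <- which(folds$fold == fd)
      train_idx <- which(folds$fold != fd)
      res <- decode_window_fold(mats, fs_method, y, train_idx, test_idx, e,
                                k_select, gamma,
                                seed = derive_seed(seed, wi * 100 + fd))
      if (is.null(fs_method)) {
        correct <- correct + sum(res == y[test_idx])
      } else {
        correct <- correct + sum(res$pred == y[test_idx])
        sel_events[[fd]] <- res$chosen
      }
    }
    acc[wi] <- correct / length(idx_pair)
    if (!is.null(selections)) selections[[wi]] <- sel_events
  }
  list(accuracy = acc, centers_ms = centers, selections = selections)
}

#' Run a time-resolved decoding study over a cohort
#'
#' For every participant and every method: decode all `C(K, 2)` category
#' pairs with 10-fold cross-validation and average the pairwise accuracies,
#' giving one participant x window accuracy matrix per method (chance 0.5).
#'
#' @param cohort list of `epoched_dataset` (e.g. from [generate_cohort()]).
#' @param methods character vector: feature names decode that individual
#'   feature; registered FS method names decode the selected-and-combined
#'   feature set.
#' @param spec a [window_spec()].
#' @param features features available to combination methods (default all
#'   26).
#' @param n_folds,k_select,gamma pipeline parameters.
#' @param seed master seed (folds and stochastic scorers derive from it).
#' @param window_range_ms optional restriction of window centers.
#' @param ... passed to [extract_feature_tensor()].
#' @return Named list of `decoding_curve` objects: `method`, `accuracy`
#'   (participants x windows), `centers_ms`, `chance`, and for combination
#'   methods a `merit` matrix (features x windows) from [merit_timecourse()].
#' @export
run_study <- function(cohort, methods, spec = window_spec(),
                      features = available_features(), n_folds = 10,
                      k_select = 5, gamma = 0.05, seed = 1L,
                      window_range_ms = NULL, ...) {
  stopifnot(length(cohort) >= 1)
  is_fs <- methods %in% available_fs_methods()
  unknown <- !is_fs & !methods %in% available_features()
  if (any(unknown))
    stop_config("unknown method(s): %s", paste(methods[unknown],
                                               collapse = ", "))
  need_feats <- union(methods[!is_fs], if (any(is_fs)) features else NULL)

  per_method_rows <- setNames(vector("list", length(methods)), methods)
  merit_events <- setNames(vector("list", length(methods)), methods)
  centers <- NULL
  for (p in seq_along(cohort)) {
    ds <- cohort[[p]]
    tensors <- setNames(lapply(need_feats, function(fn)
      extract_feature_tensor(ds, fn, spec, window_range_ms = window_range_ms,
                             ...)), need_feats)
    centers <- tensors[[1]]$centers_ms
    K <- length(unique(ds$labels))
    pairs <- utils::combn(sort(unique(ds$labels)), 2)
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      accs <- matrix(0, ncol(pairs), length(centers))
      for (pr in seq_len(ncol(pairs))) {
        pair <- pairs[, pr]
        fseed <- derive_seed(seed, p * 1000 + pr)
        if (is_fs[mi]) {
          res <- decode_pair(tensors[features], pair, fs_method = m,
                             n_folds = n_folds,
                             k_select = k_select, gamma = gamma, seed = fseed)
          merit_events[[m]] <- append_selection_events(merit_events[[m]],
                                                       res$selections)
        } else {
          res <- decode_pair(tensors[[m]], pair, fs_method = NULL,
                             n_folds = n_folds, gamma = gamma, seed = fseed)
        }
        accs[pr, ] <- res$accuracy
      }
      per_method_rows[[m]] <- rbind(per_method_rows[[m]], colMeans(accs))
    }
  }
  n_pairs <- choose(length(unique(cohort[[1]]$labels)), 2)
  out <- lapply(methods, function(m) {
    cv <- structure(list(method = m, accuracy = per_method_rows[[m]],
                         centers_ms = centers, chance = 0.5,
                         n_pairs = n_pairs),
                    class = "decoding_curve")
    if (m %in% available_fs_methods() && !is.null(merit_events[[m]]))
      cv$merit <- merit_timecourse(merit_events[[m]],
                                   n_features = length(features),
                                   feature_names = features)
    cv
  })
  setNames(out, methods)
}

# accumulate per-window selection events across pairs/participants
append_selection_events <- function(acc, selections) {
  if (is.null(acc)) return(selections)
  for (wi in seq_along(selections))
    acc[[wi]] <- c(acc[[wi]], selections[[wi]])
  acc
}
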