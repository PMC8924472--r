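# Feature registry ----------------------------------------------------------

#' Names of the 26 window features
#'
#' Single-valued features yield one value per electrode per window; the
#' multi-valued features yield `w` (`samples`, `hilbert_amplitude`,
#' `hilbert_phase`), `e - 1` (`cross_correlation`) or the wavelet coefficient
#' count (57 for a 50-sample window) values per electrode.
#'
#' @return Character vector of the 26 feature names.
#' @export
available_features <- function() {
  c("mean", "variance", "skewness", "kurtosis", "median",
    "lempel_ziv", "higuchi_fd", "katz_fd", "hurst",
    "sample_entropy", "approx_entropy", "autocorrelation",
    "hjorth_mobility", "hjorth_complexity",
    "mean_frequency", "median_frequency", "zero_crossings", "sef95",
    "signal_power", "power_median_freq", "phase_median_freq",
    "cross_correlation", "wavelet", "hilbert_amplitude", "hilbert_phase",
    "samples")
}

#' Values per electrode for a feature
#'
#' @param feature feature name (see [available_features()]).
#' @param w window length in samples.
#' @param e number of electrodes.
#' @param include_approximation include the wavelet approximation block.
#' @return Integer `f`, the number of values per electrode per window.
#' @export
feature_f <- function(feature, w, e, include_approximation = FALSE) {
  switch(feature,
         samples = , hilbert_amplitude = , hilbert_phase = as.integer(w),
         cross_correlation = as.integer(e - 1),
         wavelet = {
           lev <- suppressWarnings(wavelet_levels(w))
           op <- dwt_operators(w, lev)
           as.integer(sum(op$detail_lengths) +
                        if (include_approximation) nrow(op$approx) else 0L)
         },
         1L)
}

col_vars <- function(M) {
  mu <- colMeans(M)
  colMeans(M^2) - mu^2
}

# Vectorized extractors: take a w x m matrix of window columns, return an
# f x m matrix. The loop-based scalar ops fall back to vapply per column.
feature_block <- function(feature, M, fs, lag, include_approximation) {
  w <- nrow(M)
  switch(feature,
    mean = rbind(colMeans(M)),
    variance = rbind(col_vars(M) * w / (w - 1)),
    skewness = {
      mu <- colMeans(M); D <- sweep(M, 2, mu)
      m2 <- colMeans(D^2); m3 <- colMeans(D^3)
      out <- ifelse(m2 > 0, m3 / m2^1.5, 0)
      rbind(out)
    },
    kurtosis = {
      mu <- colMeans(M); D <- sweep(M, 2, mu)
      m2 <- colMeans(D^2); m4 <- colMeans(D^4)
      rbind(ifelse(m2 > 0, m4 / m2^2, 0))
    },
    median = rbind(apply(M, 2, median)),
    lempel_ziv = rbind(apply(M, 2, lz_complexity)),
    higuchi_fd = rbind(apply(M, 2, function(x) fractal_dimensions(x)$higuchi)),
    katz_fd = rbind(apply(M, 2, function(x) fractal_dimensions(x)$katz)),
    hurst = rbind(apply(M, 2, hurst_exponent)),
    sample_entropy = rbind(apply(M, 2, function(x) entropies(x)$sample_entropy)),
    approx_entropy = rbind(apply(M, 2,
                                 function(x) entropies(x)$approximate_entropy)),
    autocorrelation = {
      a <- M[seq_len(w - lag), , drop = FALSE]
      b <- M[(lag + 1):w, , drop = FALSE]
      va <- col_vars(a); vb <- col_vars(b)
      cov <- colMeans(a * b) - colMeans(a) * colMeans(b)
      rbind(ifelse(va > 0 & vb > 0, cov / sqrt(va * vb), 0))
    },
    hjorth_mobility = {
      D <- diff(M)
      v0 <- col_vars(M) * w / (w - 1)
      v1 <- col_vars(D) * (w - 1) / (w - 2)
      rbind(ifelse(v0 > 0, sqrt(v1 / v0), 0))
    },
    hjorth_complexity = {
      D1 <- diff(M); D2 <- diff(D1)
      v0 <- col_vars(M) * w / (w - 1)
      v1 <- col_vars(D1) * (w - 1) / (w - 2)
      v2 <- col_vars(D2) * (w - 2) / (w - 3)
      mob <- ifelse(v0 > 0, sqrt(v1 / v0), 0)
      rbind(ifelse(v1 > 0 & mob > 0, sqrt(v2 / v1) / mob, 0))
    },
    mean_frequency = spectral_block(M, fs)["mean_freq", , drop = FALSE],
    median_frequency = spectral_block(M, fs)["median_freq", , drop = FALSE],
    zero_crossings = spectral_block(M, fs)["zero_cross", , drop = FALSE],
    sef95 = spectral_block(M, fs)["sef95", , drop = FALSE],
    signal_power = spectral_block(M, fs)["total_power", , drop = FALSE],
    power_median_freq = spectral_block(M, fs)["power_at_medfreq", ,
                                              drop = FALSE],
    phase_median_freq = spectral_block(M, fs)["phase_at_medfreq", ,
                                              drop = FALSE],
    wavelet = {
      lev <- suppressWarnings(wavelet_levels(w))
      op <- dwt_operators(w, lev)
      B <- do.call(rbind, lapply(op$ops, `[[`, "detail"))
      if (include_approximation) B <- rbind(B, op$approx)
      B %*% M
    },
    hilbert_amplitude = hilbert_block(M)$amplitude,
    hilbert_phase = hilbert_block(M)$phase,
    samples = M,
    stop_config("unknown feature '%s'; valid names: %s", feature,
                paste(available_features(), collapse = ", "))
  )
}

# All seven spectral summaries for every column at once (cached per call).
spectral_block <- function(M, fs) {
  w <- nrow(M); m <- ncol(M)
  Mc <- sweep(M, 2, colMeans(M))
  X <- mvfft(Mc)
  kmax <- w %/% 2
  freq <- seq_len(kmax) * fs / w
  P <- 2 * Mod(X[seq_len(kmax) + 1, , drop = FALSE])^2 / w^2
  if (w %% 2 == 0) P[kmax, ] <- P[kmax, ] / 2
  tot <- colSums(P)
  out <- matrix(0, 7, m,
                dimnames = list(c("mean_freq", "median_freq", "zero_cross",
                                  "sef95", "total_power", "power_at_medfreq",
                                  "phase_at_medfreq"), NULL))
  out["total_power", ] <- colMeans(Mc^2)
  live <- tot > 0
  if (any(live)) {
    CP <- apply(P[, live, drop = FALSE], 2, cumsum) /
      rep(tot[live], each = kmax)
    med_i <- apply(CP >= 0.5, 2, which.max)
    sef_i <- apply(CP >= 0.95, 2, which.max)
    out["mean_freq", live] <- colSums(P[, live, drop = FALSE] * freq) /
      tot[live]
    out["median_freq", live] <- freq[med_i]
    out["sef95", live] <- freq[sef_i]
    li <- which(live)
    out["power_at_medfreq", li] <- P[cbind(med_i, seq_along(li))]
    out["phase_at_medfreq", li] <-
      Arg(X[cbind(med_i + 1, li)])
  }
  for (j in seq_len(m)) {
    s <- sign(Mc[, j]); s <- s[s != 0]
    out["zero_cross", j] <- if (length(s) > 1) sum(diff(s) != 0) else 0
  }
  out
}

hilbert_block <- function(M) {
  w <- nrow(M)
  h <- numeric(w)
  if (w %% 2 == 0) { h[c(1, w / 2 + 1)] <- 1; h[2:(w / 2)] <- 2 }
  else { h[1] <- 1; h[2:((w + 1) / 2)] <- 2 }
  Z <- mvfft(mvfft(M) * h, inverse = TRUE) / w
  ph <- Arg(Z)
  ph[ph == -pi] <- pi
  list(amplitude = Mod(Z), phase = ph)
}

# Extraction ----------------------------------------------------------------

#' Extract one feature across all sliding windows
#'
#' Applies the named per-window feature electrode- and trial-wise after
#' per-trial baseline correction (mean over the pre-stimulus span removed
#' from every trial and electrode). Output columns are electrode-major:
#' the `f` values of electrode 1, then electrode 2, and so on.
#'
#' @param dataset an `epoched_dataset`.
#' @param feature one of [available_features()].
#' @param spec a [window_spec()].
#' @param lag autocorrelation lag in samples (default: 10 ms at `fs`).
#' @param include_approximation include the wavelet approximation block.
#' @param baseline apply baseline correction first (set `FALSE` if already
#'   corrected).
#' @param window_range_ms optional length-2 vector restricting window centers
#'   to a ms interval (an efficiency device for targeted analyses).
#' @return A `feature_tensor`: list with `feature`, `centers_ms`, `values`
#'   (list of trial x (e*f) matrices, one per window), `f`, `e`, `n`, and a
#'   per-window count of degenerate (zero-variance) window columns in
#'   `flags`.
#' @export
extract_feature_tensor <- function(dataset, feature, spec = window_spec(),
                                   lag = NULL, include_approximation = FALSE,
                                   baseline = TRUE, window_range_ms = NULL) {
  if (!feature %in% available_features())
    stop_config("unknown feature '%s'; valid names: %s", feature,
                paste(available_features(), collapse = ", "))
  if (baseline) dataset <- baseline_correct(dataset)
  sw <- sliding_windows(dataset, spec)
  keep <- seq_along(sw$centers_ms)
  if (!is.null(window_range_ms))
    keep <- which(sw$centers_ms >= window_range_ms[1] &
                    sw$centers_ms <= window_range_ms[2])
  n <- dim(dataset$data)[1]
  e <- dim(dataset$data)[2]
  w <- sw$w
  if (is.null(lag)) lag <- max(1L, as.integer(round_half_up(10 * dataset$fs /
                                                              1000)))
  f <- feature_f(feature, w, e, include_approximation)
  values <- vector("list", length(keep))
  flags <- integer(length(keep))
  for (ii in seq_along(keep)) {
    wi <- keep[ii]
    S <- dataset$data[, , sw$idx[wi, ], drop = FALSE]   # n x e x w
    if (feature == "cross_correlation") {
      out <- matrix(0, n, e * f)
      for (tr in seq_len(n)) {
        blk <- matrix(S[tr, , ], e, w)
        sds <- apply(blk, 1, sd)
        C <- matrix(0, e, e)
        ok <- sds > 0
        if (sum(ok) >= 2) C[ok, ok] <- cor(t(blk[ok, , drop = FALSE]))
        for (j in seq_len(e)) out[tr, (j - 1) * f + seq_len(f)] <- C[j, -j]
        flags[ii] <- flags[ii] + sum(!ok)
      }
    } else {
      M <- aperm(S, c(3, 1, 2))
      dim(M) <- c(w, n * e)
      flags[ii] <- sum(col_vars(M) == 0)
      V <- feature_block(feature, M, dataset$fs, lag, include_approximation)
      dim(V) <- c(f, n, e)
      out <- aperm(V, c(2, 1, 3))       # trial x f x e: electrode-major cols
      dim(out) <- c(n, f * e)
    }
    values[[ii]] <- out
  }
  structure(list(feature = feature, centers_ms = sw$centers_ms[keep],
                 values = values, f = f, e = e, n = n, w = w,
                 labels = dataset$labels, flags = flags),
            class = "feature_tensor")
}
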