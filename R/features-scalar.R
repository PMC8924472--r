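# Single-valued window features. Each takes one numeric window (w samples)
# and returns the stated statistic; degenerate (zero-variance) windows return
# the documented sentinel instead of NaN, with attr(x, "degenerate") = TRUE
# where the op defines a flag.

flag_degenerate <- function(x) {
  attr(x, "degenerate") <- TRUE
  x
}

#' Window moments and median
#'
#' Sample variance uses the n-1 denominator; skewness and kurtosis are the
#' standardized 3rd and 4th central moments (kurtosis raw, not excess; a
#' Gaussian gives 3). A zero-variance window returns 0 for both, flagged.
#'
#' @param x numeric window of at least 4 samples.
#' @return Named list: `mean`, `variance`, `skewness`, `kurtosis`, `median`.
#' @export
moments_and_median <- function(x) {
  w <- length(x)
  stopifnot(w >= 4, all(is.finite(x)))
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  out <- list(mean = mu, variance = sum(d^2) / (w - 1),
              skewness = 0, kurtosis = 0, median = median(x))
  if (m2 > 0) {
    out$skewness <- mean(d^3) / m2^1.5
    out$kurtosis <- mean(d^4) / m2^2
  } else {
    out <- flag_degenerate(out)
  }
  out
}

#' Lempel-Ziv (LZ76) complexity of a window
#'
#' The window is binarized against its own median (`x >= median -> 1`) and
#' parsed with the exhaustive LZ76 scheme; the returned value is the phrase
#' count, with no length normalization. Constant windows binarize to all ones
#' (2 phrases). Invariant to positive affine rescaling.
#'
#' @param x numeric window (>= 2 samples).
#' @return Integer phrase count.
#' @export
lz_complexity <- function(x) {
  stopifnot(length(x) >= 2)
  s <- as.integer(x >= median(x))
  lz76_phrases(s)
}

# Kaspar-Schuster exhaustive parsing phrase count of a 0/1 sequence.
lz76_phrases <- function(s) {
  n <- length(s)
  c_n <- 1L; l <- 1L; i <- 0L; k <- 1L; k_max <- 1L
  while (TRUE) {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) { c_n <- c_n + 1L; break }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        c_n <- c_n + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  c_n
}

#' Higuchi and Katz fractal dimensions
#'
#' Katz: `FD = log10(m) / (log10(m) + log10(d/L))` with `L` the summed
#' Euclidean lengths of successive (index, value) points, `d` the maximum
#' distance from the first point and `m = w - 1` steps; the window is scaled
#' to unit SD first so the estimate does not depend on amplitude units, and
#' a straight line gives exactly 1. Higuchi: slope of `log(curve length)`
#' against `log(1/k)` over `k = 1..kmax` (default 8, reduced to
#' `max(2, w %/% 5)` for short windows). Constant windows return 1 for both,
#' flagged.
#'
#' @param x numeric window (>= 10 samples for the Higuchi estimate).
#' @param kmax maximum Higuchi delay.
#' @return Named list `higuchi`, `katz`.
#' @export
fractal_dimensions <- function(x, kmax = 8) {
  w <- length(x)
  stopifnot(w >= 10)
  if (sd(x) == 0)
    return(flag_degenerate(list(higuchi = 1, katz = 1)))
  z <- x / sd(x)                 # unit-free Katz geometry
  dz <- diff(z)
  L <- sum(sqrt(1 + dz^2))
  d <- max(sqrt((seq_len(w) - 1)^2 + (z - z[1])^2)[-1])
  m <- w - 1
  katz <- log10(m) / (log10(m) + log10(d / L))

  kmax <- min(kmax, max(2, w %/% 5))
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m0 in seq_len(k)) {
      idx <- seq(m0, w, by = k)
      ni <- length(idx) - 1
      lm[m0] <- sum(abs(diff(x[idx]))) * (w - 1) / (ni * k) / k
    }
    lk[k] <- mean(lm)
  }
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax))), log(lk))
  list(higuchi = unname(fit$coefficients[2]), katz = katz)
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' Log-log regression of the mean rescaled range over dyadic segment lengths
#' (`w, w/2, w/4, ...`, all >= 8), with the Anis-Lloyd-Peters small-sample
#' correction (the estimate is 0.5 plus the deviation of the empirical R/S
#' slope from the expected null slope), clipped to `[0, 1]`. Zero-variance
#' segments are skipped; an all-degenerate window returns 0.5, flagged.
#'
#' @param x numeric window (>= 16 samples).
#' @return Hurst estimate in `[0, 1]`.
#' @export
hurst_exponent <- function(x) {
  w <- length(x)
  stopifnot(w >= 16)
  lens <- c()
  L <- w
  while (L >= 8) { lens <- c(lens, L); L <- L %/% 2 }
  rs <- rep(NA_real_, length(lens))
  for (i in seq_along(lens)) {
    L <- lens[i]
    nseg <- w %/% L
    vals <- c()
    for (s in seq_len(nseg)) {
      seg <- x[((s - 1) * L + 1):(s * L)]
      sdv <- sd(seg)
      if (sdv == 0) next
      cum <- cumsum(seg - mean(seg))
      vals <- c(vals, (max(cum) - min(cum)) / sdv)
    }
    if (length(vals)) rs[i] <- mean(vals)
  }
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) return(flag_degenerate(0.5))
  fit <- stats::lm.fit(cbind(1, log(lens[ok])), log(rs[ok]))
  null_fit <- stats::lm.fit(cbind(1, log(lens[ok])),
                            log(expected_rs(lens[ok])))
  h <- 0.5 + unname(fit$coefficients[2]) - unname(null_fit$coefficients[2])
  min(max(h, 0), 1)
}

# Anis-Lloyd expected R/S of an i.i.d. series of length n, with the Peters
# finite-sample factor.
expected_rs <- function(n) {
  vapply(n, function(nn) {
    i <- seq_len(nn - 1)
    (nn - 0.5) / nn * sum(sqrt((nn - i) / i)) / sqrt(pi * nn / 2)
  }, numeric(1))
}

# Chebyshev-distance template match counts for entropy estimators.
template_counts <- function(x, m, r) {
  n <- length(x) - m + 1
  emb <- sapply(seq_len(m), function(j) x[j:(j + n - 1)])
  if (is.null(dim(emb))) emb <- matrix(emb, ncol = m)
  counts <- integer(n)
  for (i in seq_len(n)) {
    dmax <- rep(0, n)
    for (j in seq_len(m)) dmax <- pmax(dmax, abs(emb[, j] - emb[i, j]))
    counts[i] <- sum(dmax <= r)            # includes self
  }
  counts
}

#' Sample and approximate entropy
#'
#' Both use embedding dimension `m = 2` and tolerance `r = 0.2 * SD(window)`
#' under the Chebyshev distance. Sample entropy excludes self-matches
#' (`-ln(A/B)`); when no m+1 template pairs match, A is replaced by 0.5
#' (small-count correction) and the result flagged. Approximate entropy is
#' the Pincus phi-difference including self-matches. Zero-SD windows return
#' 0 for both, flagged.
#'
#' @param x numeric window (>= 10 samples).
#' @param m embedding dimension.
#' @param r_factor tolerance as a multiple of the window SD.
#' @return Named list `sample_entropy`, `approximate_entropy`.
#' @export
entropies <- function(x, m = 2, r_factor = 0.2) {
  w <- length(x)
  stopifnot(w >= 10)
  sdx <- sd(x)
  if (sdx == 0)
    return(flag_degenerate(list(sample_entropy = 0, approximate_entropy = 0)))
  r <- r_factor * sdx

  # SampEn over the N - m templates common to both lengths (the final
  # m-template is excluded, per the standard definition)
  cm <- template_counts(x[seq_len(w - 1)], m, r)   # counts incl self
  cm1 <- template_counts(x, m + 1, r)
  B <- sum(cm - 1L) / 2
  A <- sum(cm1 - 1L) / 2
  flagged <- FALSE
  if (B == 0) { sampen <- 0; flagged <- TRUE }
  else if (A == 0) { sampen <- -log(0.5 / B); flagged <- TRUE }
  else sampen <- -log(A / B)

  phi <- function(mm) {
    cc <- template_counts(x, mm, r)
    mean(log(cc / (w - mm + 1)))
  }
  apen <- phi(m) - phi(m + 1)
  out <- list(sample_entropy = sampen, approximate_entropy = apen)
  if (flagged) out <- flag_degenerate(out)
  out
}

#' Lagged autocorrelation of a window
#'
#' Pearson correlation of the window with its lag-shifted copy over the
#' `w - lag` overlapping samples. Zero variance in either segment gives 0,
#' flagged.
#'
#' @param x numeric window.
#' @param lag lag in samples, `1 <= lag <= w/2`.
#' @return Correlation in `[-1, 1]`.
#' @export
autocorrelation <- function(x, lag) {
  w <- length(x)
  stopifnot(lag >= 1, lag <= w / 2)
  a <- x[seq_len(w - lag)]
  b <- x[(lag + 1):w]
  if (sd(a) == 0 || sd(b) == 0) return(flag_degenerate(0))
  cor(a, b)
}

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(diff(x)) / var(x))` (spectral width proxy);
#' complexity is the mobility of the first difference divided by the mobility
#' of the signal. Zero-variance windows return 0 for both, flagged.
#'
#' @param x numeric window (>= 3 samples).
#' @return Named list `mobility`, `complexity`.
#' @export
hjorth <- function(x) {
  stopifnot(length(x) >= 3)
  v0 <- var(x)
  if (v0 == 0) return(flag_degenerate(list(mobility = 0, complexity = 0)))
  d1 <- diff(x)
  v1 <- var(d1)
  mob <- sqrt(v1 / v0)
  v2 <- var(diff(d1))
  comp <- if (v1 == 0) 0 else sqrt(v2 / v1) / mob
  list(mobility = mob, complexity = comp)
}

#' Spectral summary of a window
#'
#' Computed from the raw (rectangular-window) periodogram of the mean-removed
#' window: power-weighted mean frequency; median frequency (smallest
#' frequency at which cumulative power reaches 50% of the total) and the 95%
#' spectral edge; zero-crossing count of the mean-removed signal; total power
#' (mean squared amplitude); and the power and phase of the discrete spectrum
#' bin nearest the median frequency. Single-sided bin powers are scaled so a
#' unit-amplitude on-bin sinusoid has total power 0.5. A zero-power window
#' returns zeros, flagged.
#'
#' @param x numeric window (>= 8 samples).
#' @param fs sampling rate in Hz.
#' @return Named list `mean_freq`, `median_freq`, `zero_cross`, `sef95`,
#'   `total_power`, `power_at_medfreq`, `phase_at_medfreq`.
#' @export
spectral_summary <- function(x, fs) {
  w <- length(x)
  stopifnot(w >= 8)
  xc <- x - mean(x)
  if (all(xc == 0))
    return(flag_degenerate(list(mean_freq = 0, median_freq = 0,
                                zero_cross = 0, sef95 = 0, total_power = 0,
                                power_at_medfreq = 0, phase_at_medfreq = 0)))
  X <- fft(xc)
  kmax <- w %/% 2
  k <- seq_len(kmax)
  freq <- k * fs / w
  p <- 2 * Mod(X[k + 1])^2 / w^2
  if (w %% 2 == 0) p[kmax] <- p[kmax] / 2      # Nyquist bin is not doubled
  tot <- sum(p)
  cum <- cumsum(p) / tot
  medf <- freq[which(cum >= 0.5)[1]]
  sef <- freq[which(cum >= 0.95)[1]]
  sgn <- sign(xc)
  sgn <- sgn[sgn != 0]
  zc <- sum(diff(sgn) != 0)
  kb <- which.min(abs(freq - medf))
  list(mean_freq = sum(freq * p) / tot, median_freq = medf, zero_cross = zc,
       sef95 = sef, total_power = mean(xc^2),
       power_at_medfreq = p[kb], phase_at_medfreq = Arg(X[kb + 1]))
}
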