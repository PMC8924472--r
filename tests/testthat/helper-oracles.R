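# Independent brute-force oracles. These deliberately use a different route
# than the package implementation (plain loops, explicit DFT sums, direct
# definitions) so the two can be compared on small instances.

# exhaustive LZ76 parsing by literal substring search: the next phrase is
# the shortest prefix of the remainder not contained in the previously seen
# text (all of it, up to but excluding the phrase's final character).
naive_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  i <- 1L; phrases <- 0L
  while (i <= n) {
    k <- 1
    repeat {
      if (i + k - 1 > n) break
      cand <- substr(s, i, i + k - 1)
      hist <- substr(s, 1, i + k - 2)
      if (!grepl(cand, hist, fixed = TRUE)) break
      k <- k + 1
    }
    phrases <- phrases + 1L
    i <- i + as.integer(k)
  }
  phrases
}

naive_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  list(mean = mu,
       variance = sum((x - mu)^2) / (n - 1),
       skewness = if (m2 == 0) 0 else (sum((x - mu)^3) / n) / m2^(3 / 2),
       kurtosis = if (m2 == 0) 0 else (sum((x - mu)^4) / n) / m2^2,
       median = {
         s <- sort(x)
         if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
       })
}

# sample/approximate entropy by direct double loops over templates
naive_entropies <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  cheb <- function(i, j, mm) max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
  A <- 0; B <- 0
  for (i in 1:(n - m)) for (j in 1:(n - m)) {
    if (i == j) next
    if (cheb(i, j, m) <= r) B <- B + 1
    if (cheb(i, j, m + 1) <= r) A <- A + 1
  }
  A <- A / 2; B <- B / 2
  sampen <- if (B == 0) 0 else if (A == 0) -log(0.5 / B) else -log(A / B)
  phi <- function(mm) {
    nt <- n - mm + 1
    mean(sapply(1:nt, function(i)
      log(sum(sapply(1:nt, function(j) cheb(i, j, mm) <= r)) / nt)))
  }
  list(sample_entropy = sampen,
       approximate_entropy = phi(m) - phi(m + 1))
}

# spectral summaries from explicit DFT sums
naive_spectral <- function(x, fs) {
  w <- length(x)
  xc <- x - sum(x) / w
  kmax <- w %/% 2
  Xr <- sapply(1:kmax, function(k) sum(xc * cos(-2 * pi * k * (0:(w - 1)) / w)))
  Xi <- sapply(1:kmax, function(k) sum(xc * sin(-2 * pi * k * (0:(w - 1)) / w)))
  p <- 2 * (Xr^2 + Xi^2) / w^2
  if (w %% 2 == 0) p[kmax] <- p[kmax] / 2
  freq <- (1:kmax) * fs / w
  tot <- sum(p)
  cum <- cumsum(p) / tot
  medf <- freq[which(cum >= 0.5)[1]]
  kb <- which.min(abs(freq - medf))
  sgn <- sign(xc); sgn <- sgn[sgn != 0]
  list(mean_freq = sum(freq * p) / tot, median_freq = medf,
       zero_cross = sum(diff(sgn) != 0), sef95 = freq[which(cum >= 0.95)[1]],
       total_power = sum(xc^2) / w, power_at_medfreq = p[kb],
       phase_at_medfreq = atan2(Xi[kb], Xr[kb]))
}

# PCA via eigen-decomposition of the covariance matrix
naive_pca <- function(X, k) {
  ctr <- colMeans(X)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  list(center = ctr, loadings = eg$vectors[, seq_len(k), drop = FALSE],
       explained_variance = eg$values[seq_len(k)])
}

# JZS BF10 by integrating the noncentral-t likelihood against the Cauchy
# effect-size prior (a different integral than the package's g-mixture).
naive_jzs_bf <- function(tstat, neff, nu, rscale = sqrt(2) / 2) {
  # dt(ncp) emits precision warnings far in the tails; harmless here
  num <- suppressWarnings(stats::integrate(function(delta)
    stats::dt(tstat, df = nu, ncp = delta * sqrt(neff)) *
      stats::dcauchy(delta, 0, rscale),
    -Inf, Inf, rel.tol = 1e-10)$value)
  num / stats::dt(tstat, df = nu)
}

# binomial half-width of the 95% chance band for a mean of n_units
# independent Bernoulli(0.5) predictions
chance_band_half <- function(n_units) 1.96 * sqrt(0.25 / n_units)
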