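# Bayes-factor evidence, decoding-curve parameters, and the
# decoding-behavior correlation with permutation testing and pFDR.

#' JZS Bayes factor t test
#'
#' Bayes factor (BF10, evidence for a difference) for a one- or two-sample
#' t test under the Jeffreys-Zellner-Siow prior: a Cauchy prior with scale
#' `rscale` on the standardized effect size, evaluated through the standard
#' g-prior integral by adaptive quadrature.
#'
#' @param x,y numeric samples (`y = NULL` for one-sample against zero).
#' @param paired treat `x` and `y` as paired (differences tested against 0).
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return BF10 as a positive scalar.
#' @export
jzs_bf_ttest <- function(x, y = NULL, paired = FALSE, rscale = sqrt(2) / 2) {
  if (!is.null(y) && paired) {
    stopifnot(length(x) == length(y))
    x <- x - y
    y <- NULL
  }
  if (is.null(y)) {
    n <- length(x)
    stopifnot(n >= 2)
    if (sd(x) == 0) stop_config("zero within-sample variance")
    tstat <- mean(x) / (sd(x) / sqrt(n))
    neff <- n
    nu <- n - 1
  } else {
    n1 <- length(x); n2 <- length(y)
    stopifnot(n1 >= 2, n2 >= 2)
    v1 <- var(x); v2 <- var(y)
    if (v1 == 0 && v2 == 0) stop_config("zero within-sample variance")
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    neff <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
  }
  jzs_bf_from_t(tstat, neff, nu, rscale)
}

# BF10 from the t statistic: marginal likelihood under the JZS prior over
# the null likelihood. The effect-size prior Cauchy(0, r) is an inverse-
# gamma(1/2, r^2/2) scale mixture of normals, giving the 1-D integral below.
jzs_bf_from_t <- function(tstat, neff, nu, rscale = sqrt(2) / 2) {
  integrand <- function(g) {
    vg <- 1 + neff * g * rscale^2
    exp(-0.5 * log(vg) -
          (nu + 1) / 2 * log1p(tstat^2 / (vg * nu)) -
          1.5 * log(g) - 1 / (2 * g) - 0.5 * log(2 * pi))
  }
  num <- integrate(integrand, 0, Inf, rel.tol = 1e-9,
                   stop.on.error = FALSE)$value
  den <- exp(-(nu + 1) / 2 * log1p(tstat^2 / nu))
  num / den
}

#' Map a Bayes factor to an evidence category
#'
#' BF10 > 10: strong evidence for a difference; > 3: moderate; < 1/10 and
#' < 1/3 the same for the null; anything between 1/3 and 3 is insufficient.
#'
#' @param bf numeric BF10 values.
#' @return Character vector in `{strong_H1, moderate_H1, insufficient,
#'   moderate_H0, strong_H0}`.
#' @export
bf_evidence <- function(bf) {
  ifelse(bf > 10, "strong_H1",
         ifelse(bf > 3, "moderate_H1",
                ifelse(bf < 1 / 10, "strong_H0",
                       ifelse(bf < 1 / 3, "moderate_H0", "insufficient"))))
}

#' Bayes-factor evidence series against the pre-stimulus baseline
#'
#' Per participant, the baseline is the mean decoding accuracy over
#' pre-stimulus windows; each post-stimulus window's accuracies (one value
#' per participant) are compared against that baseline vector with the
#' unpaired JZS Bayes-factor t test. No multiplicity correction is applied.
#'
#' @param curve a `decoding_curve`.
#' @param baseline_window ms pair delimiting the baseline (default
#'   `c(-200, 0)`).
#' @return A `bayes_series`: list with `centers_ms` (post-stimulus windows),
#'   `bf`, and `evidence` categories.
#' @export
evidence_series <- function(curve, baseline_window = c(-200, 0)) {
  ctr <- curve$centers_ms
  pre <- ctr >= baseline_window[1] & ctr <= baseline_window[2]
  post <- ctr > 0
  if (!any(pre)) stop_config("curve has no pre-stimulus baseline windows")
  baseline <- rowMeans(curve$accuracy[, pre, drop = FALSE])
  bf <- vapply(which(post), function(wi)
    jzs_bf_ttest(curve$accuracy[, wi], baseline), numeric(1))
  structure(list(centers_ms = ctr[post], bf = bf,
                 evidence = bf_evidence(bf)),
            class = "bayes_series")
}

#' Decoding-curve parameters per participant
#'
#' Over the post-stimulus windows: maximum and mean accuracy, time of
#' maximum (first window on ties), and onset = first window of a run of at
#' least `sustain` consecutive windows above chance (NA if never sustained).
#'
#' @param curve a `decoding_curve`.
#' @param chance chance level (default 0.5).
#' @param sustain run length required for the onset (default 5 windows,
#'   25 ms at a 5 ms step).
#' @return data.frame with one row per participant: `max_acc`, `mean_acc`,
#'   `t_max_ms`, `t_onset_ms`.
#' @export
curve_parameters <- function(curve, chance = 0.5, sustain = 5) {
  post <- curve$centers_ms > 0
  if (!any(post)) stop_config("no post-stimulus windows")
  ctr <- curve$centers_ms[post]
  A <- curve$accuracy[, post, drop = FALSE]
  res <- t(apply(A, 1, function(a) {
    above <- a > chance
    onset <- NA_real_
    r <- rle(above)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= sustain)
    if (length(hit))
      onset <- ctr[ends[hit[1]] - r$lengths[hit[1]] + 1]
    c(max_acc = max(a), mean_acc = mean(a),
      t_max_ms = ctr[which.max(a)], t_onset_ms = onset)
  }))
  as.data.frame(res)
}

#' Across-participant Spearman correlation between decoding and reaction time
#'
#' At every window, the rank correlation (average-rank ties) between the
#' participants' decoding accuracies and their mean reaction times.
#'
#' @param curve a `decoding_curve` (one accuracy row per participant).
#' @param rt mean reaction time per participant (ms).
#' @return A `behavior_corr_series`: list with `centers_ms` and `rho` (NA
#'   with a flag when the RT vector is constant).
#' @export
brain_behavior_correlation <- function(curve, rt) {
  stopifnot(length(rt) == nrow(curve$accuracy))
  if (length(rt) < 5) stop_config("need >= 5 participants for correlation")
  if (sd(rt) == 0) {
    out <- list(centers_ms = curve$centers_ms,
                rho = rep(NA_real_, length(curve$centers_ms)))
    attr(out, "degenerate") <- TRUE
    return(structure(out, class = "behavior_corr_series"))
  }
  rho <- apply(curve$accuracy, 2, function(a)
    cor(a, rt, method = "spearman"))
  structure(list(centers_ms = curve$centers_ms, rho = rho),
            class = "behavior_corr_series")
}

#' Permutation p-values for the decoding-behavior correlation
#'
#' The null distribution at each window is built from Spearman correlations
#' with the reaction-time vector randomly permuted across participants
#' (`n_perm` seeded permutations, shared across windows). The p-value is
#' one-sided in the observed direction with add-one smoothing:
#' `(1 + #{null >= rho}) / (n_perm + 1)` for positive observed rho, and the
#' mirrored count for negative.
#'
#' @param series a `behavior_corr_series` from
#'   [brain_behavior_correlation()].
#' @param curve the `decoding_curve` used for the series.
#' @param rt per-participant mean reaction times.
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param seed integer seed.
#' @return The series with `p` added.
#' @export
permutation_pvalues <- function(series, curve, rt, n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 100)
  n <- length(rt)
  rt_rank <- rank(rt)
  perms <- with_seed(seed, replicate(n_perm, sample(rt_rank)))
  acc_ranks <- apply(curve$accuracy, 2, rank)        # n x W
  # Spearman rho = Pearson on ranks; compute null matrix W x n_perm at once
  cr <- function(R, P) {
    Rc <- sweep(R, 2, colMeans(R))
    Pc <- sweep(P, 2, colMeans(P))
    crossprod(Rc, Pc) / outer(sqrt(colSums(Rc^2)), sqrt(colSums(Pc^2)))
  }
  null_rho <- cr(acc_ranks, perms)                    # W x n_perm
  p <- vapply(seq_along(series$rho), function(wi) {
    obs <- series$rho[wi]
    if (is.na(obs)) return(NA_real_)
    nd <- null_rho[wi, ]
    if (obs >= 0) (1 + sum(nd >= obs)) / (n_perm + 1)
    else (1 + sum(nd <= obs)) / (n_perm + 1)
  }, numeric(1))
  series$p <- p
  series
}

#' Positive false-discovery-rate correction
#'
#' Storey q-values with a fixed pi0 estimate at `lambda = 0.5`; when the
#' estimate is unstable (short series or no p-values above lambda), falls
#' back to Benjamini-Hochberg (noted in `attr(, "method")`). Significance is
#' declared where `q < alpha`.
#'
#' @param p p-values in `(0, 1]` (NAs tolerated, never significant).
#' @param lambda pi0 tuning constant (default 0.5).
#' @param alpha significance threshold on q (default 0.05).
#' @param directional set `TRUE` when `p` are one-sided in the observed
#'   direction (as returned by [permutation_pvalues()]); such p-values are
#'   the smaller of the two tails and concentrate below 0.5 even under the
#'   null, so they are first converted to their two-sided equivalent
#'   (`min(1, 2p)`) to restore the uniform-null assumption the correction
#'   relies on.
#' @return List with `q`, `significant`, `pi0`; `attr(, "method")` records
#'   `"storey"` or `"BH"`.
#' @export
fdr_correct <- function(p, lambda = 0.5, alpha = 0.05, directional = FALSE) {
  if (directional) p <- pmin(1, 2 * p)
  ok <- !is.na(p)
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  pi0 <- min(1, sum(p[ok] > lambda) / ((1 - lambda) * m))
  method <- "storey"
  if (m < 20 || sum(p[ok] > lambda) == 0) {
    method <- "BH"
    pi0 <- 1
  }
  q[ok] <- pi0 * p.adjust(p[ok], method = "BH")
  q <- pmin(q, 1)
  out <- list(q = q, significant = !is.na(q) & q < alpha, pi0 = pi0)
  attr(out, "method") <- method
  out
}
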