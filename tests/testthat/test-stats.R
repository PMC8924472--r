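test_that("JZS Bayes factor matches the noncentral-t quadrature oracle", {
  for (tt in c(0, 0.8, 1.5, 2.5, 4)) {
    for (n in c(8, 12, 20)) {
      got <- eegdecode:::jzs_bf_from_t(tt, neff = n / 2, nu = 2 * n - 2)
      ora <- naive_jzs_bf(tt, neff = n / 2, nu = 2 * n - 2)
      expect_equal(got, ora, tolerance = 5e-4)
    }
  }
})

test_that("JZS Bayes factor behaves like evidence", {
  set.seed(50)
  x <- rnorm(10)
  x <- (x - mean(x)) / sd(x)          # t exactly 0
  expect_lt(jzs_bf_ttest(x, x + 0), 1)
  # strictly increasing in |t| at fixed n
  bfs <- sapply(seq(0, 4, by = 0.5), function(tt)
    eegdecode:::jzs_bf_from_t(tt, 5, 18))
  expect_true(all(diff(bfs) > 0))
  # 5 pooled SDs apart, n = 10 per group: strong evidence
  a <- rnorm(10); a <- (a - mean(a)) / sd(a)
  expect_gt(jzs_bf_ttest(a + 5, a), 10)
  expect_error(jzs_bf_ttest(rep(1, 5), rep(2, 5)), "variance")
  # paired test reduces to the one-sample test on differences
  y <- rnorm(10)
  expect_equal(jzs_bf_ttest(y + 0.5, y, paired = TRUE),
               jzs_bf_ttest(y + 0.5 - y))
})

test_that("evidence categories follow the thresholds", {
  expect_equal(bf_evidence(c(50, 5, 1, 0.2, 0.05)),
               c("strong_H1", "moderate_H1", "insufficient",
                 "moderate_H0", "strong_H0"))
})

fake_curve <- function(acc, centers) {
  structure(list(method = "mean", accuracy = acc, centers_ms = centers,
                 chance = 0.5), class = "decoding_curve")
}

test_that("evidence series compares post windows against the baseline", {
  set.seed(51)
  centers <- seq(-150, 300, by = 50)
  P <- 10
  acc <- matrix(rnorm(P * length(centers), 0.5, 0.01), P)
  acc[, centers > 100] <- acc[, centers > 100] + 0.2
  cv <- fake_curve(acc, centers)
  bs <- evidence_series(cv)
  expect_length(bs$bf, sum(centers > 0))
  expect_true(all(bs$evidence[bs$centers_ms > 100] == "strong_H1"))
  expect_true(all(bs$bf > 0))
  cv2 <- fake_curve(acc[, centers > 0], centers[centers > 0])
  expect_error(evidence_series(cv2), "baseline")
})

test_that("curve parameters implement the sustain rule", {
  centers <- seq(-100, 500, by = 25)
  flat <- matrix(0.5, 2, length(centers))
  cp <- curve_parameters(fake_curve(flat, centers))
  expect_equal(cp$max_acc, c(0.5, 0.5))
  expect_equal(cp$mean_acc, c(0.5, 0.5))
  expect_true(all(is.na(cp$t_onset_ms)))

  acc <- matrix(0.5, 1, length(centers))
  post <- which(centers > 0)
  acc[1, post[5:12]] <- 0.7                    # 8-window plateau
  acc[1, post[8]] <- 0.9                       # peak inside it
  cp2 <- curve_parameters(fake_curve(acc, centers))
  expect_equal(cp2$max_acc, 0.9)
  expect_equal(cp2$t_max_ms, centers[post[8]])
  expect_equal(cp2$t_onset_ms, centers[post[5]])
  expect_lte(cp2$mean_acc, cp2$max_acc)

  # a 4-window excursion is too short to count as onset
  acc3 <- matrix(0.5, 1, length(centers))
  acc3[1, post[3:6]] <- 0.8
  expect_true(is.na(curve_parameters(fake_curve(acc3, centers))$t_onset_ms))
})

test_that("behavior correlation is a rank statistic", {
  centers <- c(100, 200)
  acc <- cbind(seq(0.9, 0.45, length.out = 10), seq(0.5, 0.95,
                                                    length.out = 10))
  rt <- seq(500, 1400, length.out = 10)
  ser <- brain_behavior_correlation(fake_curve(acc, centers), rt)
  expect_equal(ser$rho, c(-1, 1))
  # invariant to monotone transforms of either vector
  ser2 <- brain_behavior_correlation(fake_curve(sqrt(acc), centers),
                                     exp(rt / 500))
  expect_equal(ser2$rho, ser$rho)
  serc <- brain_behavior_correlation(fake_curve(acc, centers), rep(700, 10))
  expect_true(all(is.na(serc$rho)))
  expect_true(isTRUE(attr(serc, "degenerate")))
  expect_error(brain_behavior_correlation(fake_curve(acc[1:3, ], centers),
                                          rt[1:3]), "participants")
})

test_that("permutation p-values are valid and directional", {
  set.seed(52)
  centers <- seq(25, 250, by = 25)
  acc <- matrix(rnorm(10 * length(centers), 0.6, 0.05), 10)
  rt <- seq(400, 1300, length.out = 10)
  acc[, 3] <- 1 - (rt - min(rt)) / 2000          # perfectly antitone
  cv <- fake_curve(acc, centers)
  ser <- brain_behavior_correlation(cv, rt)
  ser <- permutation_pvalues(ser, cv, rt, n_perm = 1000, seed = 1)
  expect_equal(ser$rho[3], -1)
  expect_lt(ser$p[3], 3 / 1001)                  # smallest attainable region
  expect_true(all(ser$p > 0 & ser$p <= 1))
  # same seed, same p
  ser2 <- permutation_pvalues(ser, cv, rt, n_perm = 1000, seed = 1)
  expect_equal(ser2$p, ser$p)
})

test_that("pFDR controls the null and flags real signal", {
  p <- rep(0.001, 200)
  fd <- fdr_correct(p)
  expect_true(all(fd$significant))
  # q is monotone in p after sorting
  set.seed(53)
  p2 <- runif(150)
  q2 <- fdr_correct(p2)$q
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
  # null calibration: expected significant fraction stays near alpha
  frac <- replicate(100, mean(fdr_correct(runif(200))$significant))
  expect_lte(mean(frac), 0.05 + 0.01)
  # short series fall back to BH
  fd3 <- fdr_correct(runif(10))
  expect_equal(attr(fd3, "method"), "BH")
  # directional p-values are doubled before correction
  fd4 <- fdr_correct(rep(0.04, 100), directional = TRUE)
  expect_false(any(fd4$significant))
  fd5 <- fdr_correct(rep(0.04, 100), directional = FALSE)
  expect_true(all(fd5$significant))
})
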