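# Symlet-2 (= Daubechies-2) decomposition filters.
SYM2_LO <- c(-0.12940952255092145, 0.22414386804185735,
             0.83651630373746899, 0.48296291314469025)
SYM2_HI <- c(-0.48296291314469025, 0.83651630373746899,
             -0.22414386804185735, -0.12940952255092145)

# One analysis level of the DWT with half-point symmetric boundary
# extension, as a pair of coefficient matrices so whole windows (and many
# columns at once) reduce to matrix products. Output length per branch is
# floor((n - 1) / 2) + 2.
dwt_step_matrices <- function(n) {
  lf <- 4L
  extidx <- c(3L, 2L, 1L, seq_len(n), n, n - 1L, n - 2L)
  nconv <- n + lf - 1L
  keep <- seq(2L, nconv, by = 2L)
  make <- function(filt) {
    fr <- rev(filt)
    M <- matrix(0, length(keep), n)
    for (r in seq_along(keep)) {
      i <- keep[r]
      for (j in seq_len(lf)) {
        src <- extidx[i + j - 1L]
        M[r, src] <- M[r, src] + fr[j]
      }
    }
    M
  }
  list(lo = make(SYM2_LO), hi = make(SYM2_HI))
}

# Cache of (n, levels) -> list of per-level detail/approx operator matrices.
.dwt_cache <- new.env(parent = emptyenv())

dwt_operators <- function(n, levels) {
  key <- paste(n, levels, sep = "_")
  hit <- .dwt_cache[[key]]
  if (!is.null(hit)) return(hit)
  ops <- vector("list", levels)
  len <- n
  acc <- diag(len)
  for (lev in seq_len(levels)) {
    st <- dwt_step_matrices(len)
    ops[[lev]] <- list(detail = st$hi %*% acc)
    acc <- st$lo %*% acc
    len <- nrow(acc)
  }
  res <- list(ops = ops, approx = acc,
              detail_lengths = vapply(ops, function(o) nrow(o$detail), 1L))
  .dwt_cache[[key]] <- res
  res
}

wavelet_levels <- function(w) {
  if (w >= 32) return(5L)
  lev <- max(1L, as.integer(floor(log2(w)) - 1))
  warning(sprintf("window of %d samples supports only %d wavelet levels",
                  w, lev), call. = FALSE)
  lev
}

#' Symlet-2 discrete wavelet coefficients of a window
#'
#' Five-level discrete wavelet decomposition with the Symlet-2 basis and
#' half-point symmetric boundary extension, returning the concatenated detail
#' coefficients `D1..D5` (57 values for a 50-sample window); the level-5
#' approximation `A5` (4 more values) is appended when
#' `include_approximation = TRUE`. Windows shorter than 32 samples reduce the
#' depth to `floor(log2(w)) - 1` levels with a warning.
#'
#' @param x numeric window.
#' @param include_approximation append the deepest approximation block.
#' @return Numeric coefficient vector, ordered D1, D2, ..., then A.
#' @export
wavelet_features <- function(x, include_approximation = FALSE) {
  w <- length(x)
  lev <- wavelet_levels(w)
  op <- dwt_operators(w, lev)
  det <- unlist(lapply(op$ops, function(o) as.numeric(o$detail %*% x)))
  if (include_approximation) det <- c(det, as.numeric(op$approx %*% x))
  det
}

#' Hilbert amplitude envelope and instantaneous phase
#'
#' FFT-based analytic signal of the window; returns the amplitude envelope
#' and the instantaneous phase in radians wrapped to `(-pi, pi]`, one value
#' per sample.
#'
#' @param x numeric window (>= 8 samples).
#' @return Named list `amplitude`, `phase`, each of length `w`.
#' @export
hilbert_features <- function(x) {
  w <- length(x)
  stopifnot(w >= 8)
  h <- numeric(w)
  if (w %% 2 == 0) {
    h[c(1, w / 2 + 1)] <- 1
    h[2:(w / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((w + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / w
  ph <- Arg(z)
  ph[ph == -pi] <- pi                      # wrap to (-pi, pi]
  list(amplitude = Mod(z), phase = ph)
}

#' Zero-lag cross-correlation profile of one electrode
#'
#' Pearson correlation between the target electrode's window and every other
#' electrode's simultaneous window, ordered by electrode index (`e - 1`
#' values). Zero-variance pairings yield 0, flagged.
#'
#' @param window_block electrode x w matrix (one trial's window, all
#'   electrodes).
#' @param electrode target electrode index.
#' @return Numeric vector of length `e - 1`.
#' @export
cross_correlation_profile <- function(window_block, electrode) {
  e <- nrow(window_block)
  stopifnot(e >= 2, electrode >= 1, electrode <= e)
  x <- window_block[electrode, ]
  others <- setdiff(seq_len(e), electrode)
  sx <- sd(x)
  out <- vapply(others, function(j) {
    y <- window_block[j, ]
    if (sx == 0 || sd(y) == 0) return(0)
    cor(x, y)
  }, numeric(1))
  if (sx == 0) out <- flag_degenerate(out)
  out
}

#' Raw window samples
#'
#' Identity feature: the window itself (`f = w` values), so classification
#' can use the unreduced magnitude data.
#'
#' @param x numeric window.
#' @return `x`, unchanged.
#' @export
raw_samples <- function(x) x
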