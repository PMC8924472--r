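#' Sliding analysis-window specification
#'
#' Windows of `width_ms` slide along the epoch in steps of `step_ms`; each
#' window contains `w = round(width_ms * fs / 1000)` samples (round-half-up)
#' spanning samples `-floor(w/2) .. w - 1 - floor(w/2)` around the center,
#' i.e. -25..+24 for a 50 ms window at 1000 Hz. Centers are placed on the
#' `step_ms` grid (multiples of the step, in ms relative to stimulus onset)
#' and only where the full window fits inside the epoch.
#'
#' @param width_ms window width in ms (default 50).
#' @param step_ms step between window centers in ms (default 5).
#' @return A list of class `"window_spec"`.
#' @export
window_spec <- function(width_ms = 50, step_ms = 5) {
  if (width_ms <= 0 || step_ms <= 0)
    stop_config("window width and step must be positive")
  structure(list(width_ms = width_ms, step_ms = step_ms),
            class = "window_spec")
}

window_samples <- function(spec, fs) {
  w <- as.integer(round_half_up(spec$width_ms * fs / 1000))
  if (w < 8) stop_config("window of %g ms at fs=%g has only %d samples (< 8)",
                         spec$width_ms, fs, w)
  w
}

#' Enumerate sliding windows over an epoched dataset
#'
#' @param dataset an `epoched_dataset`.
#' @param spec a [window_spec()].
#' @return List with `centers_ms` (window centers, ms relative to onset),
#'   `idx` (windows x w matrix of sample indices into the epoch), and `w`.
#' @export
sliding_windows <- function(dataset, spec = window_spec()) {
  fs <- dataset$fs
  nsamp <- dim(dataset$data)[3]
  w <- window_samples(spec, fs)
  if (w > nsamp) stop_config("window (%d samples) larger than epoch (%d)",
                             w, nsamp)
  lo <- -(w %/% 2)
  hi <- w - 1 + lo
  t_first <- dataset$t_first_sample
  t_last <- t_first + (nsamp - 1) * 1000 / fs
  step <- spec$step_ms
  # candidate centers on the step grid
  k <- seq(ceiling((t_first - 1000 / fs) / step),
           floor((t_last + 1000 / fs) / step))
  centers <- k * step
  cidx <- round_half_up((centers - t_first) * fs / 1000) + 1
  ok <- (cidx + lo) >= 1 & (cidx + hi) <= nsamp
  centers <- centers[ok]
  cidx <- cidx[ok]
  if (!length(centers)) stop_config("no valid window centers in epoch")
  idx <- outer(cidx, lo:hi, "+")
  list(centers_ms = centers, idx = idx, w = w)
}
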