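#' Configuration for a synthetic epoched-EEG cohort
#'
#' Builds and validates the configuration object consumed by
#' [generate_participant()] and [generate_cohort()]. The generator emulates
#' visually evoked, epoched multi-channel recordings: 1/f ("pink") background
#' noise, a category-independent event-related potential (ERP) with a Gaussian
#' temporal envelope, and a category *code* injected on top of it. Which
#' feature family carries the category information is set by `code`:
#'
#' * `"mean"`: the ERP-envelope amplitude offset grows with category index,
#'   so window means are informative while window variances are matched.
#' * `"variance"`: zero-mean noise with category-dependent SD is added inside
#'   the ERP envelope, so variances are informative while means are matched.
#' * `"frequency"`: a fixed-amplitude sinusoid (random phase per trial) whose
#'   frequency depends on category, informative for spectral features only.
#' * `"multiscale"`: a deterministic one-cycle oscillatory burst whose
#'   duration is a category-specific dyadic scale (about `2^level` samples),
#'   energy-matched across categories so that neither window mean nor window
#'   variance separates categories, but scale-resolved (wavelet) coefficients
#'   do.
#' * `"none"`: no code; labels are exchangeable (null data).
#'
#' A per-participant gain `g_p ~ lognormal(0, 0.25)` multiplies the code, so
#' decodability varies across simulated participants; [attach_reaction_times()]
#' links reaction times negatively to that gain.
#'
#' @param n_participants number of participants in the cohort.
#' @param n_categories number of object categories (>= 2).
#' @param trials_per_category trials per category per participant.
#' @param n_electrodes number of electrodes.
#' @param fs sampling rate in Hz.
#' @param epoch_span length-2 vector (pre, post) in ms around stimulus onset;
#'   must bracket 0.
#' @param code encoding code, one of `"mean"`, `"variance"`, `"frequency"`,
#'   `"multiscale"`, `"none"`.
#' @param effect_size dimensionless code strength (microvolt scale for the
#'   amplitude-type codes); 0 disables the code.
#' @param noise_sd SD of the background noise in microvolts.
#' @param pink_exponent spectral slope of the background (power ~ 1/f^a).
#' @param spatial_loadings optional per-electrode weights in `[0, 1]`;
#'   defaults to an exponential fall-off across the electrode index.
#' @param erp_latency,erp_width Gaussian ERP envelope peak latency and SD, ms.
#' @param rt_link list with `intercept` (ms), `slope` (ms per unit gain) and
#'   `noise_sd` (ms) for the reaction-time model
#'   `mean RT = intercept - slope * g_p + noise`.
#' @param seed integer master seed for the cohort.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_participants = 10, n_categories = 4,
                         trials_per_category = 24, n_electrodes = 16,
                         fs = 250, epoch_span = c(-200, 1000),
                         code = c("none", "mean", "variance", "frequency",
                                  "multiscale"),
                         effect_size = 1, noise_sd = 10, pink_exponent = 1,
                         spatial_loadings = NULL,
                         erp_latency = 150, erp_width = 50,
                         rt_link = list(intercept = 1146, slope = 300,
                                        noise_sd = 60),
                         seed = 1L) {
  code <- match.arg(code)
  if (n_categories < 2) stop_config("n_categories must be >= 2")
  if (trials_per_category < 2) stop_config("trials_per_category must be >= 2")
  if (trials_per_category < 20)
    warning("trials_per_category < 2 x 10 folds; stratified 10-fold ",
            "cross-validation may be infeasible", call. = FALSE)
  if (length(epoch_span) != 2 || epoch_span[1] >= 0 || epoch_span[2] <= 0)
    stop_config("epoch_span must bracket 0 (stimulus onset)")
  if (fs * 50 / 1000 < 8)
    stop_config("fs too low: a 50 ms window must contain >= 8 samples")
  if (noise_sd <= 0) stop_config("noise_sd must be positive")
  if (is.null(spatial_loadings))
    spatial_loadings <- 0.2 + 0.8 * exp(-(seq_len(n_electrodes) - 1) / 6)
  if (length(spatial_loadings) != n_electrodes ||
      any(spatial_loadings < 0 | spatial_loadings > 1))
    stop_config("spatial_loadings must be %d weights in [0, 1]", n_electrodes)
  stopifnot(is.list(rt_link),
            all(c("intercept", "slope", "noise_sd") %in% names(rt_link)))
  structure(list(n_participants = as.integer(n_participants),
                 n_categories = as.integer(n_categories),
                 trials_per_category = as.integer(trials_per_category),
                 n_electrodes = as.integer(n_electrodes), fs = fs,
                 epoch_span = epoch_span, code = code,
                 effect_size = effect_size, noise_sd = noise_sd,
                 pink_exponent = pink_exponent,
                 spatial_loadings = spatial_loadings,
                 erp_latency = erp_latency, erp_width = erp_width,
                 rt_link = rt_link, seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f^a background: spectrally shaped white noise, one column per
# trial-electrode pair, each column rescaled to sd = noise_sd.
pink_noise_matrix <- function(nsamp, ncol, exponent, noise_sd) {
  white <- matrix(rnorm(nsamp * ncol), nsamp, ncol)
  if (exponent == 0) return(white * noise_sd)
  freq <- c(1, seq_len(nsamp - 1))            # avoid DC blow-up
  freq <- pmin(freq, nsamp - freq + c(nsamp, rep(0, nsamp - 1)))
  scale <- freq^(-exponent / 2)
  shaped <- Re(mvfft(mvfft(white) * scale, inverse = TRUE)) / nsamp
  sds <- sqrt(colMeans(shaped^2) - colMeans(shaped)^2)
  sds[sds == 0] <- 1
  sweep(shaped, 2, noise_sd / sds, "*")
}

# One-cycle zero-mean oscillatory burst of `dur` samples, unit peak amplitude.
burst_kernel <- function(dur) sin(2 * pi * seq(0, dur - 1) / dur)

#' Generate one synthetic participant
#'
#' Deterministic in `(config$seed, participant_index)`; see [synth_config()]
#' for the signal model.
#'
#' @param config a [synth_config()] object.
#' @param participant_index 1-based index, `<= config$n_participants`.
#' @param seed optional override of the derived per-participant seed.
#' @return An `epoched_dataset`: list with `data` (trial x electrode x sample
#'   array, microvolts), `labels` (integer categories), `fs`,
#'   `t_first_sample` (ms), `participant_id`, `category_names`, and optional
#'   `rt`; the per-participant code gain is stored in `attr(, "gain")`.
#' @export
generate_participant <- function(config, participant_index, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (participant_index < 1 || participant_index > config$n_participants)
    stop_config("participant_index must be in 1..%d", config$n_participants)
  if (is.null(seed)) seed <- derive_seed(config$seed, participant_index)

  fs <- config$fs
  nsamp <- round_half_up((config$epoch_span[2] - config$epoch_span[1]) *
                           fs / 1000)
  t_ms <- config$epoch_span[1] + (seq_len(nsamp) - 1) * 1000 / fs
  K <- config$n_categories
  n <- K * config$trials_per_category
  e <- config$n_electrodes
  env <- exp(-(t_ms - config$erp_latency)^2 / (2 * config$erp_width^2))
  load <- config$spatial_loadings

  with_seed(seed, {
    g <- rlnorm(1, 0, 0.25)
    labels <- sample(rep(seq_len(K), config$trials_per_category))
    noise <- pink_noise_matrix(nsamp, n * e, config$pink_exponent,
                               config$noise_sd)
    dim(noise) <- c(nsamp, n, e)
    # common ERP (4 microvolt peak), identical across categories
    erp <- 4 * env
    sig <- array(0, dim = c(nsamp, n, e))
    for (j in seq_len(e)) sig[, , j] <- erp * load[j]

    es <- config$effect_size
    if (config$code != "none" && es != 0) {
      if (config$code == "mean") {
        for (tr in seq_len(n)) {
          amp <- g * es * (labels[tr] - 1)
          if (amp != 0) for (j in seq_len(e))
            sig[, tr, j] <- sig[, tr, j] + amp * env * load[j]
        }
      } else if (config$code == "variance") {
        for (tr in seq_len(n)) {
          sdx <- g * es * (labels[tr] - 1)
          if (sdx > 0) {
            extra <- matrix(rnorm(nsamp * e, 0, sdx), nsamp, e)
            for (j in seq_len(e))
              sig[, tr, j] <- sig[, tr, j] + extra[, j] * env * load[j]
          }
        }
      } else if (config$code == "frequency") {
        f0 <- 8; df <- 16          # well-separated category frequencies (Hz)
        for (tr in seq_len(n)) {
          fk <- f0 + df * (labels[tr] - 1)
          phase <- runif(1, 0, 2 * pi)
          wave <- g * es * sin(2 * pi * fk * t_ms / 1000 + phase) * env
          for (j in seq_len(e)) sig[, tr, j] <- sig[, tr, j] + wave[] * load[j]
        }
      } else if (config$code == "multiscale") {
        centre <- which.min(abs(t_ms - config$erp_latency))
        ref_dur <- round_half_up(0.016 * fs)   # 16 ms reference scale
        for (tr in seq_len(n)) {
          dur <- 2^(labels[tr] + 1)            # dyadic, category-specific
          dur <- min(dur, nsamp - centre)
          kern <- burst_kernel(dur) * sqrt(ref_dur / dur)  # energy-matched
          idx <- centre + seq_len(dur) - 1
          for (j in seq_len(e))
            sig[idx, tr, j] <- sig[idx, tr, j] + g * es * kern * load[j]
        }
      }
    }
    data <- aperm(noise + sig, c(2, 3, 1))     # trial x electrode x sample
    ds <- structure(list(data = data, labels = labels, fs = fs,
                         t_first_sample = t_ms[1],
                         participant_id = sprintf("P%02d", participant_index),
                         rt = NULL,
                         category_names = paste0("cat", seq_len(K))),
                    class = "epoched_dataset")
    attr(ds, "gain") <- g
    validate_epoched_dataset(ds)
    ds
  })
}

#' Generate a full synthetic cohort
#'
#' @param config a [synth_config()] object; per-participant seeds are derived
#'   deterministically from `config$seed`.
#' @return List of `epoched_dataset`, one per participant, each carrying its
#'   code gain in `attr(, "gain")`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lapply(seq_len(config$n_participants),
         function(i) generate_participant(config, i))
}

#' Attach reaction times linked to decodability
#'
#' Per-participant mean reaction time is `intercept - slope * g_p` plus
#' Gaussian noise (`config$rt_link`), where `g_p` is the stored code gain;
#' per-trial values are jittered around the participant mean and floored at
#' 101 ms. With `slope > 0`, better-decodable participants respond faster.
#'
#' @param cohort output of [generate_cohort()].
#' @param config the [synth_config()] used to build the cohort.
#' @param seed integer seed for the RT noise.
#' @return The cohort with `rt` (ms per trial) filled in.
#' @export
attach_reaction_times <- function(cohort, config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  gains <- vapply(cohort, function(d) {
    g <- attr(d, "gain")
    if (is.null(g)) stop_config("cohort datasets lack stored code gains")
    g
  }, numeric(1))
  if (is.null(seed)) seed <- derive_seed(config$seed, 999L)
  lk <- config$rt_link
  with_seed(seed, {
    for (i in seq_along(cohort)) {
      mu <- lk$intercept - lk$slope * gains[i] + rnorm(1, 0, lk$noise_sd)
      n <- length(cohort[[i]]$labels)
      rt <- mu + rnorm(n, 0, lk$noise_sd)
      cohort[[i]]$rt <- pmax(rt, 101)
    }
    cohort
  })
}

#' Validate an epoched dataset container
#'
#' Checks the structural invariants: rectangular finite array, labels from at
#' least two categories, pre-stimulus baseline available, positive per-trial
#' reaction times when present.
#'
#' @param dataset an `epoched_dataset`.
#' @return The dataset, invisibly; errors describe the violated field.
#' @export
validate_epoched_dataset <- function(dataset) {
  d <- dataset$data
  if (!is.array(d) || length(dim(d)) != 3)
    stop_config("data must be a trial x electrode x sample array")
  if (!all(is.finite(d))) stop_config("data contains non-finite values")
  n <- dim(d)[1]
  if (length(dataset$labels) != n)
    stop_config("labels: expected one per trial (%d), got %d",
                n, length(dataset$labels))
  if (length(unique(dataset$labels)) < 2)
    stop_config("labels must cover at least 2 categories")
  if (is.null(dataset$fs) || dataset$fs <= 0) stop_config("fs must be > 0")
  if (dataset$t_first_sample >= 0)
    stop_config("t_first_sample must be negative (pre-stimulus baseline)")
  if (!is.null(dataset$rt)) {
    if (length(dataset$rt) != n)
      stop_config("rt: expected one value per trial")
    if (any(dataset$rt <= 0)) stop_config("rt values must be positive")
  }
  invisible(dataset)
}
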