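# Epoch container I/O and per-trial baseline correction.

#' Per-trial baseline correction
#'
#' Subtracts, per trial and electrode, the mean amplitude over the
#' pre-stimulus baseline window. Idempotent up to numerical noise.
#'
#' @param dataset an `epoched_dataset`.
#' @param window ms pair delimiting the baseline (default `c(-200, 0)`).
#' @return The corrected dataset.
#' @export
baseline_correct <- function(dataset, window = c(-200, 0)) {
  nsamp <- dim(dataset$data)[3]
  t_ms <- dataset$t_first_sample + (seq_len(nsamp) - 1) * 1000 / dataset$fs
  sel <- t_ms >= window[1] & t_ms <= window[2]
  if (!any(sel)) stop_config("baseline window [%g, %g] outside epoch",
                             window[1], window[2])
  bl <- apply(dataset$data[, , sel, drop = FALSE], c(1, 2), mean)
  dataset$data <- dataset$data - as.vector(bl)   # recycles over sample dim
  dataset
}

#' Write an epoched dataset to a portable text container
#'
#' The amplitudes go to `<prefix>_data.csv` (one row per trial-electrode
#' pair, trial-major; one column per sample) and the metadata (`fs`,
#' `t_first_sample`, labels, category names, optional reaction times,
#' participant id) to a `<prefix>_meta.json` sidecar.
#'
#' @param dataset an `epoched_dataset`.
#' @param prefix file path prefix.
#' @return The two file paths, invisibly.
#' @export
write_epochs <- function(dataset, prefix) {
  validate_epoched_dataset(dataset)
  d <- dataset$data
  n <- dim(d)[1]; e <- dim(d)[2]; s <- dim(d)[3]
  flat <- matrix(aperm(d, c(2, 1, 3)), n * e, s)   # rows: trial-major, elec
  data_path <- paste0(prefix, "_data.csv")
  meta_path <- paste0(prefix, "_meta.json")
  lines <- apply(flat, 1, function(r) paste(sprintf("%.17g", r),
                                            collapse = ","))
  writeLines(lines, data_path)   # full precision for an exact round trip
  meta <- list(n_trials = n, n_electrodes = e, n_samples = s,
               fs = dataset$fs, t_first_sample = dataset$t_first_sample,
               labels = dataset$labels,
               category_names = dataset$category_names,
               participant_id = dataset$participant_id)
  if (!is.null(dataset$rt)) meta$rt <- dataset$rt
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data_path, meta_path))
}

#' Read an epoched dataset written by [write_epochs()]
#'
#' @param prefix file path prefix used at write time.
#' @return A validated `epoched_dataset`.
#' @export
read_epochs <- function(prefix) {
  data_path <- paste0(prefix, "_data.csv")
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(data_path) || !file.exists(meta_path))
    stop_config("missing container files for prefix '%s'", prefix)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (fld in c("n_trials", "n_electrodes", "n_samples", "fs",
                "t_first_sample", "labels"))
    if (is.null(meta[[fld]]))
      stop_config("sidecar is missing required field '%s'", fld)
  flat <- as.matrix(utils::read.table(data_path, sep = ","))
  n <- meta$n_trials; e <- meta$n_electrodes; s <- meta$n_samples
  if (nrow(flat) != n * e || ncol(flat) != s)
    stop_config("data array is %d x %d; sidecar promises %d x %d",
                nrow(flat), ncol(flat), n * e, s)
  d <- aperm(array(flat, dim = c(e, n, s)), c(2, 1, 3))
  ds <- structure(list(data = d, labels = meta$labels, fs = meta$fs,
                       t_first_sample = meta$t_first_sample,
                       participant_id = meta$participant_id %||% "unknown",
                       rt = meta$rt,
                       category_names = meta$category_names),
                  class = "epoched_dataset")
  validate_epoched_dataset(ds)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a decoding curve as long-format CSV
#'
#' Columns: method, participant, window_ms, accuracy.
#'
#' @param curve a `decoding_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_decoding_curve <- function(curve, path) {
  P <- nrow(curve$accuracy)
  df <- data.frame(method = curve$method,
                   participant = rep(seq_len(P),
                                     times = length(curve$centers_ms)),
                   window_ms = rep(curve$centers_ms, each = P),
                   accuracy = as.vector(curve$accuracy))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
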