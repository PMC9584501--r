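#' Construct a labelled set of EEG trials
#'
#' The unit of cross-validation and augmentation. Signals are a numeric array
#' `(n_trials x N electrodes x T samples)` in volts (any consistent unit);
#' labels are integer classes in `[0, n_classes)`; `trial_ids` identify the
#' source trial and are inherited by augmented segments so that folds can be
#' kept leakage-free.
#'
#' @param signals 3-d numeric array, trials x electrodes x samples.
#' @param labels integer vector, one class per trial, zero-based.
#' @param fs sampling rate in Hz.
#' @param trial_ids optional character/integer vector of provenance ids
#'   (default: `1..n_trials`).
#' @param electrode_names optional character vector of length N.
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(signals, labels, fs, trial_ids = NULL, electrode_names = NULL) {
  if (!is.array(signals) || length(dim(signals)) != 3L)
    stop_arg("signals must be a 3-d array (trials x electrodes x samples)")
  n <- dim(signals)[1]
  if (length(labels) != n) stop_arg("labels length must equal the number of trials")
  if (any(!is.finite(labels)) || any(labels != floor(labels)) || any(labels < 0))
    stop_arg("labels must be non-negative integers (zero-based classes)")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_arg("fs must be a positive sampling rate in Hz")
  trial_ids <- trial_ids %||% seq_len(n)
  if (length(trial_ids) != n) stop_arg("trial_ids length must equal the number of trials")
  if (!is.null(electrode_names) && length(electrode_names) != dim(signals)[2])
    stop_arg("electrode_names length must equal the number of electrodes")
  structure(
    list(signals = signals, labels = as.integer(labels), fs = fs,
         trial_ids = trial_ids, electrode_names = electrode_names),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$signals)
  cat("<trial_set> ", d[1], " trials, ", d[2], " electrodes, ", d[3],
      " samples @ ", x$fs, " Hz, ", length(unique(x$labels)), " classes\n", sep = "")
  invisible(x)
}

n_trials <- function(ts) dim(ts$signals)[1]

#' Per-trial, per-electrode z-scoring
#'
#' Standardizes each electrode's time course within each trial to zero mean
#' and unit variance (constant channels are left at zero). Removes per-trial
#' amplitude offsets before modelling; toggled by the pipeline configuration.
#'
#' @param ts a [trial_set()].
#' @return a `trial_set` with standardized signals.
#' @export
zscore_trials <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  sig <- ts$signals
  d <- dim(sig)
  for (i in seq_len(d[1])) {
    x <- sig[i, , , drop = FALSE]
    dim(x) <- d[2:3]
    mu <- rowMeans(x)
    sdv <- sqrt(rowMeans((x - mu)^2))
    sdv[sdv == 0] <- 1
    sig[i, , ] <- (x - mu) / sdv
  }
  ts$signals <- sig
  ts
}

#' Save / load a trial set
#'
#' Runtime container round-trip (RDS; no HDF5 binding is available in the
#' target environment). All fields — signals, labels, trial_ids, fs,
#' electrode_names — are preserved losslessly.
#'
#' @param ts a [trial_set()].
#' @param path file path.
#' @return `read_trialset` returns the restored `trial_set`.
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  saveRDS(unclass(ts), path)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  if (!file.exists(path)) stop_arg("trial set file not found: ", path)
  x <- readRDS(path)
  trial_set(x$signals, x$labels, x$fs, x$trial_ids, x$electrode_names)
}

subset_trials <- function(ts, idx) {
  trial_set(ts$signals[idx, , , drop = FALSE], ts$labels[idx], ts$fs,
            ts$trial_ids[idx], ts$electrode_names)
}
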