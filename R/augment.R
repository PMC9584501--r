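#' Sliding-window data augmentation
#'
#' Cuts each trial into overlapping windows of `window_s` seconds advanced by
#' `step_s` seconds, the standard EEG augmentation for 3 s motor-imagery
#' trials (window 2 s, step 0.32 s at 250 Hz turns each trial into 4
#' segments). Each window inherits the label and the `trial_id` of its source
#' trial, so cross-validation can keep all windows of a trial on one side of
#' the split. Window and step lengths are truncated toward zero samples; a
#' trial of T samples yields `floor((T - W) / S) + 1` windows and no window
#' extends past the trial end.
#'
#' @param ts a [trial_set()].
#' @param window_s window length, seconds.
#' @param step_s sliding step, seconds.
#' @return a `trial_set` of windows.
#' @export
sliding_window_augment <- function(ts, window_s = 2, step_s = 0.32) {
  stopifnot(inherits(ts, "trial_set"))
  d <- dim(ts$signals)
  W <- trunc(window_s * ts$fs)
  S <- trunc(step_s * ts$fs)
  if (W < 1 || W > d[3])
    stop_arg("window (", window_s, " s = ", W, " samples) must lie in [1 sample, trial length ",
             d[3], "]")
  if (S < 1) stop_arg("step_s too small: less than one sample at fs = ", ts$fs, " Hz")
  offsets <- seq(0L, d[3] - W, by = S)
  n_win <- length(offsets) # floor((T - W)/S) + 1
  out <- array(0, dim = c(d[1] * n_win, d[2], W))
  lab <- integer(d[1] * n_win)
  ids <- rep(ts$trial_ids, each = n_win)
  r <- 0L
  for (i in seq_len(d[1])) {
    for (o in offsets) {
      r <- r + 1L
      out[r, , ] <- ts$signals[i, , (o + 1L):(o + W)]
      lab[r] <- ts$labels[i]
    }
  }
  trial_set(out, lab, ts$fs, ids, ts$electrode_names)
}

#' White-noise data augmentation
#'
#' Returns the original trials plus `copies` noisy replicas of each, the
#' augmentation used for short (1 s) trials where sliding windows are not
#' viable. Noise is zero-mean Gaussian scaled per trial so that
#' `10 * log10(signal power / noise power) = snr_db`. `snr_db = Inf` is the
#' documented sentinel for "noise disabled" (replicas identical to their
#' originals). Deterministic given `seed`.
#'
#' @param ts a [trial_set()].
#' @param snr_db target signal-to-noise ratio in dB (default 20).
#' @param copies noisy replicas per trial (default 3).
#' @param seed integer seed.
#' @return a `trial_set` with `n * (copies + 1)` trials; replicas carry their
#'   source `trial_id`.
#' @export
white_noise_augment <- function(ts, snr_db = 20, copies = 3L, seed = 0L) {
  stopifnot(inherits(ts, "trial_set"))
  if (length(snr_db) != 1L || is.na(snr_db) || is.nan(snr_db) || snr_db == -Inf)
    stop_arg("snr_db must be a finite dB value (or +Inf to disable noise)")
  if (copies < 1 || copies != floor(copies)) stop_arg("copies must be a positive integer")
  d <- dim(ts$signals)
  n_out <- d[1] * (copies + 1L)
  out <- array(0, dim = c(n_out, d[2], d[3]))
  lab <- integer(n_out)
  ids <- vector(mode = typeof(ts$trial_ids), n_out)
  set.seed(derive_seed(seed, "white_noise"))
  r <- 0L
  for (i in seq_len(d[1])) {
    x <- ts$signals[i, , , drop = FALSE]
    dim(x) <- d[2:3]
    p_sig <- mean(x^2)
    sd_noise <- if (is.infinite(snr_db)) 0 else sqrt(p_sig * 10^(-snr_db / 10))
    r <- r + 1L
    out[r, , ] <- x; lab[r] <- ts$labels[i]; ids[r] <- ts$trial_ids[i]
    for (k in seq_len(copies)) {
      r <- r + 1L
      out[r, , ] <- x + matrix(stats::rnorm(d[2] * d[3], sd = sd_noise), d[2], d[3])
      lab[r] <- ts$labels[i]; ids[r] <- ts$trial_ids[i]
    }
  }
  trial_set(out, lab, ts$fs, ids, ts$electrode_names)
}
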