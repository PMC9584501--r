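#' Specification of a synthetic motor-imagery EEG task
#'
#' Describes the generative world for the synthetic trials: a montage, a
#' number of classes, and one effect per class — an amplitude-modulated
#' sinusoid at a class-specific carrier frequency on a class-specific set of
#' active electrodes — on top of a 1/f^alpha (pink) background plus white
#' sensor noise on every electrode. This emulates the band-limited
#' event-related (de)synchronization structure motor-imagery decoding relies
#' on; it does not attempt forward-modelled physiological EEG.
#'
#' Defaults give the "easy" two-class task used by the acceptance suite:
#' a 3 x 3 grid of 9 electrodes, 100 trials per class of 3 s at 250 Hz,
#' class 0 driving a 10 Hz carrier on the top grid row and class 1 a 22 Hz
#' carrier on the bottom row, carrier amplitude 2 against a unit-variance
#' pink background (amplitude/noise ratio 2) with white noise sigma 0.5, and
#' a 0.5 s linear on/off amplitude ramp.
#'
#' @param mont a [montage()]; default `grid_montage(3, 3)`.
#' @param n_classes number of classes.
#' @param trials_per_class trials generated per class.
#' @param fs sampling rate, Hz.
#' @param duration trial length, seconds.
#' @param effects list of length `n_classes`; each element a list with fields
#'   `active` (electrode indices), `freq` (carrier Hz, < fs/2), `amplitude`
#'   (>= 0) and optional `envelope` (logical, default TRUE).
#' @param pink_alpha spectral exponent of the 1/f^alpha background.
#' @param pink_sigma standard deviation of the pink background.
#' @param white_sigma standard deviation of the additive white noise.
#' @param ramp_s envelope ramp duration, seconds.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mont = grid_montage(3, 3),
                           n_classes = 2L,
                           trials_per_class = 100L,
                           fs = 250,
                           duration = 3,
                           effects = NULL,
                           pink_alpha = 1,
                           pink_sigma = 1,
                           white_sigma = 0.5,
                           ramp_s = 0.5,
                           seed = 0L) {
  stopifnot(inherits(mont, "cgcnn_montage"))
  if (n_classes < 1 || trials_per_class < 1) stop_arg("need >= 1 class and >= 1 trial per class")
  if (is.null(effects)) {
    if (n_classes != 2L || mont$n_electrodes != 9L)
      stop_arg("default effects cover only the 2-class 3x3 easy task; supply `effects`")
    effects <- list(
      list(active = 1:3, freq = 10, amplitude = 2, envelope = TRUE),
      list(active = 7:9, freq = 22, amplitude = 2, envelope = TRUE)
    )
  }
  if (length(effects) != n_classes) stop_arg("need one effect per class")
  for (ef in effects) {
    if (any(ef$active < 1) || any(ef$active > mont$n_electrodes))
      stop_arg("active electrodes must index into the montage (1..", mont$n_electrodes, ")")
    if (ef$freq >= fs / 2) stop_arg("carrier_freq must be below fs/2 = ", fs / 2, " Hz")
    if (ef$amplitude < 0) stop_arg("amplitude must be >= 0")
  }
  if (pink_sigma < 0 || white_sigma < 0) stop_arg("noise sigmas must be >= 0")
  structure(
    list(montage = mont, n_classes = as.integer(n_classes),
         trials_per_class = as.integer(trials_per_class), fs = fs,
         duration = duration, effects = effects, pink_alpha = pink_alpha,
         pink_sigma = pink_sigma, white_sigma = white_sigma, ramp_s = ramp_s,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# 1/f^alpha noise by spectral shaping of white Gaussian noise, standardized to
# sd = 1 (DC removed).
pink_noise <- function(n, alpha = 1) {
  X <- stats::fft(stats::rnorm(n))
  nfreq <- floor(n / 2)
  f <- c(1, seq_len(nfreq), if (n %% 2 == 0) seq_len(nfreq - 1)[rev(seq_len(nfreq - 1))]
         else rev(seq_len(nfreq)))
  # f: symmetric bin index (1-indexed magnitude) per FFT bin; DC slot unused
  g <- f^(-alpha / 2)
  X <- X * g
  X[1] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

trapezoid_envelope <- function(n, fs, ramp_s) {
  ramp <- min(trunc(ramp_s * fs), floor(n / 2))
  env <- rep(1, n)
  if (ramp > 0) {
    up <- seq(0, 1, length.out = ramp)
    env[seq_len(ramp)] <- up
    env[(n - ramp + 1):n] <- rev(up)
  }
  env
}

#' Generate a synthetic labelled trial set
#'
#' Each trial is pink background + white noise on all electrodes, plus the
#' class's amplitude-modulated sinusoid (random uniform phase per trial) on
#' its active electrodes. Labels are balanced by construction and the output
#' is bit-identical for a given spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a [trial_set()] with `n_classes * trials_per_class` trials.
#' @export
generate_trials <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$montage$n_electrodes
  T_samp <- trunc(spec$fs * spec$duration)
  n <- spec$n_classes * spec$trials_per_class
  sig <- array(0, dim = c(n, N, T_samp))
  lab <- integer(n)
  tt <- (0:(T_samp - 1)) / spec$fs
  env <- trapezoid_envelope(T_samp, spec$fs, spec$ramp_s)
  set.seed(derive_seed(spec$seed, "synthetic"))
  r <- 0L
  for (cls in seq_len(spec$n_classes)) {
    ef <- spec$effects[[cls]]
    use_env <- isTRUE(ef$envelope %||% TRUE)
    for (tr in seq_len(spec$trials_per_class)) {
      r <- r + 1L
      x <- matrix(0, N, T_samp)
      for (e in seq_len(N)) {
        x[e, ] <- spec$pink_sigma * pink_noise(T_samp, spec$pink_alpha) +
          stats::rnorm(T_samp, sd = spec$white_sigma)
      }
      if (ef$amplitude > 0 && length(ef$active)) {
        phase <- stats::runif(1, 0, 2 * pi)
        carrier <- ef$amplitude * sin(2 * pi * ef$freq * tt + phase)
        if (use_env) carrier <- carrier * env
        x[ef$active, ] <- x[ef$active, , drop = FALSE] +
          matrix(carrier, length(ef$active), T_samp, byrow = TRUE)
      }
      sig[r, , ] <- x
      lab[r] <- cls - 1L
    }
  }
  trial_set(sig, lab, spec$fs, electrode_names = spec$montage$entries$name)
}
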