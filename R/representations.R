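#' Graph tensor container
#'
#' One trial mapped onto the electrode graph: a numeric array
#' `(N nodes x L steps x C channels)` where the step axis is time (temporal
#' mode) or frequency (spectral mode). Raw inputs have `C = 1`; graph
#' convolution widens the channel axis.
#'
#' @param values numeric N x L x C array (an N x L matrix is promoted to C = 1).
#' @param mode `"temporal"` or `"spectral"`.
#' @param axis optional numeric vector of per-step time (s) or frequency (Hz).
#' @return an object of class `graph_tensor`.
#' @export
graph_tensor <- function(values, mode = c("temporal", "spectral"), axis = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_arg("graph_tensor values must be an N x L x C array")
  if (mode == "spectral" && any(values < 0))
    stop_arg("spectral-mode graph tensors must be non-negative (PSD)")
  if (!is.null(axis) && length(axis) != dim(values)[2])
    stop_arg("axis length must equal the step dimension L")
  structure(list(values = values, mode = mode, axis = axis), class = "graph_tensor")
}

#' @export
print.graph_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<graph_tensor mode=", x$mode, "> ", d[1], " nodes x ", d[2], " steps x ",
      d[3], " channels\n", sep = "")
  invisible(x)
}

# Band-limited (Fourier-domain) downsampling of one signal to length m.
# Keeps the lowest output-representable frequencies; the Nyquist bin is folded
# so the reconstruction stays real. Preserves constants exactly (DC bin only).
resample_fourier <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  if (m > n) stop_arg("Fourier resampling here only shortens signals (m <= n)")
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  half <- floor((m + 1) / 2) # DC + positive frequencies
  Y[seq_len(half)] <- X[seq_len(half)]
  negn <- m - half
  if (negn > 0) Y[(half + 1):m] <- X[(n - negn + 1):n]
  if (m %% 2 == 0) { # fold the +Nyquist component into the single slot
    Y[m / 2 + 1] <- Y[m / 2 + 1] + X[m / 2 + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Spatial-temporal graph representation
#'
#' Maps a single raw trial (N electrodes x T samples) onto the graph with the
#' time axis resampled to exactly `T_target` steps. Default resampling is
#' band-limited (Fourier-domain), avoiding aliasing of mu/beta rhythms when a
#' 500-sample window becomes T = 100 steps; plain decimation (index
#' subsampling) is available for comparison.
#'
#' @param x numeric matrix N x T (one trial).
#' @param T_target number of output time steps (default 100).
#' @param method `"fourier"` (anti-aliased) or `"decimate"`.
#' @param fs optional sampling rate (Hz) used only to annotate the time axis.
#' @return a temporal-mode [graph_tensor()] of shape N x T_target x 1.
#' @export
to_spatial_temporal <- function(x, T_target = 100L, method = c("fourier", "decimate"),
                                fs = NULL) {
  method <- match.arg(method)
  if (!is.matrix(x)) stop_arg("x must be an N x T matrix (one trial)")
  T_samp <- ncol(x)
  if (length(T_target) != 1L || T_target < 1 || T_target != floor(T_target))
    stop_arg("T_target must be a positive integer")
  if (T_target > T_samp)
    stop_arg("T_target (", T_target, ") exceeds trial length (", T_samp, " samples)")
  out <- if (T_target == T_samp) {
    x
  } else if (method == "fourier") {
    t(apply(x, 1, resample_fourier, m = T_target))
  } else {
    x[, round(seq(1, T_samp, length.out = T_target)), drop = FALSE]
  }
  dim(out) <- c(nrow(x), T_target, 1L)
  axis <- if (!is.null(fs)) seq(0, (T_samp - 1) / fs, length.out = T_target) else NULL
  graph_tensor(out, "temporal", axis)
}

# Welch PSD of one signal: averaged modified periodograms of mean-detrended,
# Hann-tapered segments with the given overlap. One-sided density scaling, so
# sum(psd) * df ~ var(x) for broadband signals.
welch_spectrum <- function(x, fs, nperseg, overlap = 0.5) {
  n <- length(x)
  if (nperseg > n)
    stop_arg("trial (", n, " samples) is shorter than one Welch segment (",
             nperseg, "); lower welch_nperseg or supply longer trials")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg) # periodic Hann
  U <- sum(w^2)
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / (fs * U)
    sp[2:nfreq] <- 2 * sp[2:nfreq]
    if (nperseg %% 2 == 0) sp[nfreq] <- sp[nfreq] / 2 # Nyquist not doubled
    acc <- acc + sp
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = acc / length(starts))
}

#' Spatial-spectral graph representation (Welch PSD)
#'
#' Estimates each electrode's power spectral density by Welch's method
#' (mean-detrended, Hann-tapered, 50%-overlapping segments by default) and
#' pools the Welch frequencies into `F_target` equal-width bins spanning
#' `band`. Bins containing no Welch frequency are filled by linear
#' interpolation at the bin centre. All values are non-negative.
#'
#' @param x numeric matrix N x T (one trial).
#' @param fs sampling rate, Hz.
#' @param F_target number of frequency bins (default 100).
#' @param band `c(f_lo, f_hi)` in Hz with `0 <= f_lo < f_hi <= fs/2`
#'   (default `c(0.5, 50.5)`).
#' @param nperseg Welch segment length in samples (default `min(256, T)`).
#' @param overlap fractional segment overlap (default 0.5).
#' @return a spectral-mode [graph_tensor()] of shape N x F_target x 1 with the
#'   bin centres as the frequency axis.
#' @export
welch_psd <- function(x, fs, F_target = 100L, band = c(0.5, 50.5),
                      nperseg = NULL, overlap = 0.5) {
  if (!is.matrix(x)) stop_arg("x must be an N x T matrix (one trial)")
  if (length(band) != 2L || band[1] < 0 || band[2] <= band[1] || band[2] > fs / 2)
    stop_arg("band must satisfy 0 <= f_lo < f_hi <= fs/2 (fs/2 = ", fs / 2, " Hz)")
  nper <- as.integer(nperseg %||% min(256L, ncol(x)))
  edges <- seq(band[1], band[2], length.out = F_target + 1L)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  out <- array(0, dim = c(nrow(x), F_target, 1L))
  for (i in seq_len(nrow(x))) {
    sp <- welch_spectrum(x[i, ], fs, nper, overlap)
    inb <- sp$freq >= band[1] & sp$freq <= band[2]
    bin <- findInterval(sp$freq[inb], edges, rightmost.closed = TRUE)
    pooled <- rep(NA_real_, F_target)
    agg <- tapply(sp$psd[inb], bin, mean)
    pooled[as.integer(names(agg))] <- agg
    if (anyNA(pooled)) {
      filled <- which(!is.na(pooled))
      if (length(filled) == 0) {
        pooled[] <- 0
      } else {
        pooled <- stats::approx(centres[filled], pooled[filled], xout = centres,
                                rule = 2)$y
      }
    }
    out[i, , 1] <- pmax(pooled, 0)
  }
  graph_tensor(out, "spectral", centres)
}
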