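test_that("to_spatial_temporal resamples to the requested length", {
  set.seed(1)
  x <- matrix(rnorm(9 * 500), 9, 500)
  gt <- to_spatial_temporal(x, 100L)
  expect_s3_class(gt, "graph_tensor")
  expect_equal(dim(gt$values), c(9L, 100L, 1L))
  expect_equal(gt$mode, "temporal")

  # identity when T_target equals the trial length
  gt_id <- to_spatial_temporal(x, 500L)
  expect_equal(gt_id$values[, , 1], x)

  # both schemes preserve constant signals exactly
  xc <- matrix(rep(c(-2, 0.5, 3), each = 120), 3, 120, byrow = TRUE)
  for (meth in c("fourier", "decimate")) {
    out <- to_spatial_temporal(xc, 40L, method = meth)$values[, , 1]
    expect_equal(out, matrix(rep(c(-2, 0.5, 3), 40), 3, 40), tolerance = 1e-12)
  }

  expect_error(to_spatial_temporal(x, 501L), "exceeds trial length")
})

test_that("fourier resampling preserves band-limited content", {
  # a 5 Hz tone at 250 Hz downsampled to 50 steps (50 Hz) stays a 5 Hz tone
  fs <- 250; tt <- (0:499) / fs
  x <- matrix(sin(2 * pi * 5 * tt), 1)
  y <- to_spatial_temporal(x, 50L)$values[1, , 1]
  # new sampling rate: 50 samples over the same 2 s span -> 25 Hz
  expect_equal(y, sin(2 * pi * 5 * (0:49) / 25), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("welch_psd: zeros, peak location, shape and non-negativity", {
  z <- welch_psd(matrix(0, 4, 512), fs = 250, F_target = 50)
  expect_equal(dim(z$values), c(4L, 50L, 1L))
  expect_true(all(z$values == 0))

  # pure 10 Hz sinusoid: argmax lands in the bin containing 10 Hz
  fs <- 250; tt <- (0:1249) / fs
  x <- rbind(sin(2 * pi * 10 * tt), rnorm(1250, sd = 0.1))
  gt <- welch_psd(x, fs, F_target = 50, band = c(0.5, 50.5))
  peak_bin <- which.max(gt$values[1, , 1])
  edges <- seq(0.5, 50.5, length.out = 51)
  expect_true(edges[peak_bin] <= 10 && 10 <= edges[peak_bin + 1])
  expect_true(all(gt$values >= 0))

  expect_error(welch_psd(matrix(0, 1, 100), fs = 250, nperseg = 256),
               "shorter than one Welch segment")
  expect_error(welch_psd(matrix(0, 1, 512), fs = 250, band = c(30, 10)), "band")
})

test_that("welch_psd integrates to the signal variance (Parseval, Monte Carlo)", {
  fs <- 250
  ratios <- vapply(1:50, function(s) {
    set.seed(s)
    x <- matrix(rnorm(1000), 1)
    gt <- welch_psd(x, fs, F_target = 80, band = c(0, fs / 2))
    df <- (fs / 2) / 80
    sum(gt$values) * df / stats::var(x[1, ])
  }, numeric(1))
  expect_true(all(abs(ratios - 1) < 0.2))
})

test_that("sliding windows: counts, offsets, inheritance", {
  # 3 s at 250 Hz, window 2 s, step 0.32 s -> 4 windows per trial
  tt <- tiny_trialset(n_per_class = 2, fs = 250, duration = 3)
  aug <- sliding_window_augment(tt$ts, window_s = 2, step_s = 0.32)
  expect_equal(dim(aug$signals)[1], 4L * 4L)
  expect_equal(dim(aug$signals)[3], 500L)

  # window = trial duration -> exactly one window equal to the trial
  one <- sliding_window_augment(tt$ts, window_s = 3, step_s = 0.32)
  expect_equal(one$signals, tt$ts$signals)

  # 1000 samples, W = 300, S = 150: offsets 0,150,...,600 by enumeration
  ts1 <- trial_set(array(rnorm(1 * 2 * 1000), c(1, 2, 1000)), 0:0, fs = 1000)
  a <- sliding_window_augment(ts1, window_s = 0.3, step_s = 0.15)
  expect_equal(dim(a$signals)[1], 5L)
  for (w in 1:5) {
    off <- (w - 1) * 150
    expect_equal(a$signals[w, , ], ts1$signals[1, , (off + 1):(off + 300)])
  }

  expect_error(sliding_window_augment(tt$ts, window_s = 10), "window")
})

test_that("window count formula matches exhaustive offset enumeration", {
  set.seed(21)
  for (rep in 1:200) {
    T_samp <- sample(50:400, 1)
    W <- sample(10:T_samp, 1)
    S <- sample(1:60, 1)
    enumerated <- sum((seq(0, T_samp) + W) <= T_samp & seq(0, T_samp) %% S == 0)
    formula <- floor((T_samp - W) / S) + 1
    expect_equal(formula, enumerated)
  }
})

test_that("white-noise augmentation: SNR calibration, sentinel, determinism", {
  set.seed(2)
  sig <- array(rnorm(1 * 2 * 10000), c(1, 2, 10000)) # unit power
  ts <- trial_set(sig, 0L, fs = 100)

  aug <- white_noise_augment(ts, snr_db = 20, copies = 1, seed = 9)
  expect_equal(dim(aug$signals)[1], 2L)
  noise <- aug$signals[2, , ] - sig[1, , ]
  p_sig <- mean(sig[1, , ]^2)
  expect_lt(abs(mean(noise^2) / (0.01 * p_sig) - 1), 0.1)

  inf_aug <- white_noise_augment(ts, snr_db = Inf, copies = 2, seed = 9)
  expect_equal(inf_aug$signals[2, , ], sig[1, , ])
  expect_equal(inf_aug$signals[3, , ], sig[1, , ])

  a1 <- white_noise_augment(ts, snr_db = 10, copies = 3, seed = 4)
  a2 <- white_noise_augment(ts, snr_db = 10, copies = 3, seed = 4)
  expect_identical(a1$signals, a2$signals)

  expect_error(white_noise_augment(ts, snr_db = NaN), "snr_db")
})

test_that("augmentation preserves labels, fs, trial ids and multiplies counts", {
  tt <- tiny_trialset(n_per_class = 3)
  for (aug in list(sliding_window_augment(tt$ts, 0.5, 0.25),
                   white_noise_augment(tt$ts, 15, copies = 2, seed = 1))) {
    expect_equal(aug$fs, tt$ts$fs)
    expect_equal(dim(aug$signals)[2], dim(tt$ts$signals)[2])
    expect_true(dim(aug$signals)[1] %% dim(tt$ts$signals)[1] == 0)
    mult <- dim(aug$signals)[1] / dim(tt$ts$signals)[1]
    expect_equal(aug$labels, rep(tt$ts$labels, each = mult))
    expect_equal(aug$trial_ids, rep(tt$ts$trial_ids, each = mult))
  }
})

test_that("trial sets round-trip through the container and z-scoring standardizes", {
  tt <- tiny_trialset(n_per_class = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  write_trialset(tt$ts, f)
  back <- read_trialset(f)
  expect_identical(back$signals, tt$ts$signals)
  expect_identical(back$labels, tt$ts$labels)
  expect_identical(back$fs, tt$ts$fs)

  z <- zscore_trials(tt$ts)
  n_samp <- dim(z$signals)[3]
  expect_lt(max(abs(apply(z$signals, c(1, 2), mean))), 1e-12)
  expect_lt(max(abs(apply(z$signals, c(1, 2), stats::sd) *
                      sqrt((n_samp - 1) / n_samp) - 1)), 1e-10)
})
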