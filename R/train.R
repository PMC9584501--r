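#' Convert a trial set into the two branch input arrays
#'
#' Applies optional per-trial z-scoring, then computes the spatial-temporal
#' representation (resampled to `T_target` steps) and the spatial-spectral
#' representation (Welch PSD pooled into `F_target` bins over `band`) for
#' every trial.
#'
#' @param ts a [trial_set()].
#' @param T_target,F_target step-axis lengths (defaults 100).
#' @param band spectral band in Hz.
#' @param zscore standardize each electrode within each trial first.
#' @param resample_method passed to [to_spatial_temporal()].
#' @param nperseg,overlap Welch parameters, see [welch_psd()].
#' @return list with arrays `st` (n x N x T_target), `ss` (n x N x F_target),
#'   plus `labels`, `trial_ids`, `freq_axis`.
#' @export
prepare_tensors <- function(ts, T_target = 100L, F_target = 100L,
                            band = c(0.5, 50.5), zscore = TRUE,
                            resample_method = "fourier",
                            nperseg = NULL, overlap = 0.5) {
  stopifnot(inherits(ts, "trial_set"))
  if (zscore) ts <- zscore_trials(ts)
  d <- dim(ts$signals)
  st <- array(0, c(d[1], d[2], T_target))
  ss <- array(0, c(d[1], d[2], F_target))
  freq_axis <- NULL
  for (i in seq_len(d[1])) {
    x <- ts$signals[i, , , drop = FALSE]
    dim(x) <- d[2:3]
    st[i, , ] <- to_spatial_temporal(x, T_target, resample_method, fs = ts$fs)$values[, , 1]
    gt <- welch_psd(x, ts$fs, F_target, band, nperseg, overlap)
    ss[i, , ] <- gt$values[, , 1]
    freq_axis <- gt$axis
  }
  list(st = st, ss = ss, labels = ts$labels, trial_ids = ts$trial_ids,
       freq_axis = freq_axis)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (grp in names(params)) {
    for (nm in names(params[[grp]])) {
      gr <- grads[[grp]][[nm]]
      state$m[[grp]][[nm]] <- beta1 * state$m[[grp]][[nm]] + (1 - beta1) * gr
      state$v[[grp]][[nm]] <- beta2 * state$v[[grp]][[nm]] + (1 - beta2) * gr^2
      mh <- state$m[[grp]][[nm]] / bc1
      vh <- state$v[[grp]][[nm]] / bc2
      params[[grp]][[nm]] <- params[[grp]][[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, state = state)
}

slice_inputs <- function(arr, idx) {
  d <- dim(arr)
  lapply(idx, function(i) array(arr[i, , ], c(d[2], d[3], 1L)))
}

#' Train a C-GCNN by minibatch Adam on the cross-entropy loss
#'
#' Defaults follow the reference protocol (Adam, learning rate 0.001, batch
#' size 64); epochs, batch size and learning rate come from the model's
#' config unless overridden. Shuffling is seeded per epoch from the config
#' seed, so training is deterministic end to end.
#'
#' @param model a [cgcnn_model()].
#' @param tensors output of [prepare_tensors()] (fields `st`, `ss`, `labels`).
#' @param epochs,lr,batch_size overrides of the config values.
#' @param verbose print per-epoch loss.
#' @return the model with trained parameters and a `loss_history` field
#'   (mean training loss per epoch).
#' @export
train_cgcnn <- function(model, tensors, epochs = NULL, lr = NULL,
                        batch_size = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cgcnn"))
  cfg <- model$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  lr <- lr %||% cfg$lr
  batch_size <- as.integer(batch_size %||% cfg$batch_size)
  labels <- tensors$labels
  n <- length(labels)
  if (n == 0) stop_arg("empty training set")
  if (length(unique(labels)) < 2)
    stop_arg("training set must contain at least 2 classes")
  x_st <- if (cfg$use_st_branch) slice_inputs(tensors$st, seq_len(n)) else NULL
  x_ss <- if (cfg$use_ss_branch) slice_inputs(tensors$ss, seq_len(n)) else NULL
  state <- adam_init(model$params)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(cfg$seed, "shuffle", ep))
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      lg <- cgcnn_loss_grad(model,
                            if (is.null(x_st)) NULL else x_st[idx],
                            if (is.null(x_ss)) NULL else x_ss[idx],
                            labels[idx])
      st <- adam_step(model$params, lg$grads, state, lr)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    history[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, history[ep]))
  }
  model$loss_history <- history
  model
}
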