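#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred zero-based integer class labels of equal length.
#' @param n_classes number of classes m (default: inferred).
#' @return an object of class `confusion_matrix`: an m x m count matrix with
#'   true classes in rows and predicted classes in columns.
#' @export
confusion_matrix <- function(truth, pred, n_classes = NULL) {
  if (length(truth) != length(pred)) stop_arg("truth and pred lengths differ")
  m <- as.integer(n_classes %||% (max(c(truth, pred)) + 1L))
  counts <- matrix(0L, m, m)
  for (i in seq_along(truth)) {
    counts[truth[i] + 1L, pred[i] + 1L] <- counts[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  structure(counts, class = c("confusion_matrix", "matrix"))
}

as_conf <- function(conf) {
  if (!is.matrix(conf) || nrow(conf) != ncol(conf) || any(conf < 0))
    stop_arg("expected a square non-negative confusion matrix")
  if (sum(conf) == 0) stop_arg("empty confusion matrix (n = 0)")
  unclass(conf)
}

#' Classification accuracy
#'
#' Ratio of correctly classified samples (the trace) to the total count.
#'
#' @param conf a square confusion matrix (true x predicted counts).
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(conf) {
  conf <- as_conf(conf)
  sum(diag(conf)) / sum(conf)
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` where
#' `p_o = trace / n` is the observed accuracy and
#' `p_e = sum_m a_m * b_m / n^2` the chance agreement from the true class
#' totals `a_m` (row sums) and predicted totals `b_m` (column sums). In the
#' degenerate case `p_e = 1` (all mass in one cell) the convention is
#' `kappa = 0`, with a warning.
#'
#' @param conf a square confusion matrix (true x predicted counts).
#' @return kappa in `[-1, 1]`.
#' @examples
#' kappa_score(matrix(c(40, 20, 10, 30), 2)) # 0.4
#' @export
kappa_score <- function(conf) {
  conf <- as_conf(conf)
  n <- sum(conf)
  p_o <- sum(diag(conf)) / n
  p_e <- sum(rowSums(conf) * colSums(conf)) / n^2
  if (1 - p_e <= .Machine$double.eps) {
    warning("degenerate confusion matrix: p_e = 1, returning kappa = 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Stratified fold assignment
#'
#' Assigns each of `n` samples to one of `n_folds` folds, balancing classes:
#' within each class, samples are shuffled (seeded) and dealt out round-robin.
#'
#' @param labels zero-based class labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer fold index (1-based) per sample.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 0L) {
  n <- length(labels)
  fold <- integer(n)
  set.seed(derive_seed(seed, "folds"))
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    if (length(idx) < n_folds)
      stop_arg("class ", cls, " has only ", length(idx), " trials; need >= ",
               n_folds, " per class for stratified ", n_folds, "-fold CV")
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Subject-specific k-fold cross-validation
#'
#' The reference evaluation protocol: stratified 5-fold split on the source
#' trials, a model trained from scratch per fold, accuracy and Cohen's kappa
#' on the held-out fold, and the arithmetic mean over folds. Augmentation
#' (sliding window or white noise) is applied *inside* each training fold
#' only — split-then-augment — so no augmented segment of a held-out trial
#' can leak into training (fold membership follows `trial_id`).
#'
#' @param ts a [trial_set()] of source (un-augmented) trials.
#' @param config a [cgcnn_config()].
#' @param ops [build_spectral_operators()] matching the montage and config K.
#' @param seed master seed for folds, augmentation and per-fold model init.
#' @param n_folds number of folds (default 5).
#' @param augment `"none"`, `"sliding_window"` or `"white_noise"`.
#' @param augment_args list of arguments for the augmentation function.
#' @param T_target,F_target,band,zscore,nperseg,overlap representation
#'   parameters, see [prepare_tensors()].
#' @param epochs,lr,batch_size training overrides, see [train_cgcnn()].
#' @return an object of class `cv_result`: `per_fold` (data.frame with
#'   accuracy and kappa), `mean_accuracy`, `mean_kappa`, `fold_assignment`
#'   (trial_id -> fold), `confusions` (per-fold confusion matrices).
#' @export
cross_validate <- function(ts, config, ops, seed = 0L, n_folds = 5L,
                           augment = c("none", "sliding_window", "white_noise"),
                           augment_args = list(),
                           T_target = 100L, F_target = 100L, band = c(0.5, 50.5),
                           zscore = TRUE, nperseg = NULL, overlap = 0.5,
                           epochs = NULL, lr = NULL, batch_size = NULL) {
  stopifnot(inherits(ts, "trial_set"), inherits(config, "cgcnn_config"))
  augment <- match.arg(augment)
  fold <- stratified_folds(ts$labels, n_folds, seed)
  per_fold <- data.frame(fold = seq_len(n_folds), accuracy = NA_real_,
                         kappa = NA_real_)
  confusions <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr_set <- subset_trials(ts, which(fold != f))
    te_set <- subset_trials(ts, which(fold == f))
    if (augment == "sliding_window") {
      tr_set <- do.call(sliding_window_augment, c(list(tr_set), augment_args))
    } else if (augment == "white_noise") {
      aa <- augment_args
      aa$seed <- aa$seed %||% derive_seed(seed, "augment", f)
      tr_set <- do.call(white_noise_augment, c(list(tr_set), aa))
    }
    tr_tensors <- prepare_tensors(tr_set, T_target, F_target, band, zscore,
                                  nperseg = nperseg, overlap = overlap)
    te_tensors <- prepare_tensors(te_set, T_target, F_target, band, zscore,
                                  nperseg = nperseg, overlap = overlap)
    cfg_f <- config
    cfg_f$seed <- derive_seed(seed, "fold_model", f)
    model <- cgcnn_model(cfg_f, ops, T_target, F_target)
    model <- train_cgcnn(model, tr_tensors, epochs = epochs, lr = lr,
                         batch_size = batch_size)
    probs <- predict(model,
                     x_st = if (config$use_st_branch) te_tensors$st else NULL,
                     x_ss = if (config$use_ss_branch) te_tensors$ss else NULL)
    pred <- max.col(probs, ties.method = "first") - 1L
    conf <- confusion_matrix(te_set$labels, pred, config$n_classes)
    confusions[[f]] <- conf
    per_fold$accuracy[f] <- accuracy(conf)
    per_fold$kappa[f] <- kappa_score(conf)
  }
  structure(
    list(per_fold = per_fold,
         mean_accuracy = mean(per_fold$accuracy),
         mean_kappa = mean(per_fold$kappa),
         fold_assignment = stats::setNames(fold, ts$trial_ids),
         confusions = confusions),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", nrow(x$per_fold), "-fold: mean accuracy ",
      sprintf("%.4f", x$mean_accuracy), ", mean kappa ",
      sprintf("%.4f", x$mean_kappa), "\n", sep = "")
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}

#' Serialize a CV result to JSON
#'
#' @param cv a `cv_result`.
#' @param path output JSON path.
#' @export
write_cv_result <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  jsonlite::write_json(
    list(per_fold = cv$per_fold,
         mean_accuracy = cv$mean_accuracy,
         mean_kappa = cv$mean_kappa,
         fold_assignment = as.list(cv$fold_assignment)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
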