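# Shared fixtures: everything is generated in code, no binary data.

# random montage: n electrodes on distinct cells of an nr x nc grid
random_montage <- function(n, nr = 6L, nc = 6L) {
  stopifnot(n <= nr * nc)
  cells <- sample(nr * nc, n)
  montage(data.frame(name = paste0("E", seq_len(n)),
                     row = (cells - 1L) %/% nc,
                     col = (cells - 1L) %% nc))
}

# tiny dual-branch model + matching random inputs, for gradient/consistency
# tests (N = 6, L = 12 unless overridden)
tiny_model <- function(seed = 3L, n_trials = 4L, L = 12L, C1 = 3L, C2 = 3L,
                       K = 3L, ...) {
  ops <- build_spectral_operators(build_graph(grid_montage(2, 3)), K)
  cfg <- cgcnn_config(n_classes = 2L, C1 = C1, C2 = C2, K = K, seed = seed, ...)
  model <- cgcnn_model(cfg, ops, T_target = L, F_target = L)
  set.seed(seed)
  list(
    model = model, ops = ops, cfg = cfg,
    x_st = lapply(seq_len(n_trials), function(i) array(rnorm(6 * L), c(6, L, 1))),
    x_ss = lapply(seq_len(n_trials), function(i) array(abs(rnorm(6 * L)), c(6, L, 1))),
    labels = rep_len(c(0L, 1L), n_trials)
  )
}

# norm-based relative error between two gradient structures
grad_rel_err <- function(an, fd) {
  worst <- 0
  for (grp in names(an)) for (nm in names(an[[grp]])) {
    a <- as.vector(an[[grp]][[nm]])
    b <- as.vector(fd[[grp]][[nm]])
    re <- sqrt(sum((a - b)^2)) / max(sqrt(sum(a^2)) + sqrt(sum(b^2)), 1e-8)
    worst <- max(worst, re)
  }
  worst
}

# small labelled trial set with class-dependent oscillations, cheap enough
# for train/cv contract tests
tiny_trialset <- function(n_per_class = 10L, fs = 64, duration = 1,
                          n_rows = 2L, n_cols = 2L, seed = 1L) {
  mont <- grid_montage(n_rows, n_cols)
  spec <- synthetic_spec(
    mont, n_classes = 2L, trials_per_class = n_per_class, fs = fs,
    duration = duration,
    effects = list(
      list(active = 1:2, freq = 8, amplitude = 2),
      list(active = 3:4, freq = 20, amplitude = 2)),
    seed = seed)
  list(ts = generate_trials(spec), mont = mont, spec = spec)
}
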