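#' Model configuration
#'
#' Hyperparameters and ablation toggles of the dual-branch network. Defaults
#' follow the reference training protocol: Chebyshev order `K = 3`, 64
#' channels in both the graph convolution (`C1`) and the temporal/spectral
#' convolution (`C2`), a `(1, 5)` convolution kernel with stride 1 and valid
#' padding, Adam with learning rate 0.001, batch size 64.
#'
#' The ablation toggles reproduce the published model variants:
#' one branch only (`use_st_branch` / `use_ss_branch`), the plain dual-branch
#' model (`use_attention = FALSE`, `use_global_aggregation = FALSE`), dual
#' branch + aggregation, and the full model. With attention disabled the
#' spatial attention matrix is replaced by all-ones (leaving the Chebyshev
#' term unmodulated) and the temporal/spectral attention by the identity.
#' With aggregation disabled the branch feature is the global mean of the
#' convolution output over nodes and steps.
#'
#' @param n_classes number of classes (>= 2).
#' @param K Chebyshev polynomial order.
#' @param C1,C2 channel widths of graph convolution and temporal/spectral
#'   convolution.
#' @param kernel_t temporal/spectral convolution kernel length (the "5" in
#'   the (1,5) kernel).
#' @param use_st_branch,use_ss_branch,use_attention,use_global_aggregation,use_shortcut
#'   ablation toggles.
#' @param lr,batch_size,epochs Adam learning rate, minibatch size, training
#'   epochs.
#' @param seed integer seed governing weight initialization and shuffling.
#' @return an object of class `cgcnn_config`.
#' @export
cgcnn_config <- function(n_classes,
                         K = 3L, C1 = 64L, C2 = 64L, kernel_t = 5L,
                         use_st_branch = TRUE, use_ss_branch = TRUE,
                         use_attention = TRUE, use_global_aggregation = TRUE,
                         use_shortcut = TRUE,
                         lr = 0.001, batch_size = 64L, epochs = 100L,
                         seed = 0L) {
  if (n_classes < 2) stop_arg("n_classes must be >= 2")
  if (!use_st_branch && !use_ss_branch)
    stop_arg("at least one branch must be enabled")
  if (K < 0 || K != floor(K)) stop_arg("K must be a non-negative integer")
  if (C1 < 1 || C2 < 1) stop_arg("channel widths must be positive")
  if (kernel_t < 1) stop_arg("kernel_t must be positive")
  structure(
    list(n_classes = as.integer(n_classes), K = as.integer(K),
         C1 = as.integer(C1), C2 = as.integer(C2), kernel_t = as.integer(kernel_t),
         use_st_branch = isTRUE(use_st_branch), use_ss_branch = isTRUE(use_ss_branch),
         use_attention = isTRUE(use_attention),
         use_global_aggregation = isTRUE(use_global_aggregation),
         use_shortcut = isTRUE(use_shortcut),
         lr = lr, batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = as.integer(seed)),
    class = "cgcnn_config"
  )
}

glorot <- function(dims) {
  fan_in <- if (length(dims) >= 2) prod(dims[-length(dims)]) else dims[1]
  fan_out <- dims[length(dims)]
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

init_branch_params <- function(cfg, N, L, C_in) {
  L2 <- L - cfg$kernel_t + 1L
  if (L2 < 1)
    stop_arg("step axis (L = ", L, ") shorter than the convolution kernel (",
             cfg$kernel_t, ")")
  p <- list()
  if (cfg$use_attention) {
    p$ws1 <- glorot(c(C_in, 1))[, 1]; p$bs1 <- 0
    p$ws2 <- glorot(c(C_in, 1))[, 1]; p$bs2 <- 0
    p$wt1 <- glorot(c(cfg$C1, 1))[, 1]; p$bt1 <- 0
    p$wt2 <- glorot(c(cfg$C1, 1))[, 1]; p$bt2 <- 0
  }
  p$theta <- glorot(c(cfg$K + 1L, C_in, cfg$C1))
  # ReLU-layer biases start at a small positive constant: keeps units alive
  # and, with dead inputs, off the exact ReLU kink (where finite differences
  # and the subgradient disagree)
  p$W2 <- glorot(c(cfg$kernel_t * cfg$C1, cfg$C2)); p$b2 <- rep(0.01, cfg$C2)
  if (cfg$use_global_aggregation) {
    p$W3 <- glorot(c(N * cfg$C2, cfg$C2)); p$b3 <- rep(0.01, cfg$C2)
    p$W4 <- glorot(c(L2 * cfg$C2, cfg$C2)); p$b4 <- rep(0.01, cfg$C2)
  }
  if (cfg$use_shortcut) p$Wsc <- glorot(c(C_in, cfg$C2))
  p
}

#' Build a C-GCNN model
#'
#' Instantiates all learnable parameters (Glorot-uniform, seeded from
#' `config$seed`) for the given graph operators and branch input lengths.
#' Each enabled branch owns: spatial attention weights, the Chebyshev
#' coefficient tensors `theta` (one `C_in x C1` map per polynomial order),
#' temporal/spectral attention weights, the `(1, kernel_t)` convolution, the
#' two aggregation convolutions (`(N, 1)` then `(1, L2)`), and the shortcut
#' projection; the head is one fully connected layer over the concatenated
#' branch features followed by softmax.
#'
#' @param config a [cgcnn_config()].
#' @param ops [build_spectral_operators()] for the electrode graph.
#' @param T_target,F_target step-axis lengths of the spatial-temporal and
#'   spatial-spectral inputs.
#' @param C_in input channel count (1 for raw representations).
#' @return an object of class `cgcnn`.
#' @export
cgcnn_model <- function(config, ops, T_target = 100L, F_target = 100L, C_in = 1L) {
  stopifnot(inherits(config, "cgcnn_config"), inherits(ops, "spectral_operators"))
  if (config$K != ops$cheb_order)
    stop_arg("config K (", config$K, ") does not match the operator stack (K = ",
             ops$cheb_order, ")")
  N <- nrow(ops$laplacian_norm)
  set.seed(derive_seed(config$seed, "init"))
  params <- list()
  if (config$use_st_branch) params$st <- init_branch_params(config, N, T_target, C_in)
  if (config$use_ss_branch) params$ss <- init_branch_params(config, N, F_target, C_in)
  n_feat <- (config$use_st_branch + config$use_ss_branch) * config$C2
  params$fc <- list(Wfc = glorot(c(n_feat, config$n_classes)),
                    bfc = numeric(config$n_classes))
  structure(
    list(config = config, params = params, basis = ops$cheb_basis,
         dims = list(N = N, L_st = as.integer(T_target),
                     L_ss = as.integer(F_target), C_in = as.integer(C_in))),
    class = "cgcnn"
  )
}

#' @export
print.cgcnn <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(unlist(x$params, recursive = FALSE), length, integer(1)))
  cat("<cgcnn> N=", x$dims$N, " T=", x$dims$L_st, " F=", x$dims$L_ss,
      " K=", cfg$K, " C1=", cfg$C1, " C2=", cfg$C2,
      " classes=", cfg$n_classes, " params=", n_par, "\n",
      " branches: st=", cfg$use_st_branch, " ss=", cfg$use_ss_branch,
      " attention=", cfg$use_attention, " aggregation=", cfg$use_global_aggregation,
      " shortcut=", cfg$use_shortcut, "\n", sep = "")
  invisible(x)
}

# ---- layer operations (forward-only, exported per the module contract) ----

#' Raw pairwise attention scores
#'
#' Computes the unnormalized association-intensity matrix from a graph tensor
#' by contracting the channel axis with two weight vectors, Tanh-activating
#' both factors and taking their product. Spatial mode contracts the step
#' axis to give an N x N matrix of node-node intensities; temporal/spectral
#' mode contracts the node axis to give an L x L matrix of step-step
#' intensities.
#'
#' @param x numeric N x L x C array.
#' @param w1,w2 weight vectors of length C.
#' @param b1,b2 scalar biases.
#' @param mode `"spatial"`, `"temporal"` or `"spectral"`.
#' @return the raw attention matrix (N x N or L x L).
#' @seealso [l2_normalize_rows()] which turns this into the attention matrix
#'   used by the network.
#' @export
pairwise_attention <- function(x, w1, b1, w2, b2,
                               mode = c("spatial", "temporal", "spectral")) {
  mode <- match.arg(mode)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(w1) != d[3] || length(w2) != d[3])
    stop_arg("attention weight vectors must have length C = ", d[3])
  Xrs <- matrix(x, d[1] * d[2], d[3])
  f1 <- tanh(matrix(Xrs %*% w1, d[1], d[2]) + b1)
  f2 <- tanh(matrix(Xrs %*% w2, d[1], d[2]) + b2)
  if (mode == "spatial") f1 %*% t(f2) else crossprod(f1, f2)
}

#' Row-wise L2 normalization of an attention matrix
#'
#' Divides each row by its Euclidean norm, so every node's (or time step's)
#' outgoing attention has unit energy; all-zero rows are returned unchanged.
#'
#' @param a finite numeric matrix.
#' @return the normalized matrix.
#' @examples
#' l2_normalize_rows(matrix(c(3, 4), 1)) # 0.6 0.8
#' @export
l2_normalize_rows <- function(a) {
  if (!is.matrix(a) || !all(is.finite(a)))
    stop_arg("attention matrix must be a finite numeric matrix")
  rn <- sqrt(rowSums(a^2))
  scl <- ifelse(rn > 0, 1 / rn, 1)
  a * scl
}

#' Attention-modulated Chebyshev graph convolution
#'
#' Filters the node signal with `sum_k (T_k(L~) * a') x theta_k` where `*` is
#' the element-wise product of the k-th Chebyshev basis matrix with the
#' spatial attention matrix, applied independently at every step of the
#' time/frequency axis, followed by ReLU. With `a'` all ones this is the
#' plain (unmodulated) ChebNet spatial filter.
#'
#' @param x numeric N x L x C array.
#' @param ops [build_spectral_operators()] (supplies the T_k stack).
#' @param a_prime N x N spatial attention matrix.
#' @param theta Chebyshev coefficients: array `(K+1) x C x C1` (or a list of
#'   K+1 `C x C1` matrices).
#' @param activation `"relu"` or `"linear"` (pre-activation output).
#' @return numeric N x L x C1 array.
#' @export
attn_graph_conv <- function(x, ops, a_prime, theta, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  stopifnot(inherits(ops, "spectral_operators"))
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (is.list(theta)) {
    th <- array(0, c(length(theta), dim(theta[[1]])[1], dim(theta[[1]])[2]))
    for (k in seq_along(theta)) th[k, , ] <- theta[[k]]
    theta <- th
  }
  if (length(dim(theta)) == 1L) dim(theta) <- c(length(theta), 1L, 1L)
  K1 <- dim(theta)[1]
  if (K1 != ops$cheb_order + 1L)
    stop_arg("theta supplies ", K1 - 1L, " orders but the operator stack has K = ",
             ops$cheb_order)
  if (dim(theta)[2] != d[3]) stop_arg("theta input channels must equal C = ", d[3])
  if (!is.matrix(a_prime) || any(dim(a_prime) != d[1]))
    stop_arg("a_prime must be an N x N matrix")
  C1 <- dim(theta)[3]
  Xmat <- matrix(x, d[1], d[2] * d[3])
  pre <- matrix(0, d[1] * d[2], C1)
  for (k in seq_len(K1)) {
    M <- ops$cheb_basis[[k]] * a_prime
    Y2 <- matrix(array(M %*% Xmat, d), d[1] * d[2], d[3])
    pre <- pre + Y2 %*% matrix(theta[k, , ], d[3], C1)
  }
  if (activation == "relu") pre <- relu(pre)
  array(pre, c(d[1], d[2], C1))
}

#' Attention-modulated temporal / spectral convolution
#'
#' Contracts the step axis with the temporal (or spectral) attention matrix,
#' then applies a `(1, kernel_t)` stride-1 valid-padding 2-D convolution with
#' `C2` filters and ReLU. Valid padding means the output step axis shrinks to
#' `L2 = L - kernel_t + 1` while the node axis is untouched.
#'
#' @param x1 numeric N x L x C1 array (graph-convolution output).
#' @param a_prime L x L temporal/spectral attention matrix (identity recovers
#'   a plain convolution).
#' @param W numeric `(kernel_t * C1) x C2` weight matrix (kernel offset-major,
#'   channel-minor rows).
#' @param b bias vector of length C2.
#' @param activation `"relu"` or `"linear"`.
#' @return numeric N x L2 x C2 array.
#' @export
temporal_spectral_conv <- function(x1, a_prime, W, b, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  d <- dim(x1)
  if (!is.matrix(a_prime) || any(dim(a_prime) != d[2]))
    stop_arg("a_prime must be an L x L matrix with L = ", d[2])
  C1 <- d[3]
  k_t <- nrow(W) / C1
  if (k_t != floor(k_t)) stop_arg("nrow(W) must be a multiple of C1")
  if (d[2] < k_t)
    stop_arg("step axis (L = ", d[2], ") shorter than the convolution kernel (", k_t, ")")
  Xflat <- matrix(aperm(x1, c(1, 3, 2)), d[1] * C1, d[2])
  xa <- aperm(array(Xflat %*% a_prime, c(d[1], C1, d[2])), c(1, 3, 2))
  L2 <- d[2] - k_t + 1L
  Z <- matrix(0, d[1] * L2, k_t * C1)
  for (dd in seq_len(k_t)) {
    Z[, ((dd - 1) * C1 + 1):(dd * C1)] <-
      matrix(xa[, dd:(dd + L2 - 1), , drop = FALSE], d[1] * L2, C1)
  }
  C2 <- ncol(W)
  pre <- Z %*% W + matrix(b, d[1] * L2, C2, byrow = TRUE)
  if (activation == "relu") pre <- relu(pre)
  array(pre, c(d[1], L2, C2))
}

#' Global feature aggregation
#'
#' Two ReLU-activated convolutions collapse the remaining axes: an `(N, 1)`
#' kernel aggregates all nodes into the global spatial feature `x3`
#' (1 x L2 x C2), then a `(1, L2)` kernel aggregates all steps into the
#' global temporal/spectral feature `x4` (1 x 1 x C2, returned as a length-C2
#' vector).
#'
#' @param x2 numeric N x L2 x C2 array.
#' @param W3 `(N * C2) x C2` spatial aggregation weights, `b3` bias (C2).
#' @param W4 `(L2 * C2) x C2` temporal aggregation weights, `b4` bias (C2).
#' @param b3,b4 bias vectors of length C2.
#' @return list with `x3` (L2 x C2 matrix) and `x4` (length-C2 vector).
#' @export
global_aggregate <- function(x2, W3, b3, W4, b4) {
  d <- dim(x2)
  X2r <- matrix(aperm(x2, c(2, 1, 3)), d[2], d[1] * d[3])
  x3 <- relu(X2r %*% W3 + matrix(b3, d[2], length(b3), byrow = TRUE))
  x4 <- relu(drop(crossprod(W4, as.vector(x3))) + b4)
  list(x3 = x3, x4 = x4)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
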