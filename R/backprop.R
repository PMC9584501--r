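# Hand-written forward/backward passes for one branch and the fused head.
# The cached forward mirrors the exported layer ops exactly (a consistency
# test asserts this); the backward is verified against central finite
# differences in the test suite.

l2norm_rows_cached <- function(a) {
  rn <- sqrt(rowSums(a^2))
  scl <- ifelse(rn > 0, 1 / rn, 1)
  list(an = a * scl, norms = rn)
}

# d(loss)/d(raw a) given d(loss)/d(normalized a); rows with zero norm pass
# the gradient through unchanged (the map is the identity there).
l2norm_rows_backward <- function(dan, an, norms) {
  scl <- ifelse(norms > 0, 1 / norms, 1)
  (dan - an * rowSums(an * dan)) * scl
}

branch_forward <- function(x, p, basis, cfg, want_cache = TRUE) {
  d <- dim(x)
  N <- d[1]; L <- d[2]; C <- d[3]
  C1 <- cfg$C1; C2 <- cfg$C2; k_t <- cfg$kernel_t
  K1 <- cfg$K + 1L
  Xrs <- matrix(x, N * L, C)
  Xmat <- matrix(x, N, L * C)

  if (cfg$use_attention) {
    sl <- tanh(matrix(Xrs %*% p$ws1, N, L) + p$bs1)
    sr <- tanh(matrix(Xrs %*% p$ws2, N, L) + p$bs2)
    a_s <- sl %*% t(sr)
    ns <- l2norm_rows_cached(a_s)
    asn <- ns$an
  } else {
    sl <- sr <- NULL; ns <- NULL
    asn <- matrix(1, N, N)
  }

  pre1 <- matrix(0, N * L, C1)
  Mk <- vector("list", K1)
  Y2k <- vector("list", K1)
  for (k in seq_len(K1)) {
    Mk[[k]] <- basis[[k]] * asn
    Y2k[[k]] <- matrix(array(Mk[[k]] %*% Xmat, d), N * L, C)
    pre1 <- pre1 + Y2k[[k]] %*% matrix(p$theta[k, , ], C, C1)
  }
  mask1 <- pre1 > 0
  x1rs <- pre1 * mask1
  x1 <- array(x1rs, c(N, L, C1))

  if (cfg$use_attention) {
    tl <- tanh(matrix(x1rs %*% p$wt1, N, L) + p$bt1)
    tr <- tanh(matrix(x1rs %*% p$wt2, N, L) + p$bt2)
    a_t <- crossprod(tl, tr)
    nt <- l2norm_rows_cached(a_t)
    atn <- nt$an
  } else {
    tl <- tr <- NULL; nt <- NULL
    atn <- diag(1, L)
  }

  Xflat <- matrix(aperm(x1, c(1, 3, 2)), N * C1, L)
  xa <- aperm(array(Xflat %*% atn, c(N, C1, L)), c(1, 3, 2))

  L2 <- L - k_t + 1L
  Z <- matrix(0, N * L2, k_t * C1)
  for (dd in seq_len(k_t)) {
    Z[, ((dd - 1) * C1 + 1):(dd * C1)] <-
      matrix(xa[, dd:(dd + L2 - 1), , drop = FALSE], N * L2, C1)
  }
  pre2 <- Z %*% p$W2 + matrix(p$b2, N * L2, C2, byrow = TRUE)
  mask2 <- pre2 > 0
  x2rs <- pre2 * mask2
  x2 <- array(x2rs, c(N, L2, C2))

  if (cfg$use_global_aggregation) {
    X2r <- matrix(aperm(x2, c(2, 1, 3)), L2, N * C2)
    pre3 <- X2r %*% p$W3 + matrix(p$b3, L2, C2, byrow = TRUE)
    mask3 <- pre3 > 0
    x3 <- pre3 * mask3
    v3 <- as.vector(x3)
    pre4 <- drop(crossprod(p$W4, v3)) + p$b4
    mask4 <- pre4 > 0
    feat <- pre4 * mask4
  } else {
    X2r <- pre3 <- mask3 <- x3 <- v3 <- pre4 <- mask4 <- NULL
    feat <- colMeans(x2rs)
  }

  sc_in <- NULL
  if (cfg$use_shortcut) {
    sc_in <- colMeans(Xrs)
    feat <- feat + drop(crossprod(p$Wsc, sc_in))
  }

  cache <- if (want_cache) {
    list(d = d, Xrs = Xrs, Xmat = Xmat, sl = sl, sr = sr, ns = ns, asn = asn,
         Mk = Mk, Y2k = Y2k, mask1 = mask1, x1rs = x1rs, x1 = x1,
         tl = tl, tr = tr, nt = nt, atn = atn, Xflat = Xflat, xa = xa,
         Z = Z, mask2 = mask2, x2rs = x2rs, x2 = x2,
         X2r = X2r, mask3 = mask3, x3 = x3, v3 = v3, mask4 = mask4,
         sc_in = sc_in, L2 = L2)
  } else NULL
  list(feat = feat, cache = cache)
}

branch_backward <- function(dfeat, cache, p, basis, cfg) {
  d <- cache$d
  N <- d[1]; L <- d[2]; C <- d[3]
  C1 <- cfg$C1; C2 <- cfg$C2; k_t <- cfg$kernel_t
  K1 <- cfg$K + 1L
  L2 <- cache$L2
  g <- list()

  if (cfg$use_shortcut) g$Wsc <- tcrossprod(cache$sc_in, dfeat)

  if (cfg$use_global_aggregation) {
    dpre4 <- dfeat * cache$mask4
    g$W4 <- tcrossprod(cache$v3, dpre4)
    g$b4 <- dpre4
    dx3 <- matrix(drop(p$W4 %*% dpre4), L2, C2)
    dpre3 <- dx3 * cache$mask3
    g$W3 <- crossprod(cache$X2r, dpre3)
    g$b3 <- colSums(dpre3)
    dX2r <- dpre3 %*% t(p$W3)
    dx2rs <- matrix(aperm(array(dX2r, c(L2, N, C2)), c(2, 1, 3)), N * L2, C2)
  } else {
    dx2rs <- matrix(dfeat / (N * L2), N * L2, C2, byrow = TRUE)
  }

  dpre2 <- dx2rs * cache$mask2
  g$W2 <- crossprod(cache$Z, dpre2)
  g$b2 <- colSums(dpre2)
  dZ <- dpre2 %*% t(p$W2)
  dxa <- array(0, c(N, L, C1))
  for (dd in seq_len(k_t)) {
    blk <- array(dZ[, ((dd - 1) * C1 + 1):(dd * C1)], c(N, L2, C1))
    dxa[, dd:(dd + L2 - 1), ] <- dxa[, dd:(dd + L2 - 1), , drop = FALSE] + blk
  }

  dXaF <- matrix(aperm(dxa, c(1, 3, 2)), N * C1, L)
  dXflat <- dXaF %*% t(cache$atn)
  dx1rs <- matrix(aperm(array(dXflat, c(N, C1, L)), c(1, 3, 2)), N * L, C1)

  if (cfg$use_attention) {
    datn <- crossprod(cache$Xflat, dXaF)
    da_t <- l2norm_rows_backward(datn, cache$atn, cache$nt$norms)
    dtl <- cache$tr %*% t(da_t)
    dtr <- cache$tl %*% da_t
    dtl_pre <- dtl * (1 - cache$tl^2)
    dtr_pre <- dtr * (1 - cache$tr^2)
    g$wt1 <- drop(crossprod(cache$x1rs, as.vector(dtl_pre)))
    g$bt1 <- sum(dtl_pre)
    g$wt2 <- drop(crossprod(cache$x1rs, as.vector(dtr_pre)))
    g$bt2 <- sum(dtr_pre)
    dx1rs <- dx1rs + tcrossprod(as.vector(dtl_pre), p$wt1) +
      tcrossprod(as.vector(dtr_pre), p$wt2)
  }

  dpre1 <- dx1rs * cache$mask1
  g$theta <- array(0, dim(p$theta))
  dasn <- matrix(0, N, N)
  for (k in seq_len(K1)) {
    g$theta[k, , ] <- crossprod(cache$Y2k[[k]], dpre1)
    G2 <- dpre1 %*% t(matrix(p$theta[k, , ], C, C1))
    G <- matrix(array(G2, c(N, L, C)), N, L * C)
    dasn <- dasn + tcrossprod(G, cache$Xmat) * basis[[k]]
  }

  if (cfg$use_attention) {
    da_s <- l2norm_rows_backward(dasn, cache$asn, cache$ns$norms)
    dsl <- da_s %*% cache$sr
    dsr <- t(da_s) %*% cache$sl
    dsl_pre <- dsl * (1 - cache$sl^2)
    dsr_pre <- dsr * (1 - cache$sr^2)
    g$ws1 <- drop(crossprod(cache$Xrs, as.vector(dsl_pre)))
    g$bs1 <- sum(dsl_pre)
    g$ws2 <- drop(crossprod(cache$Xrs, as.vector(dsr_pre)))
    g$bs2 <- sum(dsr_pre)
  }
  g
}

as_branch_input <- function(x, dims, which) {
  L <- if (which == "st") dims$L_st else dims$L_ss
  if (inherits(x, "graph_tensor")) x <- x$values
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] != dims$N || d[2] != L || d[3] != dims$C_in)
    stop_arg(which, " branch input must be ", dims$N, " x ", L, " x ", dims$C_in,
             " (got ", paste(d, collapse = " x "), ")")
  x
}

#' Forward pass: class probabilities for one trial
#'
#' Runs every enabled branch (attention, graph convolution, temporal/spectral
#' attention + convolution, global aggregation, shortcut), concatenates the
#' branch features, applies the fully connected fusion layer and softmax.
#'
#' @param model a [cgcnn_model()].
#' @param x_st spatial-temporal input (graph_tensor or N x T x 1 array);
#'   required when the spatial-temporal branch is enabled.
#' @param x_ss spatial-spectral input; required when that branch is enabled.
#' @param detail if TRUE also return the branch features and attention
#'   matrices produced along the way.
#' @return numeric probability vector of length `n_classes` (sums to 1), or a
#'   list when `detail = TRUE`.
#' @export
forward <- function(model, x_st = NULL, x_ss = NULL, detail = FALSE) {
  stopifnot(inherits(model, "cgcnn"))
  cfg <- model$config
  if (!cfg$use_st_branch && !is.null(x_st))
    warning("spatial-temporal branch is disabled; x_st ignored")
  if (!cfg$use_ss_branch && !is.null(x_ss))
    warning("spatial-spectral branch is disabled; x_ss ignored")
  feats <- list()
  caches <- list()
  if (cfg$use_st_branch) {
    if (is.null(x_st)) stop_arg("x_st required: spatial-temporal branch is enabled")
    b <- branch_forward(as_branch_input(x_st, model$dims, "st"),
                        model$params$st, model$basis, cfg, want_cache = detail)
    feats$st <- b$feat; caches$st <- b$cache
  }
  if (cfg$use_ss_branch) {
    if (is.null(x_ss)) stop_arg("x_ss required: spatial-spectral branch is enabled")
    b <- branch_forward(as_branch_input(x_ss, model$dims, "ss"),
                        model$params$ss, model$basis, cfg, want_cache = detail)
    feats$ss <- b$feat; caches$ss <- b$cache
  }
  z <- unlist(feats, use.names = FALSE)
  probs <- softmax(drop(crossprod(model$params$fc$Wfc, z)) + model$params$fc$bfc)
  if (!detail) return(probs)
  list(probs = probs, features = feats,
       attention = list(
         spatial = lapply(caches, function(cc) cc$asn),
         steps = lapply(caches, function(cc) cc$atn)))
}

# Mean cross-entropy loss and parameter gradients over a batch.
# x_st / x_ss: lists (or NULL) of per-trial input arrays; labels zero-based.
cgcnn_loss_grad <- function(model, x_st, x_ss, labels, want_grad = TRUE) {
  cfg <- model$config
  n <- length(labels)
  grads <- if (want_grad) zero_like(model$params) else NULL
  loss <- 0
  eps <- 1e-12
  for (i in seq_len(n)) {
    feats <- list(); caches <- list()
    if (cfg$use_st_branch) {
      b <- branch_forward(x_st[[i]], model$params$st, model$basis, cfg, want_grad)
      feats$st <- b$feat; caches$st <- b$cache
    }
    if (cfg$use_ss_branch) {
      b <- branch_forward(x_ss[[i]], model$params$ss, model$basis, cfg, want_grad)
      feats$ss <- b$feat; caches$ss <- b$cache
    }
    z <- unlist(feats, use.names = FALSE)
    probs <- softmax(drop(crossprod(model$params$fc$Wfc, z)) + model$params$fc$bfc)
    y <- labels[i] + 1L
    loss <- loss - log(probs[y] + eps)
    if (!want_grad) next
    dlogits <- probs
    dlogits[y] <- dlogits[y] - 1
    grads$fc$Wfc <- grads$fc$Wfc + tcrossprod(z, dlogits)
    grads$fc$bfc <- grads$fc$bfc + dlogits
    dz <- drop(model$params$fc$Wfc %*% dlogits)
    off <- 0L
    for (br in names(feats)) {
      dfeat <- dz[(off + 1L):(off + cfg$C2)]
      off <- off + cfg$C2
      gb <- branch_backward(dfeat, caches[[br]], model$params[[br]], model$basis, cfg)
      grads[[br]] <- add_params(grads[[br]], gb)
    }
  }
  loss <- loss / n
  if (want_grad) grads <- scale_params(grads, 1 / n)
  list(loss = loss, grads = grads)
}

zero_like <- function(params) {
  lapply(params, function(grp) lapply(grp, function(a) {
    z <- a; z[] <- 0; z
  }))
}

add_params <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_params <- function(a, s) {
  lapply(a, function(grp) lapply(grp, function(x) x * s))
}

#' Central finite-difference gradient of the batch loss
#'
#' Independent oracle for the analytic backward pass: perturbs every
#' parameter entry by +/- eps and differences the loss. Quadratic cost — use
#' only on tiny models.
#'
#' @param model a [cgcnn_model()].
#' @param x_st,x_ss lists of per-trial branch inputs (or NULL for a disabled
#'   branch).
#' @param labels zero-based class labels.
#' @param eps perturbation step.
#' @return a gradient structure mirroring `model$params`.
#' @export
numeric_grad <- function(model, x_st, x_ss, labels, eps = 1e-6) {
  g <- zero_like(model$params)
  for (grp in names(model$params)) {
    for (nm in names(model$params[[grp]])) {
      arr <- model$params[[grp]][[nm]]
      for (j in seq_along(arr)) {
        m2 <- model
        m2$params[[grp]][[nm]][j] <- arr[j] + eps
        lp <- cgcnn_loss_grad(m2, x_st, x_ss, labels, want_grad = FALSE)$loss
        m2$params[[grp]][[nm]][j] <- arr[j] - eps
        lm <- cgcnn_loss_grad(m2, x_st, x_ss, labels, want_grad = FALSE)$loss
        g[[grp]][[nm]][j] <- (lp - lm) / (2 * eps)
      }
    }
  }
  g
}

#' Predict class probabilities for a set of trials
#'
#' @param object a trained [cgcnn_model()].
#' @param x_st optional array `n x N x T` of spatial-temporal inputs.
#' @param x_ss optional array `n x N x F` of spatial-spectral inputs.
#' @param ... unused.
#' @return an `n x n_classes` matrix of probabilities (rows sum to 1).
#' @export
predict.cgcnn <- function(object, x_st = NULL, x_ss = NULL, ...) {
  n <- if (!is.null(x_st)) dim(x_st)[1] else dim(x_ss)[1]
  out <- matrix(0, n, object$config$n_classes)
  for (i in seq_len(n)) {
    xs <- if (!is.null(x_st)) array(x_st[i, , ], c(dim(x_st)[2:3], 1L)) else NULL
    xf <- if (!is.null(x_ss)) array(x_ss[i, , ], c(dim(x_ss)[2:3], 1L)) else NULL
    out[i, ] <- forward(object, xs, xf)
  }
  out
}
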