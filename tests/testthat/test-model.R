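test_that("pairwise_attention: shapes, zero case, scalar hand oracle", {
  set.seed(8)
  x <- array(rnorm(5 * 7 * 2), c(5, 7, 2))
  w <- rnorm(2)
  a_sp <- pairwise_attention(x, w, 0.1, rev(w), -0.2, mode = "spatial")
  expect_equal(dim(a_sp), c(5L, 5L))
  a_tp <- pairwise_attention(x, w, 0.1, rev(w), -0.2, mode = "temporal")
  expect_equal(dim(a_tp), c(7L, 7L))

  expect_equal(pairwise_attention(array(0, c(3, 4, 1)), 1, 0, 1, 0, "spatial"),
               matrix(0, 3, 3))

  # N = 2, T = 1, C = 1, unit weights, zero biases: entry (i,j) = tanh(x_i) tanh(x_j)
  x2 <- array(c(0.7, -1.3), c(2, 1, 1))
  a <- pairwise_attention(x2, 1, 0, 1, 0, "spatial")
  expect_equal(a, tanh(c(0.7, -1.3)) %o% tanh(c(0.7, -1.3)))

  expect_error(pairwise_attention(x, rnorm(3), 0, w, 0), "length C")
})

test_that("l2_normalize_rows: hand values, idempotence, zero rows, non-finite", {
  expect_equal(l2_normalize_rows(matrix(c(3, 4), 1)), matrix(c(0.6, 0.8), 1))
  expect_equal(l2_normalize_rows(diag(4)), diag(4))
  m <- l2_normalize_rows(matrix(c(1, 0, 1, 0), 2)) # second row all zero? no:
  # rows are (1,1) and (0,0)
  expect_equal(m, matrix(c(1 / sqrt(2), 0, 1 / sqrt(2), 0), 2))
  set.seed(3)
  a <- matrix(rnorm(25), 5)
  expect_equal(l2_normalize_rows(l2_normalize_rows(a)), l2_normalize_rows(a))
  expect_error(l2_normalize_rows(matrix(c(1, NA), 1)), "finite")
})

test_that("attn_graph_conv: all-ones modulation, K = 0 identity, spectral oracle", {
  set.seed(10)
  ops <- build_spectral_operators(build_graph(random_montage(6)), 3)
  x <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  theta <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  ones <- matrix(1, 6, 6)

  # all-ones attention leaves the Chebyshev term unmodulated: compare against
  # a direct per-step evaluation of sum_k T_k x theta_k
  got <- attn_graph_conv(x, ops, ones, theta, activation = "linear")
  want <- array(0, c(6, 8, 3))
  for (l in 1:8) {
    acc <- matrix(0, 6, 3)
    for (k in 1:4) acc <- acc + ops$cheb_basis[[k]] %*% x[, l, ] %*% theta[k, , ]
    want[, l, ] <- acc
  }
  expect_equal(got, want, tolerance = 1e-12)

  # K = 0 with identity coefficient map and non-negative input: output = input
  ops0 <- build_spectral_operators(build_graph(random_montage(6)), 0)
  xp <- array(abs(rnorm(6 * 5)), c(6, 5, 1))
  got0 <- attn_graph_conv(xp, ops0, ones, array(1, c(1, 1, 1)))
  expect_equal(got0, xp)

  # spectral-domain oracle: recursion equals U g(Lambda~) U^T x
  th <- rnorm(4)
  xs <- array(rnorm(6 * 8), c(6, 8, 1))
  got_pre <- attn_graph_conv(xs, ops, ones, array(th, c(4, 1, 1)),
                             activation = "linear")
  ed <- eigen(ops$laplacian_scaled, symmetric = TRUE)
  Tl <- list(rep(1, 6), ed$values)
  for (k in 3:4) Tl[[k]] <- 2 * ed$values * Tl[[k - 1]] - Tl[[k - 2]]
  g_lam <- Reduce(`+`, Map(`*`, th, Tl))
  for (l in 1:8) {
    oracle <- ed$vectors %*% (g_lam * crossprod(ed$vectors, xs[, l, 1]))
    expect_lt(max(abs(got_pre[, l, 1] - oracle)), 1e-6)
  }

  expect_error(attn_graph_conv(x, ops, ones, array(0, c(3, 2, 3))), "orders")
})

test_that("temporal_spectral_conv: output length, identity attention, kernel error", {
  set.seed(12)
  x1 <- array(rnorm(4 * 100 * 3), c(4, 100, 3))
  W <- matrix(rnorm(5 * 3 * 6), 15, 6)
  b <- rnorm(6)
  out <- temporal_spectral_conv(x1, diag(100), W, b)
  expect_equal(dim(out), c(4L, 96L, 6L)) # L2 = (100 - 5)/1 + 1

  # identity attention equals a directly evaluated plain convolution
  direct <- array(0, c(4, 96, 6))
  for (n in 1:4) for (t in 1:96) {
    patch <- as.vector(t(x1[n, t:(t + 4), ])) # channel-minor, offset-major
    direct[n, t, ] <- pmax(drop(patch %*% W) + b, 0)
  }
  expect_equal(out, direct, tolerance = 1e-12)

  expect_error(temporal_spectral_conv(array(0, c(4, 4, 3)), diag(4), W, b),
               "shorter than the convolution kernel")
})

test_that("global_aggregate: shapes, zero case, constant-field closed form", {
  set.seed(14)
  N <- 5; L2 <- 7; C2 <- 4
  x2 <- array(rnorm(N * L2 * C2), c(N, L2, C2))
  W3 <- matrix(rnorm(N * C2 * C2), N * C2, C2)
  W4 <- matrix(rnorm(L2 * C2 * C2), L2 * C2, C2)
  out <- global_aggregate(x2, W3, rnorm(C2), W4, rnorm(C2))
  expect_equal(dim(out$x3), c(L2, C2))
  expect_length(out$x4, C2) # the 1 x 1 x C2 global feature

  zz <- global_aggregate(array(0, c(N, L2, C2)), W3, numeric(C2), W4, numeric(C2))
  expect_equal(zz$x4, numeric(C2))

  # constant input c with unit-sum aggregation weights and zero bias: x3 = c
  cval <- 1.7
  W3u <- matrix(1 / (N * C2), N * C2, C2)
  cons <- global_aggregate(array(cval, c(N, L2, C2)), W3u, numeric(C2), W4,
                           numeric(C2))
  expect_equal(cons$x3, matrix(cval, L2, C2))
})

test_that("forward produces normalized probabilities and honours branch toggles", {
  tm <- tiny_model(seed = 4)
  p <- forward(tm$model, tm$x_st[[1]], tm$x_ss[[1]])
  expect_length(p, 2L)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))

  # 4-class configuration (BCICIV-2a shaped)
  cfg4 <- cgcnn_config(n_classes = 4, C1 = 3, C2 = 3, K = 3, seed = 1)
  m4 <- cgcnn_model(cfg4, tm$ops, 12, 12)
  expect_length(forward(m4, tm$x_st[[1]], tm$x_ss[[1]]), 4L)

  # single-branch variant only needs its own input; supplying the other warns
  cfg1 <- cgcnn_config(n_classes = 2, C1 = 3, C2 = 3, K = 3,
                       use_ss_branch = FALSE, seed = 1)
  m1 <- cgcnn_model(cfg1, tm$ops, 12, 12)
  expect_length(forward(m1, x_st = tm$x_st[[1]]), 2L)
  expect_warning(forward(m1, tm$x_st[[1]], tm$x_ss[[1]]), "disabled")
  expect_error(forward(m1, x_st = NULL), "x_st required")
  expect_error(cgcnn_config(n_classes = 2, use_st_branch = FALSE,
                            use_ss_branch = FALSE), "at least one branch")

  # deterministic given fixed parameters and input
  expect_identical(forward(tm$model, tm$x_st[[1]], tm$x_ss[[1]]),
                   forward(tm$model, tm$x_st[[1]], tm$x_ss[[1]]))
})

test_that("permuting classification-head classes permutes the probabilities", {
  tm <- tiny_model(seed = 6)
  cfg3 <- cgcnn_config(n_classes = 3, C1 = 3, C2 = 3, K = 3, seed = 2)
  m3 <- cgcnn_model(cfg3, tm$ops, 12, 12)
  p <- forward(m3, tm$x_st[[1]], tm$x_ss[[1]])
  perm <- c(3L, 1L, 2L)
  m3p <- m3
  m3p$params$fc$Wfc <- m3$params$fc$Wfc[, perm]
  m3p$params$fc$bfc <- m3$params$fc$bfc[perm]
  expect_equal(forward(m3p, tm$x_st[[1]], tm$x_ss[[1]]), p[perm],
               tolerance = 1e-12)
})

test_that("node permutation leaves class probabilities unchanged", {
  set.seed(17)
  m <- random_montage(7)
  ops <- build_spectral_operators(build_graph(m), 3)
  cfg <- cgcnn_config(n_classes = 2, C1 = 3, C2 = 3, K = 3, seed = 5)
  mod <- cgcnn_model(cfg, ops, 10, 10)
  x_st <- array(rnorm(7 * 10), c(7, 10, 1))
  x_ss <- array(abs(rnorm(7 * 10)), c(7, 10, 1))
  p <- forward(mod, x_st, x_ss)

  perm <- sample(7)
  mp <- montage(m$entries[perm, ])
  opsp <- build_spectral_operators(build_graph(mp), 3)
  modp <- cgcnn_model(cfg, opsp, 10, 10)
  # node-symmetric parameters transfer unchanged except the (N,1) aggregation
  # kernel, whose node-blocks must be permuted alongside the inputs
  modp$params <- mod$params
  for (br in c("st", "ss")) {
    W3 <- mod$params[[br]]$W3
    blocks <- array(W3, c(7, ncol(W3), ncol(W3))) # rows are node-major
    modp$params[[br]]$W3 <- matrix(blocks[perm, , ], nrow(W3), ncol(W3))
  }
  pp <- forward(modp, x_st[perm, , , drop = FALSE], x_ss[perm, , , drop = FALSE])
  expect_equal(pp, p, tolerance = 1e-8)
})

test_that("cached branch forward agrees with the exported layer ops", {
  tm <- tiny_model(seed = 9)
  x <- tm$x_st[[1]]
  p <- tm$model$params$st
  det <- forward(tm$model, x, tm$x_ss[[1]], detail = TRUE)
  a_s <- l2_normalize_rows(pairwise_attention(x, p$ws1, p$bs1, p$ws2, p$bs2,
                                              "spatial"))
  expect_equal(det$attention$spatial$st, a_s, tolerance = 1e-12)
  x1 <- attn_graph_conv(x, tm$ops, a_s, p$theta)
  a_t <- l2_normalize_rows(pairwise_attention(x1, p$wt1, p$bt1, p$wt2, p$bt2,
                                              "temporal"))
  expect_equal(det$attention$steps$st, a_t, tolerance = 1e-12)
  x2 <- temporal_spectral_conv(x1, a_t, p$W2, p$b2)
  agg <- global_aggregate(x2, p$W3, p$b3, p$W4, p$b4)
  sc <- drop(crossprod(p$Wsc, colMeans(matrix(x, 6 * 12, 1))))
  expect_equal(det$features$st, agg$x4 + sc, tolerance = 1e-12)
})

test_that("ablation toggles reduce the network as specified", {
  # attention off == attention replaced by ones (spatial) / identity (steps)
  tm <- tiny_model(seed = 15, use_attention = FALSE)
  x <- tm$x_st[[1]]
  p <- tm$model$params$st
  det <- forward(tm$model, x, tm$x_ss[[1]], detail = TRUE)
  x1 <- attn_graph_conv(x, tm$ops, matrix(1, 6, 6), p$theta)
  x2 <- temporal_spectral_conv(x1, diag(12), p$W2, p$b2)
  agg <- global_aggregate(x2, p$W3, p$b3, p$W4, p$b4)
  sc <- drop(crossprod(p$Wsc, colMeans(matrix(x, 6 * 12, 1))))
  expect_equal(det$features$st, agg$x4 + sc, tolerance = 1e-12)

  # aggregation off: branch feature is the global mean of x2
  tm2 <- tiny_model(seed = 16, use_attention = FALSE,
                    use_global_aggregation = FALSE, use_shortcut = FALSE)
  x <- tm2$x_st[[1]]
  p2 <- tm2$model$params$st
  det2 <- forward(tm2$model, x, tm2$x_ss[[1]], detail = TRUE)
  x1 <- attn_graph_conv(x, tm2$ops, matrix(1, 6, 6), p2$theta)
  x2 <- temporal_spectral_conv(x1, diag(12), p2$W2, p2$b2)
  expect_equal(det2$features$st, apply(x2, 3, mean), tolerance = 1e-12)
})

test_that("every attention matrix produced in forward has unit-norm rows", {
  set.seed(19)
  for (rep in 1:5) {
    tm <- tiny_model(seed = rep + 30)
    det <- forward(tm$model, tm$x_st[[1]], tm$x_ss[[1]], detail = TRUE)
    for (a in c(det$attention$spatial, det$attention$steps)) {
      rn <- sqrt(rowSums(a^2))
      expect_true(all(abs(rn[rn > 0] - 1) < 1e-6))
    }
  }
})
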