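#' Build the EEG electrode graph from a montage
#'
#' Nodes are electrodes; an undirected edge joins two electrodes whose grid
#' cells differ by at most 1 in both row and column (Chebyshev grid distance
#' 1), so each interior node of a full grid has 8 neighbours. Every node is
#' additionally connected to itself: the adjacency matrix has a unit diagonal.
#'
#' @param mont a [montage()] object.
#' @return an object of class `electrode_graph` with fields `n_nodes`,
#'   `edges` (2-column matrix of node index pairs, i < j), `adjacency`
#'   (N x N binary, symmetric, unit diagonal) and `electrode_names`.
#' @examples
#' g <- build_graph(grid_montage(3, 3))
#' sum(g$adjacency[5, ]) - 1  # centre node: 8 neighbours
#' @export
build_graph <- function(mont) {
  if (!inherits(mont, "cgcnn_montage")) stop_arg("build_graph expects a cgcnn_montage")
  n <- mont$n_electrodes
  r <- mont$entries$row
  c <- mont$entries$col
  A <- diag(1, n)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    idx <- utils::combn(n, 2)
    dr <- abs(r[idx[1, ]] - r[idx[2, ]])
    dc <- abs(c[idx[1, ]] - c[idx[2, ]])
    adj <- dr <= 1 & dc <= 1
    edges <- t(idx[, adj, drop = FALSE])
    for (e in seq_len(nrow(edges))) {
      A[edges[e, 1], edges[e, 2]] <- 1
      A[edges[e, 2], edges[e, 1]] <- 1
    }
  }
  dimnames(edges) <- NULL
  structure(
    list(n_nodes = n, edges = edges, adjacency = A,
         electrode_names = mont$entries$name),
    class = "electrode_graph"
  )
}

#' @export
print.electrode_graph <- function(x, ...) {
  cat("<electrode_graph> ", x$n_nodes, " nodes, ", nrow(x$edges),
      " undirected edges (+ self-loops)\n", sep = "")
  invisible(x)
}

#' Spectral graph operators and the Chebyshev polynomial basis
#'
#' From the (self-looped) adjacency A computes the degree matrix D, the
#' symmetric normalized Laplacian L = I - D^(-1/2) A D^(-1/2), its largest
#' eigenvalue lambda_max, the rescaled Laplacian L~ = 2 L / lambda_max - I
#' whose spectrum lies in \[-1, 1\], and the stack of Chebyshev polynomials
#' T_0(L~) .. T_K(L~) via the recursion T_k = 2 L~ T_(k-1) - T_(k-2),
#' T_0 = I, T_1 = L~. Graph convolution then filters node signals with
#' sum_k theta_k T_k(L~) without any eigendecomposition.
#'
#' Isolated electrodes are legal: their self-loop gives degree 1 and a zero
#' Laplacian row after normalization.
#'
#' @param graph an [build_graph()] result.
#' @param K Chebyshev order (stack has K + 1 matrices); default 3.
#' @return an object of class `spectral_operators` with fields `degree`,
#'   `laplacian_norm`, `lambda_max`, `laplacian_scaled`, `cheb_order`,
#'   `cheb_basis` (list of K + 1 N x N matrices).
#' @export
build_spectral_operators <- function(graph, K = 3L) {
  if (!inherits(graph, "electrode_graph"))
    stop_arg("build_spectral_operators expects an electrode_graph")
  if (length(K) != 1L || !is.finite(K) || K != floor(K) || K < 0)
    stop_arg("K must be a non-negative integer (got ", K, ")")
  K <- as.integer(K)
  A <- graph$adjacency
  n <- graph$n_nodes
  d <- rowSums(A)
  D <- diag(d, n)
  dis <- 1 / sqrt(d) # self-loops guarantee d >= 1
  L <- diag(1, n) - (dis * A) %*% diag(dis, n) # D^(-1/2) A D^(-1/2)
  L <- (L + t(L)) / 2 # enforce exact symmetry
  lambda_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_max < .Machine$double.eps) lambda_max <- 1 # edgeless single node
  Ls <- 2 * L / lambda_max - diag(1, n)
  basis <- vector("list", K + 1L)
  basis[[1]] <- diag(1, n)
  if (K >= 1) basis[[2]] <- Ls
  if (K >= 2) {
    for (k in 3:(K + 1L)) basis[[k]] <- 2 * Ls %*% basis[[k - 1]] - basis[[k - 2]]
  }
  structure(
    list(degree = D, laplacian_norm = L, lambda_max = lambda_max,
         laplacian_scaled = Ls, cheb_order = K, cheb_basis = basis),
    class = "spectral_operators"
  )
}

#' @export
print.spectral_operators <- function(x, ...) {
  cat("<spectral_operators> N = ", nrow(x$laplacian_norm),
      ", K = ", x$cheb_order,
      ", lambda_max = ", format(x$lambda_max, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Save / load spectral operators
#'
#' Runtime serialization of the operator set (adjacency is recoverable from
#' degree and Laplacian; it is stored alongside for inspection). Stored as an
#' RDS file: the environment offers no HDF5 binding, and these are runtime
#' artifacts, not package data.
#'
#' @param ops a `spectral_operators` object.
#' @param graph the `electrode_graph` the operators were built from.
#' @param path output file path.
#' @export
write_operators <- function(ops, graph, path) {
  stopifnot(inherits(ops, "spectral_operators"), inherits(graph, "electrode_graph"))
  saveRDS(list(adjacency = graph$adjacency,
               laplacian = ops$laplacian_norm,
               cheb_basis = ops$cheb_basis,
               lambda_max = ops$lambda_max,
               cheb_order = ops$cheb_order), path)
  invisible(path)
}
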