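#' Functional-connectivity matrix from ROI signals
#'
#' Edge values are normalized dot products (cosines) between ROI voxel
#' vectors: `C[i, j] = (F_i . F_j) / (||F_i|| * ||F_j|| + eps)` with an
#' epsilon guard of 1e-8 on the norm product. The result is symmetric with
#' entries in \[-1, 1\] and a diagonal of ~1 for non-zero vectors; all-zero
#' vectors yield ~0 rows rather than errors. Zero padding of the node
#' vectors is inert because padded entries are exactly 0.
#'
#' @param nodes an [roi_signal_set()] or an `R x D` numeric matrix (rows =
#'   ROIs).
#' @return `R x R` numeric matrix.
#' @export
compute_connectivity <- function(nodes) {
  N <- if (is_roi_signal_set(nodes)) nodes$vectors else as.matrix(nodes)
  G <- N %*% t(N)
  nrm <- sqrt(diag(G))
  G / (outer(nrm, nrm) + .EPS)
}

#' NEI-GNN parameters
#'
#' One block of the node-edge interaction graph layer owns a learnable
#' weight vector `w_r` per ROI (length `D`, used to project updated node
#' vectors onto scalars) and a learnable scalar `w_{r1,r2}` per ordered ROI
#' pair (used to weight edge contributions). Blocks are not shared: each of
#' the `K` stacked blocks has its own parameter slice, so deeper blocks can
#' specialise as the receptive field over the graph grows.
#'
#' Initialization (not prescribed by the block equations): node weights
#' `~ Normal(0, 1/D)`, edge weights `~ Normal(0, 1/R)` (variances).
#'
#' @param R number of ROIs.
#' @param D padded voxel-vector length.
#' @param K number of stacked blocks (>= 0).
#' @param seed optional seed for reproducible initialization.
#' @return An object of class `nei_gnn_params`: list of `K` blocks, each
#'   with `node_weights` (`R x D`) and `edge_weights` (`R x R`), plus
#'   attributes `R`, `D`, `K`.
#' @export
nei_gnn_params <- function(R, D, K = 2, seed = NULL) {
  if (K < 0) stop_input("K must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(seq_len(K), function(k)
    list(node_weights = matrix(rnorm(R * D, sd = sqrt(1 / D)), R, D),
         edge_weights = matrix(rnorm(R * R, sd = sqrt(1 / R)), R, R)))
  structure(blocks, class = "nei_gnn_params", R = R, D = D, K = K)
}

check_graph_shapes <- function(N, E) {
  N <- as.matrix(N); E <- as.matrix(E)
  if (nrow(E) != ncol(E)) stop_input("edge matrix must be square")
  if (nrow(N) != nrow(E))
    stop_input("node count (%d) and edge matrix size (%d) disagree",
               nrow(N), nrow(E))
  list(N = N, E = E)
}

#' Edge-to-node layer
#'
#' Each node aggregates itself and its neighbours, weighted by the edges
#' (self-loop included): `N'_i = sum_j E[i, j] * N_j`. Linear in `N`.
#'
#' @param nodes `R x D` matrix of node vectors (or [roi_signal_set()]).
#' @param edges `R x R` edge-value matrix.
#' @return `R x D` matrix of updated node vectors.
#' @export
edge_to_node <- function(nodes, edges) {
  if (is_roi_signal_set(nodes)) nodes <- nodes$vectors
  s <- check_graph_shapes(nodes, edges)
  s$E %*% s$N
}

#' Node-to-edge layer
#'
#' Each edge collects its two incident (updated) nodes and every edge
#' incident to either endpoint, fused by learnable weights:
#' `E'[i,j] = w_i . N'_i + w_j . N'_j + sum_k w[i,k] E[i,k] + sum_k w[j,k] E[j,k]`.
#' All sums run over the full index range, self terms included. Linear in
#' `(N', E)` for fixed parameters.
#'
#' @param nodes_updated `R x D` matrix of updated node vectors.
#' @param edges `R x R` edge matrix (pre-update values).
#' @param block one block of [nei_gnn_params()] (fields `node_weights`,
#'   `edge_weights`).
#' @return `R x R` updated edge matrix.
#' @export
node_to_edge <- function(nodes_updated, edges, block) {
  s <- check_graph_shapes(nodes_updated, edges)
  R <- nrow(s$N)
  if (!all(dim(block$node_weights) == dim(s$N)) ||
      !all(dim(block$edge_weights) == c(R, R)))
    stop_input("parameter shapes disagree with (R, D)")
  a <- rowSums(block$node_weights * s$N)          # a_r = w_r . N'_r
  b <- rowSums(block$edge_weights * s$E)          # b_r = sum_k w[r,k] E[r,k]
  outer(a, rep(1, R)) + outer(rep(1, R), a) +
    outer(b, rep(1, R)) + outer(rep(1, R), b)
}

#' One NEI-GNN block: edge-to-node, then node-to-edge
#'
#' Applies [edge_to_node()] followed by [node_to_edge()] (which sees the
#' updated nodes and the block's input edges), returning both updates. No
#' nonlinearity is applied inside the block. An optional L2 renormalization
#' of each updated node vector back to its input norm is available to
#' control magnitude growth in deep stacks; it is off by default and is an
#' extension, not part of the core block definition.
#'
#' @inheritParams node_to_edge
#' @param nodes `R x D` node matrix.
#' @param renormalize if `TRUE`, rescale each updated node vector to its
#'   input L2 norm (epsilon-guarded).
#' @return list with `nodes` (`R x D`) and `edges` (`R x R`).
#' @export
nei_block_forward <- function(nodes, edges, block, renormalize = FALSE) {
  if (is_roi_signal_set(nodes)) nodes <- nodes$vectors
  n1 <- edge_to_node(nodes, edges)
  if (renormalize) {
    tgt <- sqrt(rowSums(nodes^2))
    cur <- sqrt(rowSums(n1^2))
    n1 <- n1 * (tgt / (cur + .EPS))
  }
  list(nodes = n1, edges = node_to_edge(n1, edges, block))
}

#' Run the full NEI-GNN stack
#'
#' Initializes edges from [compute_connectivity()] on the input nodes, then
#' applies the `K` blocks sequentially, each with its own parameter slice;
#' block `k > 1` receives block `k - 1`'s updated edges and nodes. With
#' `K = 0` the input nodes are returned unchanged.
#'
#' @param nodes0 `R x D` node matrix or [roi_signal_set()].
#' @param params a [nei_gnn_params()].
#' @param renormalize passed to [nei_block_forward()].
#' @return `R x D` matrix of final node vectors.
#' @export
stack_forward <- function(nodes0, params, renormalize = FALSE) {
  stack_forward_cached(nodes0, params, renormalize)$nodes
}

# Forward pass retaining per-block inputs for backpropagation.
stack_forward_cached <- function(nodes0, params, renormalize = FALSE) {
  if (is_roi_signal_set(nodes0)) nodes0 <- nodes0$vectors
  if (!inherits(params, "nei_gnn_params"))
    stop_input("params must be a nei_gnn_params object")
  if (attr(params, "R") != nrow(nodes0) || attr(params, "D") != ncol(nodes0))
    stop_input("nei_gnn_params built for (R=%d, D=%d), got (R=%d, D=%d)",
               attr(params, "R"), attr(params, "D"),
               nrow(nodes0), ncol(nodes0))
  if (renormalize && length(params) > 0)
    stop_input("backward pass does not support renormalize; use stack_forward")
  N <- nodes0
  E <- compute_connectivity(nodes0)
  cache <- vector("list", length(params))
  for (k in seq_along(params)) {
    cache[[k]] <- list(N = N, E = E)
    out <- nei_block_forward(N, E, params[[k]])
    N <- out$nodes
    cache[[k]]$N1 <- N
    E <- out$edges
  }
  list(nodes = N, edges = E, cache = cache)
}

# Backpropagate a gradient w.r.t. the stack's output nodes (and optionally
# output edges) down to every block's parameters. The input nodes are data
# (or a frozen encoder's output), so their gradient is not materialized
# beyond the first block.
stack_backward <- function(fwd, params, g_nodes, g_edges = NULL) {
  K <- length(params)
  R <- attr(params, "R")
  gN <- g_nodes
  gE <- if (is.null(g_edges)) matrix(0, R, R) else g_edges
  grads <- vector("list", K)
  for (k in rev(seq_len(K))) {
    ck <- fwd$cache[[k]]
    blk <- params[[k]]
    # node_to_edge backward: s_r = rowsum_r(gE') + colsum_r(gE')
    s <- rowSums(gE) + colSums(gE)
    g_nw <- s * ck$N1                         # d/d w_r   = s_r * N'_r
    g_ew <- s * ck$E                          # d/d w[r,k] = s_r * E[r,k]
    gN1 <- gN + s * blk$node_weights          # into updated nodes
    gE_in <- s * blk$edge_weights             # into this block's input edges
    # edge_to_node backward: N' = E N
    gE_in <- gE_in + gN1 %*% t(ck$N)
    gN <- t(ck$E) %*% gN1
    gE <- gE_in
    grads[[k]] <- list(node_weights = g_nw, edge_weights = g_ew)
  }
  structure(grads, class = "nei_gnn_params",
            R = R, D = attr(params, "D"), K = K)
}
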