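test_that("connectivity is the epsilon-guarded cosine matrix", {
  s <- align_rois(list(c(1, 2, 3), c(1, 2, 3)))
  C <- compute_connectivity(s)
  expect_equal(C[1, 2], 1, tolerance = 1e-6)
  expect_equal(diag(C), c(1, 1), tolerance = 1e-6)

  C <- compute_connectivity(rbind(c(1, 0), c(0, 1)))
  expect_equal(C[1, 2], 0)

  set.seed(1)
  for (trial in 1:30) {
    N <- matrix(rnorm(7 * 10), 7, 10)
    expect_lt(max(abs(compute_connectivity(N) - ref_cosine_matrix(N))), 1e-10)
  }
  # zero vectors give ~0 rows, not errors
  N <- matrix(rnorm(3 * 4), 3, 4); N[2, ] <- 0
  expect_lt(max(abs(compute_connectivity(N)[2, ])), 1e-6)
})

test_that("connectivity is permutation-equivariant", {
  set.seed(2)
  N <- matrix(rnorm(6 * 9), 6, 9)
  p <- sample(6)
  expect_equal(compute_connectivity(N[p, ]), compute_connectivity(N)[p, p])
})

test_that("edge_to_node aggregates with self-loops and is linear", {
  N <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(edge_to_node(N, diag(4)), N)

  N2 <- rbind(c(1, 0), c(0, 1))
  E <- matrix(1, 2, 2)
  expect_equal(edge_to_node(N2, E), rbind(c(1, 1), c(1, 1)))

  set.seed(3)
  for (trial in 1:30) {
    N <- matrix(rnorm(7 * 8), 7, 8); E <- matrix(rnorm(49), 7, 7)
    expect_lt(max(abs(edge_to_node(N, E) - ref_edge_to_node(N, E))), 1e-10)
  }
  # linearity in N
  M <- matrix(rnorm(7 * 8), 7, 8); E <- matrix(rnorm(49), 7, 7)
  N <- matrix(rnorm(7 * 8), 7, 8)
  expect_equal(edge_to_node(2 * N + 3 * M, E),
               2 * edge_to_node(N, E) + 3 * edge_to_node(M, E),
               tolerance = 1e-8)
  expect_error(edge_to_node(N, matrix(0, 3, 3)), "disagree")
})

test_that("node_to_edge fuses node projections and incident edges", {
  R <- 4; D <- 5
  blk0 <- list(node_weights = matrix(0, R, D), edge_weights = matrix(0, R, R))
  N <- matrix(rnorm(R * D), R, D); E <- matrix(rnorm(R * R), R, R)
  expect_true(all(node_to_edge(N, E, blk0) == 0))

  blk1 <- list(node_weights = matrix(0, R, D), edge_weights = matrix(1, R, R))
  out <- node_to_edge(N, E, blk1)
  rs <- rowSums(E)
  expect_equal(out, outer(rs, rep(1, R)) + outer(rep(1, R), rs))

  set.seed(4)
  for (trial in 1:30) {
    R <- 7; D <- 6
    N1 <- matrix(rnorm(R * D), R, D); E <- matrix(rnorm(R * R), R, R)
    blk <- list(node_weights = matrix(rnorm(R * D), R, D),
                edge_weights = matrix(rnorm(R * R), R, R))
    expect_lt(max(abs(node_to_edge(N1, E, blk) -
                        ref_node_to_edge(N1, E, blk$node_weights,
                                         blk$edge_weights))), 1e-10)
  }
})

test_that("a block is edge-to-node followed by node-to-edge", {
  set.seed(5)
  R <- 5; D <- 6
  N <- matrix(rnorm(R * D), R, D); E <- matrix(rnorm(R * R), R, R)
  blk <- nei_gnn_params(R, D, 1, seed = 9)[[1]]
  out <- nei_block_forward(N, E, blk)
  n1 <- edge_to_node(N, E)
  expect_equal(out$nodes, n1)
  expect_equal(out$edges, node_to_edge(n1, E, blk))

  zero <- list(node_weights = matrix(0, R, D), edge_weights = matrix(0, R, R))
  out <- nei_block_forward(N, diag(R), zero)
  expect_equal(out$nodes, N)
  expect_true(all(out$edges == 0))
})

test_that("stacking applies blocks sequentially from cosine edges", {
  s <- random_roi_set(5, c(4, 7, 3, 6, 5), seed = 6)
  p0 <- nei_gnn_params(5, 7, 0)
  expect_equal(stack_forward(s, p0), s$vectors)

  p3 <- nei_gnn_params(5, 7, 3, seed = 7)
  # unrolled oracle
  N <- s$vectors; E <- compute_connectivity(s)
  for (k in 1:3) {
    out <- nei_block_forward(N, E, p3[[k]])
    N <- out$nodes; E <- out$edges
  }
  expect_equal(stack_forward(s, p3), N, tolerance = 1e-12)

  p1 <- nei_gnn_params(5, 7, 1, seed = 8)
  p2 <- nei_gnn_params(5, 7, 2, seed = 8)
  expect_false(isTRUE(all.equal(stack_forward(s, p1), stack_forward(s, p2))))
  expect_error(stack_forward(matrix(0, 3, 3), p3), "built for")
})

test_that("stack gradients match finite differences", {
  set.seed(9)
  R <- 4; D <- 5; K <- 2
  N0 <- matrix(rnorm(R * D), R, D)
  params <- nei_gnn_params(R, D, K, seed = 10)
  G <- matrix(rnorm(R * D), R, D)
  fwd <- neirecon:::stack_forward_cached(N0, params)
  gr <- neirecon:::stack_backward(fwd, params, G)
  L <- function(p) sum(stack_forward(N0, p) * G)
  eps <- 1e-6
  for (k in 1:K) for (fld in c("node_weights", "edge_weights")) {
    for (trial in 1:3) {
      i <- sample(length(params[[k]][[fld]]), 1)
      pp <- params; pp[[k]][[fld]][i] <- pp[[k]][[fld]][i] + eps
      pm <- params; pm[[k]][[fld]][i] <- pm[[k]][[fld]][i] - eps
      num <- (L(pp) - L(pm)) / (2 * eps)
      expect_equal(gr[[k]][[fld]][i], num, tolerance = 1e-4)
    }
  }
})
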