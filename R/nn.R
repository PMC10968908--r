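# Minimal neural-network layer library with analytic backward passes.
#
# Feature maps are (H*W) x C matrices, pixels column-major in (row, col)
# order (pixel (i, j) at matrix row i + (j-1)*H). Convolutions are
# "same"-padded; the heavy lifting (patch extraction / scatter-add) is done
# by the compiled im2col/col2im kernels, the contraction itself by BLAS.

conv_init <- function(k, c_in, c_out, mode = c("kaiming", "xavier")) {
  mode <- match.arg(mode)
  fan_in <- k * k * c_in
  bound <- if (mode == "kaiming") sqrt(6 / fan_in)
           else sqrt(6 / (fan_in + c_out))
  list(W = matrix(runif(fan_in * c_out, -bound, bound), fan_in, c_out),
       b = numeric(c_out))
}

linear_init <- function(n_in, n_out) {
  bound <- sqrt(6 / (n_in + n_out))   # Xavier-uniform
  list(W = matrix(runif(n_in * n_out, -bound, bound), n_out, n_in),
       b = numeric(n_out))
}

conv2d_fwd <- function(x, p, H, W, k) {
  col <- im2col_cpp(x, H, W, k)
  out <- col %*% p$W
  out <- sweep(out, 2, p$b, `+`)
  list(out = out, cache = list(x = x, H = H, W = W, k = k))
}

conv2d_bwd <- function(gout, p, cache) {
  col <- im2col_cpp(cache$x, cache$H, cache$W, cache$k)
  list(gx = col2im_cpp(gout %*% t(p$W), cache$H, cache$W, cache$k),
       gW = crossprod(col, gout), gb = colSums(gout))
}

linear_fwd <- function(x, p) as.vector(p$W %*% x + p$b)

linear_bwd <- function(gout, p, x)
  list(gx = as.vector(crossprod(p$W, gout)),
       gW = outer(gout, x), gb = gout)

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(gout, cache) gout * cache

swish_fwd <- function(x) {
  s <- plogis(x)
  list(out = x * s, cache = list(x = x, s = s))
}
swish_bwd <- function(gout, cache)
  gout * (cache$s + cache$x * cache$s * (1 - cache$s))

sigmoid_fwd <- function(x) {
  s <- plogis(x)
  list(out = s, cache = s)
}
sigmoid_bwd <- function(gout, cache) gout * cache * (1 - cache)

# ---- spatial index maps (cached per size) --------------------------------

.idx_cache <- new.env(parent = emptyenv())

upsample_idx <- function(H, W) {
  key <- sprintf("up_%d_%d", H, W)
  if (is.null(.idx_cache[[key]])) {
    H2 <- 2L * H; W2 <- 2L * W
    i2 <- rep(seq_len(H2), times = W2)
    j2 <- rep(seq_len(W2), each = H2)
    .idx_cache[[key]] <- ceiling(i2 / 2) + (ceiling(j2 / 2) - 1L) * H
  }
  .idx_cache[[key]]
}

# Nearest-neighbour x2 upsampling; backward sums each 2x2 child group.
upsample2_fwd <- function(x, H, W) x[upsample_idx(H, W), , drop = FALSE]

upsample2_bwd <- function(gout, H, W) {
  idx <- upsample_idx(H, W)
  gx <- matrix(0, H * W, ncol(gout))
  for (c in seq_len(ncol(gout)))
    gx[, c] <- rowsum(gout[, c], idx)
  gx
}

avgpool2_idx <- function(H, W) {
  key <- sprintf("pool_%d_%d", H, W)
  if (is.null(.idx_cache[[key]])) {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    i <- rep(seq_len(H), times = W)
    j <- rep(seq_len(W), each = H)
    .idx_cache[[key]] <- pmin((i + 1L) %/% 2L, H2) +
      (pmin((j + 1L) %/% 2L, W2) - 1L) * H2
  }
  .idx_cache[[key]]
}

avgpool2_fwd <- function(x, H, W) {
  idx <- avgpool2_idx(H, W)
  out <- matrix(0, (H %/% 2L) * (W %/% 2L), ncol(x))
  for (c in seq_len(ncol(x))) out[, c] <- rowsum(x[, c], idx) / 4
  out
}

avgpool2_bwd <- function(gout, H, W) gout[avgpool2_idx(H, W), , drop = FALSE] / 4

# ---- group normalization --------------------------------------------------

groupnorm_init <- function(C) list(gamma = rep(1, C), beta = numeric(C))

# Normalizes over (space x channels-within-group) per sample; groups must
# divide the channel count (asserted at network construction).
groupnorm_fwd <- function(x, p, groups, eps = 1e-5) {
  C <- ncol(x)
  gsize <- C %/% groups
  xhat <- x
  stats <- vector("list", groups)
  for (g in seq_len(groups)) {
    cols <- ((g - 1) * gsize + 1):(g * gsize)
    v <- x[, cols, drop = FALSE]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    inv <- 1 / sqrt(va + eps)
    xhat[, cols] <- (v - mu) * inv
    stats[[g]] <- list(cols = cols, inv = inv)
  }
  out <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(out = out, cache = list(xhat = xhat, stats = stats))
}

groupnorm_bwd <- function(gout, p, cache) {
  xhat <- cache$xhat
  ggamma <- colSums(gout * xhat)
  gbeta <- colSums(gout)
  gxhat <- sweep(gout, 2, p$gamma, `*`)
  gx <- gxhat
  for (st in cache$stats) {
    cols <- st$cols
    gh <- gxhat[, cols, drop = FALSE]
    xh <- xhat[, cols, drop = FALSE]
    m <- length(gh)
    gx[, cols] <- st$inv * (gh - mean(gh) - xh * mean(gh * xh))
  }
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# ---- Adam optimizer over nested parameter lists ---------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

tree_zero <- function(a) if (is.list(a)) {
  out <- lapply(a, tree_zero); attributes(out) <- attributes(a); out
} else a * 0

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = tree_zero(params), v = tree_zero(params))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g,
                     opt$m, grads)
  opt$v <- tree_map2(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2,
                     opt$v, grads)
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  step <- tree_map2(function(m, v)
    opt$lr * (m / c1) / (sqrt(v / c2) + opt$eps), opt$m, opt$v)
  params <- tree_map2(`-`, params, step)
  list(opt = opt, params = params)
}

# stable fingerprint of a parameter tree, used for freeze contracts
params_checksum <- function(params) {
  flat <- unlist(params, use.names = FALSE)
  c(n = length(flat), sum = sum(flat), sumsq = sum(flat^2),
    dot = sum(flat * seq_along(flat)))
}
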