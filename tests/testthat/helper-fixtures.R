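# Shared fixtures and independent (loop-based) reference implementations.
# References are deliberately written index-by-index so they stay
# independent of the vectorized package code they check.

random_roi_set <- function(R = 4, lens = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lens)) lens <- sample(3:8, R, replace = TRUE)
  align_rois(lapply(lens, rnorm))
}

random_image <- function(size = 112, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(size * size * 3), c(size, size, 3))
}

tiny_study <- function(n_train = 8, n_test = 4, n_repeats = 2,
                       n_unlabeled = 4, snr = 1.0, seed = 1,
                       roi_voxel_counts = c(6, 9, 5, 7)) {
  generate_study(synthetic_spec(
    n_train = n_train, n_test = n_test, n_repeats = n_repeats,
    n_unlabeled = n_unlabeled, roi_voxel_counts = roi_voxel_counts,
    roi_names = paste0("ROI", seq_along(roi_voxel_counts)),
    snr = snr, seed = seed))
}

# ---- brute-force references ----------------------------------------------

ref_cosine_matrix <- function(N, eps = 1e-8) {
  R <- nrow(N)
  C <- matrix(0, R, R)
  for (i in 1:R) for (j in 1:R) {
    num <- sum(N[i, ] * N[j, ])
    C[i, j] <- num / (sqrt(sum(N[i, ]^2)) * sqrt(sum(N[j, ]^2)) + eps)
  }
  C
}

ref_edge_to_node <- function(N, E) {
  R <- nrow(N); D <- ncol(N)
  out <- matrix(0, R, D)
  for (i in 1:R) for (d in 1:D) {
    acc <- 0
    for (j in 1:R) acc <- acc + E[i, j] * N[j, d]
    out[i, d] <- acc
  }
  out
}

ref_node_to_edge <- function(N1, E, nw, ew) {
  R <- nrow(N1)
  out <- matrix(0, R, R)
  for (i in 1:R) for (j in 1:R) {
    acc <- sum(nw[i, ] * N1[i, ]) + sum(nw[j, ] * N1[j, ])
    for (k1 in 1:R) acc <- acc + ew[i, k1] * E[i, k1]
    for (k2 in 1:R) acc <- acc + ew[j, k2] * E[j, k2]
    out[i, j] <- acc
  }
  out
}

ref_tv <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1))
  H <- dim(img)[1]; W <- dim(img)[2]
  total <- 0
  for (c in seq_len(dim(img)[3]))
    for (i in 1:(H - 1)) for (j in 1:(W - 1))
      total <- total + (img[i, j + 1, c] - img[i, j, c])^2 +
        (img[i + 1, j, c] - img[i, j, c])^2
  total
}

# valid-window Gaussian-weighted SSIM, computed pixel-by-pixel
ref_ssim <- function(x, y) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  if (is.matrix(y)) y <- array(y, c(dim(y), 1))
  w1 <- exp(-((-5:5)^2) / (2 * 1.5^2)); w1 <- w1 / sum(w1)
  w <- outer(w1, w1)
  C1 <- 0.01^2; C2 <- 0.03^2
  H <- dim(x)[1]; W <- dim(x)[2]
  per_channel <- numeric(dim(x)[3])
  for (c in seq_len(dim(x)[3])) {
    vals <- c()
    for (i in 6:(H - 5)) for (j in 6:(W - 5)) {
      px <- x[(i - 5):(i + 5), (j - 5):(j + 5), c]
      py <- y[(i - 5):(i + 5), (j - 5):(j + 5), c]
      mx <- sum(w * px); my <- sum(w * py)
      vx <- sum(w * px^2) - mx^2; vy <- sum(w * py^2) - my^2
      cxy <- sum(w * px * py) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
    per_channel[c] <- mean(vals)
  }
  mean(per_channel)
}

# separable cubic resampling computed per output pixel (Catmull-Rom,
# align-corners=false, widened kernel + renormalization when downsampling)
ref_resize_cubic <- function(img, out) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1))
  n_in <- dim(img)[1]
  s <- n_in / out
  support <- max(s, 1)
  kern <- function(x) {
    a <- -0.5; x <- abs(x)
    if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
    else if (x < 2) a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a
    else 0
  }
  axis_w <- function(u) {
    x <- (u - 0.5) * s - 0.5
    ks <- (floor(x - 2 * support) + 1):(ceiling(x + 2 * support) - 1)
    w <- vapply((x - ks) / support, kern, numeric(1))
    ks <- pmin(pmax(ks, 0), n_in - 1) + 1
    list(ks = ks, w = w / sum(w))
  }
  res <- array(0, c(out, out, dim(img)[3]))
  for (u in 1:out) for (v in 1:out) {
    wu <- axis_w(u); wv <- axis_w(v)
    for (c in seq_len(dim(img)[3])) {
      acc <- 0
      for (ii in seq_along(wu$ks)) for (jj in seq_along(wv$ks))
        acc <- acc + wu$w[ii] * wv$w[jj] * img[wu$ks[ii], wv$ks[jj], c]
      res[u, v, c] <- acc
    }
  }
  res
}
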