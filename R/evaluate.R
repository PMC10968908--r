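#' Structural similarity index (SSIM)
#'
#' Windowed SSIM with the standard settings: 11 x 11 Gaussian window with
#' sigma 1.5, stability constants K1 = 0.01, K2 = 0.03 at data range 1.0,
#' averaged over the valid window positions and over the RGB channels.
#' Inputs must be at least 11 pixels on each side.
#'
#' @param x,y images of identical shape (`H x W x C` arrays or `H x W`
#'   matrices) with values in \[0, 1\].
#' @return scalar SSIM in \[-1, 1\].
#' @export
ssim <- function(x, y) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (is.matrix(y)) y <- array(y, c(dim(y), 1L))
  if (!all(dim(x) == dim(y))) stop_input("image shapes disagree")
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H < 11 || W < 11) stop_input("images must be at least 11 x 11 for SSIM")
  C1 <- 0.01^2; C2 <- 0.03^2
  Ah <- gaussian_valid_operator(H)
  Aw <- gaussian_valid_operator(W)
  win <- function(m) Ah %*% m %*% t(Aw)
  vals <- vapply(seq_len(dim(x)[3]), function(c) {
    mx <- win(x[, , c]); my <- win(y[, , c])
    vx <- win(x[, , c]^2) - mx^2
    vy <- win(y[, , c]^2) - my^2
    cxy <- win(x[, , c] * y[, , c]) - mx * my
    mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
           ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }, numeric(1))
  mean(vals)
}

# (n-10) x n valid-mode Gaussian smoothing operator, 11 taps, sigma 1.5
gaussian_valid_operator <- function(n) {
  key <- sprintf("gauss_%d", n)
  if (is.null(.idx_cache[[key]])) {
    w <- exp(-((-5:5)^2) / (2 * 1.5^2))
    w <- w / sum(w)
    A <- matrix(0, n - 10, n)
    for (i in seq_len(n - 10)) A[i, i:(i + 10)] <- w
    .idx_cache[[key]] <- A
  }
  .idx_cache[[key]]
}

#' Image-pair similarity for the identification protocol
#'
#' @param a,b images of identical shape in \[0, 1\].
#' @param similarity `"mse"` (lower is more similar) or `"ssim"` (higher
#'   is more similar).
#' @return scalar similarity value.
#' @export
image_similarity <- function(a, b, similarity = c("mse", "ssim")) {
  similarity <- match.arg(similarity)
  if (!all(dim(a) == dim(b))) stop_input("image shapes disagree")
  if (similarity == "mse") mean((a - b)^2) else ssim(a, b)
}

#' n-way identification configuration
#'
#' @param n candidate-set size (>= 2; 2, 5 and 10 are conventional).
#' @param repetitions number of independent distractor redraws averaged
#'   into the final accuracy (10 by convention).
#' @param similarity `"mse"` or `"ssim"`.
#' @param seed seed for distractor sampling.
#' @export
n_way_config <- function(n = 2, repetitions = 10,
                         similarity = c("mse", "ssim"), seed = 1) {
  similarity <- match.arg(similarity)
  if (n < 2) stop_input("n must be >= 2")
  if (repetitions < 1) stop_input("repetitions must be >= 1")
  structure(list(n = as.integer(n), repetitions = as.integer(repetitions),
                 similarity = similarity, seed = as.integer(seed)),
            class = "n_way_config")
}

#' Single n-way identification trial
#'
#' The reconstruction passes the trial iff its similarity to the true
#' target is at least as optimal as its similarity to every distractor
#' (strictly: <= all for MSE, >= all for SSIM; exact ties pass).
#'
#' @param recon the reconstruction.
#' @param target_gt the true stimulus.
#' @param distractors list of n - 1 other candidate stimuli.
#' @param similarity `"mse"` or `"ssim"`.
#' @return logical pass/fail.
#' @export
n_way_trial <- function(recon, target_gt, distractors,
                        similarity = c("mse", "ssim")) {
  similarity <- match.arg(similarity)
  if (length(distractors) < 1) stop_input("need at least one distractor")
  s_t <- image_similarity(recon, target_gt, similarity)
  s_d <- vapply(distractors, function(d)
    image_similarity(recon, d, similarity), numeric(1))
  if (similarity == "mse") all(s_t <= s_d) else all(s_t >= s_d)
}

#' n-way identification accuracy
#'
#' For each repetition and each target, n - 1 distractors are drawn
#' uniformly without replacement from the other ground-truth stimuli
#' (seeded, fresh per repetition) and an [n_way_trial()] is run; the
#' accuracy is the mean pass rate over targets, averaged over repetitions,
#' in percent. Since every trial compares the same reconstruction/
#' ground-truth pairs, the pairwise similarity matrix is precomputed once.
#'
#' @param recons,gts aligned lists of reconstructions and ground truths
#'   (`length >= cfg$n`).
#' @param cfg an [n_way_config()].
#' @param detail if `TRUE`, also return each target's mean pass rate over
#'   the repetitions (useful for uncertainty estimates: trials of the same
#'   target are dependent, so standard errors should be computed across
#'   targets).
#' @return accuracy in percent, or `list(accuracy, per_target)` when
#'   `detail = TRUE`.
#' @export
n_way_accuracy <- function(recons, gts, cfg = n_way_config(),
                           detail = FALSE) {
  if (length(recons) != length(gts)) stop_input("recons/gts lengths differ")
  m <- length(gts)
  if (m < cfg$n) stop_input("need at least n = %d stimuli, got %d", cfg$n, m)
  S <- similarity_matrix(recons, gts, cfg$similarity)
  better <- if (cfg$similarity == "mse") `<=` else `>=`
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  pass <- matrix(NA, cfg$repetitions, m)
  for (rep in seq_len(cfg$repetitions)) {
    pass[rep, ] <- vapply(seq_len(m), function(i) {
      pool <- setdiff(seq_len(m), i)
      d <- if (length(pool) == cfg$n - 1) pool
           else sample(pool, cfg$n - 1)
      all(better(S[i, i], S[i, d]))
    }, logical(1))
  }
  acc <- 100 * mean(pass)
  if (!detail) return(acc)
  list(accuracy = acc, per_target = 100 * colMeans(pass))
}

similarity_matrix <- function(recons, gts, similarity) {
  m <- length(gts)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    S[i, j] <- image_similarity(recons[[i]], gts[[j]], similarity)
  S
}

#' Image-level reconstruction metrics
#'
#' Mean raw MSE, mean raw SSIM and (when an embedder is supplied) the mean
#' cosine distance between embeddings, each averaged over aligned
#' reconstruction/ground-truth pairs. The embedder is a pluggable contract
#' `function(image) -> numeric vector`; it is omitted from the result when
#' absent.
#'
#' @param recons,gts aligned image lists.
#' @param embedder optional embedding function.
#' @return named list: `raw_mse`, `raw_ssim`, and optionally
#'   `embed_distance`.
#' @export
image_metrics <- function(recons, gts, embedder = NULL) {
  if (length(recons) != length(gts)) stop_input("recons/gts lengths differ")
  mse <- mean(mapply(function(a, b) mean((a - b)^2), recons, gts))
  ss <- mean(mapply(ssim, recons, gts))
  out <- list(raw_mse = mse, raw_ssim = ss)
  if (!is.null(embedder)) {
    d <- mapply(function(a, b) {
      u <- embedder(a); v <- embedder(b)
      1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)) + .EPS)
    }, recons, gts)
    out$embed_distance <- mean(d)
  }
  out
}

#' Default test-profile embedder
#'
#' Flattens the deepest feature map of the tiny backbone into an embedding
#' vector, so the embedding-distance metric runs fully offline. A stronger
#' pretrained embedder can be plugged in via the same contract.
#'
#' @param backbone a [tiny_backbone()].
#' @return `function(image) -> numeric vector`.
#' @export
backbone_embedder <- function(backbone = tiny_backbone()) {
  function(image) as.vector(backbone_forward(backbone, image)$features[[4]])
}

#' Evaluate reconstructions with the full metric suite
#'
#' Runs [n_way_accuracy()] for every requested candidate-set size and
#' similarity backend plus [image_metrics()].
#'
#' @param recons,gts aligned image lists.
#' @param n_values candidate-set sizes.
#' @param similarities similarity backends to evaluate.
#' @param repetitions,seed passed to [n_way_config()].
#' @param embedder optional embedding function for [image_metrics()].
#' @return nested list: `$<similarity>$<n>` accuracies (percent),
#'   `raw_mse`, `raw_ssim`, optionally `embed_distance`.
#' @export
evaluate_reconstructions <- function(recons, gts, n_values = c(2, 5, 10),
                                     similarities = c("mse", "ssim"),
                                     repetitions = 10, seed = 1,
                                     embedder = NULL) {
  out <- list()
  for (sim in similarities) {
    out[[sim]] <- list()
    for (n in n_values) {
      cfg <- n_way_config(n = n, repetitions = repetitions,
                          similarity = sim, seed = seed)
      out[[sim]][[as.character(n)]] <- n_way_accuracy(recons, gts, cfg)
    }
  }
  c(out, image_metrics(recons, gts, embedder))
}
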