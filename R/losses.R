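#' Loss configuration
#'
#' Bundles everything the training objectives need: the perceptual-loss
#' feature extractor (the frozen tiny backbone in the test profile), which
#' of its layers to use, per-term weights, and the set of image scales on
#' which the reconstruction losses are applied (the multi-scale-constraint
#' ablation knob). The perceptual term is always applied at the 112 scale
#' only; the MAE and total-variation terms apply to every constrained
#' scale.
#'
#' @param perceptual_backbone a [tiny_backbone()]-style feature extractor.
#' @param perceptual_layers indices of its feature maps to use.
#' @param term_weights named non-negative weights: `mse`, `cossim` (encoder
#'   terms), `mae`, `per`, `tv` (decoder terms). All default to 1 except
#'   `tv`: the total-variation term is a raw sum over pixel pairs, so at
#'   the 112 scale it is roughly four orders of magnitude larger per unit
#'   contrast than the spatially averaged MAE term. Its default weight of
#'   0.002 calibrates the two so that a faithful reconstruction of a
#'   smooth stimulus attains a lower objective than the degenerate flat
#'   image (which has zero total variation); with weight 1 the flat image
#'   is the global optimum and training collapses.
#' @param scales_constrained non-empty subset of `c(14, 28, 56, 112)`.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(perceptual_backbone = tiny_backbone(),
                        perceptual_layers = 1:4,
                        term_weights = c(mse = 1, cossim = 1, mae = 1,
                                         per = 1, tv = 0.002),
                        scales_constrained = c(14, 28, 56, 112)) {
  defaults <- c(mse = 1, cossim = 1, mae = 1, per = 1, tv = 0.002)
  defaults[names(term_weights)] <- term_weights
  if (any(defaults < 0)) stop_input("term weights must be >= 0")
  if (length(scales_constrained) == 0)
    stop_input("scales_constrained must be non-empty")
  if (!all(scales_constrained %in% c(14, 28, 56, 112)))
    stop_input("scales_constrained must be a subset of {14, 28, 56, 112}")
  structure(list(perceptual_backbone = perceptual_backbone,
                 perceptual_layers = perceptual_layers,
                 term_weights = defaults,
                 scales_constrained = sort(unique(scales_constrained))),
            class = "loss_config")
}

signal_vec <- function(x) if (is_roi_signal_set(x)) flatten_nodes(x) else as.numeric(x)

#' fMRI mean-squared-error loss
#'
#' `(1/N) * sum((Fe - Fr)^2)` over all `N` elements of the flat fMRI
#' vectors; padded entries are 0 in both and contribute nothing.
#'
#' @param fe,fr estimated and reference signals ([roi_signal_set()] or
#'   numeric vectors of equal length).
#' @param grad also return the gradient w.r.t. `fe`.
#' @return the loss, or `list(loss, grad)` when `grad = TRUE`.
#' @export
loss_f_mse <- function(fe, fr, grad = FALSE) {
  a <- signal_vec(fe); b <- signal_vec(fr)
  if (length(a) != length(b)) stop_input("fMRI shapes disagree")
  d <- a - b
  l <- mean(d^2)
  if (!grad) return(l)
  list(loss = l, grad = 2 * d / length(d))
}

#' fMRI negative-cosine-similarity loss
#'
#' `-(Fe . Fr) / (||Fe|| * ||Fr|| + eps)` on the flat vectors, epsilon
#' 1e-8. Bounded in \[-1, 1\]; identical non-zero inputs give -1.
#'
#' @inheritParams loss_f_mse
#' @export
loss_f_cossim <- function(fe, fr, grad = FALSE) {
  a <- signal_vec(fe); b <- signal_vec(fr)
  if (length(a) != length(b)) stop_input("fMRI shapes disagree")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  q <- na * nb + .EPS
  s <- sum(a * b)
  l <- -s / q
  if (!grad) return(l)
  ga <- -b / q + s * nb * a / (if (na > 0) na else .EPS) / q^2
  list(loss = l, grad = ga)
}

#' Stage-1 encoder loss
#'
#' Weighted sum of the fMRI MSE and negative-cosine terms (both weights 1
#' by default, i.e. the plain unweighted sum).
#'
#' @inheritParams loss_f_mse
#' @param cfg a [loss_config()] (only `term_weights` is used).
#' @export
encoder_loss <- function(fe, fr, cfg = loss_config(), grad = FALSE) {
  w <- cfg$term_weights
  if (!grad)
    return(w[["mse"]] * loss_f_mse(fe, fr) +
           w[["cossim"]] * loss_f_cossim(fe, fr))
  m <- loss_f_mse(fe, fr, grad = TRUE)
  cs <- loss_f_cossim(fe, fr, grad = TRUE)
  list(loss = w[["mse"]] * m$loss + w[["cossim"]] * cs$loss,
       grad = w[["mse"]] * m$grad + w[["cossim"]] * cs$grad)
}

#' Image mean-absolute-error loss at one scale
#'
#' `(1/(H*W)) * sum |Ie - Ir|` per channel, averaged over the three RGB
#' channels (equivalently the mean absolute difference over all elements).
#'
#' @param ie,ir images at the same scale (`s x s x 3` arrays or `(s^2) x 3`
#'   matrices).
#' @param grad also return the gradient w.r.t. `ie` (same shape as input).
#' @export
loss_i_mae <- function(ie, ir, grad = FALSE) {
  if (!all(dim(ie) == dim(ir))) stop_input("image shapes disagree")
  d <- ie - ir
  l <- mean(abs(d))
  if (!grad) return(l)
  list(loss = l, grad = sign(d) / length(d))
}

#' Total-variation loss of an image
#'
#' `sum_{i<H, j<W} (I(i,j+1) - I(i,j))^2 + (I(i+1,j) - I(i,j))^2`,
#' computed per channel and summed over channels. A raw sum (no spatial
#' normalization), so its magnitude grows with resolution.
#'
#' @param ie image (`s x s x 3` array, matrix, or `(s^2) x 3` matrix with
#'   attribute-free square spatial layout).
#' @param grad also return the gradient w.r.t. `ie`.
#' @export
loss_i_tv <- function(ie, grad = FALSE) {
  x <- if (is.matrix(ie)) array(ie, c(dim(ie), 1L)) else ie
  H <- dim(x)[1]; W <- dim(x)[2]
  l <- 0
  g <- if (grad) array(0, dim(x)) else NULL
  ri <- seq_len(H - 1); cj <- seq_len(W - 1)
  for (c in seq_len(dim(x)[3])) {
    m <- x[, , c]
    dh <- m[ri, cj + 1, drop = FALSE] - m[ri, cj, drop = FALSE]
    dv <- m[ri + 1, cj, drop = FALSE] - m[ri, cj, drop = FALSE]
    l <- l + sum(dh^2) + sum(dv^2)
    if (grad) {
      gm <- matrix(0, H, W)
      gm[ri, cj + 1] <- gm[ri, cj + 1] + 2 * dh
      gm[ri, cj] <- gm[ri, cj] - 2 * dh - 2 * dv
      gm[ri + 1, cj] <- gm[ri + 1, cj] + 2 * dv
      g[, , c] <- gm
    }
  }
  if (!grad) return(l)
  if (is.matrix(ie)) g <- array(g, dim(ie))
  list(loss = l, grad = g)
}

#' Perceptual loss at the native scale
#'
#' Extracts feature maps of both images with the frozen perceptual
#' backbone and averages, per layer, the cosine similarity between the
#' channel vectors at every spatial position; layer means are averaged
#' over the `L` selected layers and negated. Per-layer spatial
#' normalization is used because the layers have different spatial sizes.
#' Identical images give exactly -1.
#'
#' @param ie,ir `112 x 112 x 3` images.
#' @param cfg a [loss_config()].
#' @param grad also return the gradient w.r.t. `ie`.
#' @param ir_features optional precomputed backbone features of `ir`
#'   (training caches these, since reference images are static).
#' @export
loss_i_perceptual <- function(ie, ir, cfg = loss_config(), grad = FALSE,
                              ir_features = NULL) {
  if (!all(dim(ie) == c(112, 112, 3)) ||
      (is.null(ir_features) && !all(dim(ir) == c(112, 112, 3))))
    stop_input("perceptual loss is defined at the 112 x 112 scale only")
  bb <- cfg$perceptual_backbone
  fe <- backbone_forward(bb, ie, with_cache = grad)
  fr <- if (is.null(ir_features)) backbone_forward(bb, ir)
        else list(features = ir_features)
  layers <- cfg$perceptual_layers
  L <- length(layers)
  l <- 0
  gfeats <- if (grad) lapply(fe$features, function(f) f * 0) else NULL
  for (li in layers) {
    u <- fe$features[[li]]; v <- fr$features[[li]]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    q <- nu * nv + .EPS
    s <- rowSums(u * v)
    l <- l - mean(s / q) / L
    if (grad) {
      coef <- -1 / (L * nrow(u))
      # d cos/du = v/q - s*nv*u/(nu*q^2)
      gfeats[[li]] <- coef * (v / q - (s * nv / (pmax(nu, .EPS) * q^2)) * u)
    }
  }
  if (!grad) return(l)
  gmat <- backbone_backward_input(bb, fe$cache, gfeats)
  list(loss = l, grad = mat_to_image(gmat, 112))
}

#' Decoder loss for one branch (supervised or self-supervised)
#'
#' Sum over the constrained scales of the MAE and total-variation terms,
#' plus the perceptual term at the 112 scale only. The supervised and
#' self-supervised branches share this identical composition; during
#' training the two branch losses are added when both batches are present.
#'
#' @param pyramid_e,pyramid_r estimated and reference `image_pyramid`s.
#' @param cfg a [loss_config()].
#' @return the branch loss (a scalar).
#' @export
decoder_loss <- function(pyramid_e, pyramid_r, cfg = loss_config()) {
  w <- cfg$term_weights
  total <- 0
  for (s in cfg$scales_constrained) {
    key <- as.character(s)
    total <- total + w[["mae"]] * loss_i_mae(pyramid_e[[key]], pyramid_r[[key]]) +
      w[["tv"]] * loss_i_tv(pyramid_e[[key]])
  }
  total + w[["per"]] * loss_i_perceptual(pyramid_e[["112"]],
                                         pyramid_r[["112"]], cfg)
}

# Branch loss + gradients on the four head outputs ((s^2) x 3 matrices,
# NULL where a scale is unconstrained and carries no perceptual term).
# `ref_features`: optional cached perceptual features of the 112 target.
decoder_branch_loss_grad <- function(heads, pyramid_r, cfg,
                                     ref_features = NULL) {
  w <- cfg$term_weights
  sizes <- c(14L, 28L, 56L, 112L)
  total <- 0
  gheads <- vector("list", 4)
  for (h in 1:4) {
    s <- sizes[h]
    ie <- array(heads[[h]], c(s, s, 3))
    g <- NULL
    if (s %in% cfg$scales_constrained) {
      ir <- pyramid_r[[as.character(s)]]
      mae <- loss_i_mae(ie, ir, grad = TRUE)
      tv <- loss_i_tv(ie, grad = TRUE)
      total <- total + w[["mae"]] * mae$loss + w[["tv"]] * tv$loss
      g <- w[["mae"]] * mae$grad + w[["tv"]] * tv$grad
    }
    if (s == 112L && w[["per"]] > 0) {
      per <- loss_i_perceptual(ie, pyramid_r[["112"]], cfg, grad = TRUE,
                               ir_features = ref_features)
      total <- total + w[["per"]] * per$loss
      g <- (if (is.null(g)) 0 else g) + w[["per"]] * per$grad
    }
    gheads[[h]] <- if (is.null(g)) NULL else matrix(g, s * s, 3)
  }
  list(loss = total, gheads = gheads)
}
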