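#' Encoder parameters
#'
#' The encoder maps a stimulus image to an estimated fMRI response. Each of
#' the backbone's four feature branches passes through a branch-specific
#' processing layer (one 3x3 spatial convolution with ReLU, then one 1x1
#' channel-mixing convolution); the processed maps are flattened without
#' global pooling, concatenated, and fused by a single linear layer into
#' the flat fMRI vector of length `R * D`. The backbone itself is frozen
#' and not part of these parameters.
#'
#' @param backbone a [tiny_backbone()] (defines branch channel counts).
#' @param R,D target study dimensions (ROIs x padded length).
#' @param reduce_channels channel count of each branch after the 1x1
#'   convolution (length 4).
#' @param seed optional initialization seed.
#' @return object of class `encoder_params`.
#' @export
encoder_params <- function(backbone, R, D, reduce_channels = c(2, 4, 8, 16),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- backbone$channels
  sizes <- backbone$sizes
  branches <- lapply(1:4, function(b)
    list(spatial = conv_init(3, ch[b], ch[b]),
         channel = conv_init(1, ch[b], reduce_channels[b])))
  n_feat <- sum(sizes^2 * reduce_channels)
  structure(list(branches = branches,
                 fuse = linear_init(n_feat, R * D),
                 reduce_channels = reduce_channels,
                 R = as.integer(R), D = as.integer(D),
                 backbone_id = backbone$id),
            class = "encoder_params")
}

# Forward from precomputed backbone features; caches for backprop.
encoder_forward <- function(enc, backbone, features) {
  sizes <- backbone$sizes
  caches <- vector("list", 4)
  flat <- vector("list", 4)
  for (b in 1:4) {
    s <- sizes[b]
    cs <- conv2d_fwd(features[[b]], enc$branches[[b]]$spatial, s, s, 3)
    rs <- relu_fwd(cs$out)
    cc <- conv2d_fwd(rs$out, enc$branches[[b]]$channel, s, s, 1)
    caches[[b]] <- list(cs = cs, rs = rs, cc = cc)
    flat[[b]] <- as.vector(cc$out)
  }
  x <- unlist(flat)
  fe <- linear_fwd(x, enc$fuse)
  list(fe = fe, cache = list(branches = caches, x = x))
}

# Branch-parameter gradients given the gradient on the flat output vector.
# The fusion layer's weight gradient is rank-1 per sample, so training
# accumulates it across a batch with a single gemm (see train_encoder);
# here only its input gradient is propagated into the branches.
encoder_backward_branches <- function(enc, backbone, gfe, cache) {
  gx <- as.vector(crossprod(enc$fuse$W, gfe))
  sizes <- backbone$sizes
  offs <- 0L
  gb <- vector("list", 4)
  for (b in 1:4) {
    s <- sizes[b]
    n <- s * s * enc$reduce_channels[b]
    gflat <- matrix(gx[(offs + 1):(offs + n)], s * s,
                    enc$reduce_channels[b])
    offs <- offs + n
    ck <- cache$branches[[b]]
    bw_cc <- conv2d_bwd(gflat, enc$branches[[b]]$channel, ck$cc$cache)
    grelu <- relu_bwd(bw_cc$gx, ck$rs$cache)
    bw_cs <- conv2d_bwd(grelu, enc$branches[[b]]$spatial, ck$cs$cache)
    gb[[b]] <- list(spatial = list(W = bw_cs$gW, b = bw_cs$gb),
                    channel = list(W = bw_cc$gW, b = bw_cc$gb))
  }
  gb
}

# Full parameter gradients for a single sample (used by tests; training
# uses encoder_backward_branches + a batched fusion gemm).
encoder_backward <- function(enc, backbone, gfe, cache) {
  list(branches = encoder_backward_branches(enc, backbone, gfe, cache),
       fuse = list(W = outer(gfe, cache$x), b = gfe))
}

#' Estimate the fMRI response of a stimulus image
#'
#' Runs the frozen backbone and the encoder head, returning the estimated
#' response as an [roi_signal_set()] with the study's ROI layout. Positions
#' that are padding in the target layout are forced to exactly 0 (masked
#' write), so the estimate obeys the same alignment invariants as real
#' recordings. Deterministic: identical images give identical outputs.
#'
#' @param image `112 x 112 x 3` array in \[0, 1\].
#' @param backbone a [tiny_backbone()].
#' @param enc an [encoder_params()].
#' @param roi_names,voxel_counts target study ROI layout.
#' @return an [roi_signal_set()] estimate of the response.
#' @export
encode_image <- function(image, backbone, enc, roi_names, voxel_counts) {
  if (min(image) < 0 || max(image) > 1)
    stop_input("image values must lie in [0, 1]")
  feats <- backbone_forward(backbone, image)$features
  if (length(feats) != 4L)
    stop_input("backbone output arity must be 4")
  fe <- encoder_forward(enc, backbone, feats)$fe
  fe_to_signal_set(fe, roi_names, voxel_counts)
}

# flat R*D vector -> masked roi_signal_set
fe_to_signal_set <- function(fe, roi_names, voxel_counts) {
  voxel_counts <- as.integer(voxel_counts)
  R <- length(voxel_counts)
  D <- max(voxel_counts)
  stopifnot(length(fe) == R * D)
  vec <- unflatten_nodes(fe, R, D)
  msk <- matrix(0, R, D)
  for (r in seq_len(R)) msk[r, seq_len(voxel_counts[r])] <- 1
  vec[msk == 0] <- 0
  roi_signal_set(vec, msk, voxel_counts, roi_names)
}
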