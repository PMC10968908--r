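# Feature backbones: a callable contract mapping a 112 x 112 RGB image to
# exactly 4 feature maps of decreasing spatial resolution (112, 56, 28, 14)
# and increasing channel count. Backbone weights are always frozen.

#' Create the built-in tiny convolutional backbone
#'
#' A small fixed-seed random convolutional feature extractor honouring the
#' four-branch backbone contract (feature maps at 112/56/28/14 pixels with
#' 8/16/24/32 channels, ReLU activations, average-pooling between stages).
#' Its weights are drawn once from the seed and never trained, mirroring
#' the role of a frozen pretrained feature hierarchy while keeping the
#' package fully self-contained and deterministic. The same object doubles
#' as the perceptual-loss feature extractor in the test profile.
#'
#' @param seed seed for the (frozen) random weights.
#' @param base_channels channels of the first stage; later stages use
#'   2x, 3x, 4x this count.
#' @return An object of class `feature_backbone` with fields `params`,
#'   `channels`, `sizes`, `id`.
#' @export
tiny_backbone <- function(seed = 42, base_channels = 8) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ch <- base_channels * c(1L, 2L, 3L, 4L)
  params <- list(conv1 = conv_init(3, 3, ch[1]),
                 conv2 = conv_init(3, ch[1], ch[2]),
                 conv3 = conv_init(3, ch[2], ch[3]),
                 conv4 = conv_init(3, ch[3], ch[4]))
  structure(list(params = params, channels = ch,
                 sizes = c(112L, 56L, 28L, 14L),
                 id = sprintf("tiny-backbone-seed%d-c%d", seed, base_channels)),
            class = "feature_backbone")
}

# image (112 x 112 x 3 array) -> pixel-major (H*W) x 3 matrix
image_to_mat <- function(im) matrix(im, nrow = dim(im)[1] * dim(im)[2], ncol = 3)

mat_to_image <- function(m, size) array(m, c(size, size, 3))

#' Run a feature backbone
#'
#' @param backbone a [tiny_backbone()] (or an object honouring the same
#'   contract).
#' @param image `112 x 112 x 3` array in \[0, 1\].
#' @param with_cache keep intermediate activations for input-gradient
#'   backpropagation (needed by the perceptual loss).
#' @return list with `features` (list of 4 `(s^2) x C` matrices) and,
#'   if requested, `cache`.
#' @export
backbone_forward <- function(backbone, image, with_cache = FALSE) {
  p <- backbone$params
  x <- image_to_mat(image)
  c1 <- conv2d_fwd(x, p$conv1, 112, 112, 3); r1 <- relu_fwd(c1$out)
  p1 <- avgpool2_fwd(r1$out, 112, 112)
  c2 <- conv2d_fwd(p1, p$conv2, 56, 56, 3);  r2 <- relu_fwd(c2$out)
  p2 <- avgpool2_fwd(r2$out, 56, 56)
  c3 <- conv2d_fwd(p2, p$conv3, 28, 28, 3);  r3 <- relu_fwd(c3$out)
  p3 <- avgpool2_fwd(r3$out, 28, 28)
  c4 <- conv2d_fwd(p3, p$conv4, 14, 14, 3);  r4 <- relu_fwd(c4$out)
  features <- list(r1$out, r2$out, r3$out, r4$out)
  if (length(features) != 4L)
    stop_input("backbone contract violated: expected 4 feature maps")
  out <- list(features = features)
  if (with_cache)
    out$cache <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                      c3 = c3, r3 = r3, c4 = c4, r4 = r4)
  out
}

# Gradient w.r.t. the input image given gradients on the 4 feature maps.
# Backbone weights are frozen, so no parameter gradients are produced.
backbone_backward_input <- function(backbone, cache, gfeats) {
  p <- backbone$params
  g4 <- relu_bwd(gfeats[[4]], cache$r4$cache)
  g <- conv2d_bwd(g4, p$conv4, cache$c4$cache)$gx
  g <- avgpool2_bwd(g, 28, 28)
  g3 <- relu_bwd(gfeats[[3]] + g, cache$r3$cache)
  g <- conv2d_bwd(g3, p$conv3, cache$c3$cache)$gx
  g <- avgpool2_bwd(g, 56, 56)
  g2 <- relu_bwd(gfeats[[2]] + g, cache$r2$cache)
  g <- conv2d_bwd(g2, p$conv2, cache$c2$cache)$gx
  g <- avgpool2_bwd(g, 112, 112)
  g1 <- relu_bwd(gfeats[[1]] + g, cache$r1$cache)
  conv2d_bwd(g1, p$conv1, cache$c1$cache)$gx
}
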