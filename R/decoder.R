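#' Multi-stage reconstruction network parameters
#'
#' The reconstruction trunk maps the flat post-graph node vector (length
#' `R * D`) through a linear block to a `14 x 14 x channels` feature
#' tensor, then through three upsampling convolution blocks (x2 nearest
#' upsample, 5x5 same-padded convolution, group normalization, swish).
#' Four scale-specific heads (5x5 convolution to 3 channels + sigmoid) tap
#' the trunk after each block, emitting reconstructions at 14, 28, 56 and
#' 112 pixels; the coarse heads constrain training while the 112 head is
#' the reconstruction proper.
#'
#' Initialization: Kaiming-uniform for convolutions; the linear block uses
#' a spatially correlated Xavier-scale initialization (projection rows are
#' drawn on a coarse 4 x 4 grid per channel and cubically interpolated
#' across the 14 x 14 seed map). Adjacent seed positions therefore start
#' with correlated projections, so the decoder's initial outputs are
#' smooth: the raw-sum total-variation objective starts near its optimum
#' instead of dominating the first optimization steps, while gradients
#' keep full strength (no near-zero output layers that would create a
#' saddle). Group count must divide the channel width (asserted).
#'
#' @param R,D input study dimensions.
#' @param channels trunk width (64 in the reference configuration).
#' @param groups group-normalization group count.
#' @param seed optional initialization seed.
#' @return object of class `recon_net_params`.
#' @export
recon_net_params <- function(R, D, channels = 64, groups = 8, seed = NULL) {
  if (channels %% groups != 0)
    stop_input("group count (%d) must divide channel width (%d)",
               groups, channels)
  if (!is.null(seed)) set.seed(seed)
  structure(list(
    linear = smooth_linear_init(R * D, channels),
    blocks = lapply(1:3, function(i)
      list(conv = conv_init(5, channels, channels),
           gn = groupnorm_init(channels))),
    heads = lapply(1:4, function(i) conv_init(5, channels, 3)),
    channels = as.integer(channels), groups = as.integer(groups),
    R = as.integer(R), D = as.integer(D)),
    class = "recon_net_params")
}

# Xavier-scale linear map to the 14 x 14 x C seed tensor whose projection
# rows vary smoothly over the spatial grid: rows are drawn on a 4 x 4
# coarse grid per channel and cubically upsampled, so the decoder starts
# in the smooth-output regime the total-variation objective favors.
smooth_linear_init <- function(n_in, channels) {
  sd0 <- sqrt(2 / (n_in + 14 * 14 * channels))
  W <- matrix(0, 14 * 14 * channels, n_in)
  for (c in seq_len(channels)) {
    coarse <- array(rnorm(4 * 4 * n_in, sd = sd0), c(4, 4, n_in))
    sm <- resize_cubic(coarse, 14)                   # 14 x 14 x n_in
    rows <- ((c - 1) * 196 + 1):(c * 196)
    W[rows, ] <- matrix(sm, 196, n_in)
  }
  list(W = W, b = numeric(14 * 14 * channels))
}

#' Count trainable decoder parameters
#'
#' Closed-form count for a [recon_net_params()] configuration; useful for
#' sanity-checking the architecture.
#'
#' @param dec a [recon_net_params()].
#' @return integer parameter count.
#' @export
recon_param_count <- function(dec) {
  length(unlist(dec[c("linear", "blocks", "heads")]))
}

#' Decode post-graph node vectors into an image pyramid
#'
#' @param nodes_post_gnn flat numeric vector of length `R * D` (node
#'   vectors concatenated in ROI order) or an `R x D` matrix.
#' @param dec a [recon_net_params()].
#' @return an `image_pyramid` with all values strictly inside (0, 1).
#' @export
decode_nodes <- function(nodes_post_gnn, dec) {
  pyramid_from_fwd(decoder_forward(nodes_post_gnn, dec))
}

decoder_forward <- function(x, dec, with_cache = FALSE) {
  if (is.matrix(x)) x <- flatten_nodes(x)
  if (length(x) != dec$R * dec$D)
    stop_input("decoder input length %d, expected R*D = %d",
               length(x), dec$R * dec$D)
  C <- dec$channels
  sizes <- c(14L, 28L, 56L, 112L)
  lin <- linear_fwd(x, dec$linear)
  trunk <- matrix(lin, 14 * 14, C)      # 14x14 map, channel columns
  trunks <- list(trunk)
  caches <- vector("list", 3)
  for (i in 1:3) {
    s_in <- sizes[i]; s_out <- sizes[i + 1]
    up <- upsample2_fwd(trunks[[i]], s_in, s_in)
    cv <- conv2d_fwd(up, dec$blocks[[i]]$conv, s_out, s_out, 5)
    gn <- groupnorm_fwd(cv$out, dec$blocks[[i]]$gn, dec$groups)
    sw <- swish_fwd(gn$out)
    trunks[[i + 1]] <- sw$out
    caches[[i]] <- list(cv = cv, gn = gn, sw = sw)
  }
  heads <- vector("list", 4)
  head_caches <- vector("list", 4)
  for (h in 1:4) {
    s <- sizes[h]
    hc <- conv2d_fwd(trunks[[h]], dec$heads[[h]], s, s, 5)
    sg <- sigmoid_fwd(hc$out)
    heads[[h]] <- sg$out
    head_caches[[h]] <- list(hc = hc, sg = sg)
  }
  out <- list(heads = heads, sizes = sizes)
  if (with_cache)
    out$cache <- list(x = x, trunks = trunks, blocks = caches,
                      heads = head_caches)
  out
}

pyramid_from_fwd <- function(fwd) {
  lv <- lapply(1:4, function(h) mat_to_image(fwd$heads[[h]], fwd$sizes[h]))
  structure(setNames(lv, c("14", "28", "56", "112")), class = "image_pyramid")
}

# Backward from per-head gradients (list of (s^2) x 3 matrices, NULL for
# unconstrained heads). Returns parameter gradients and the gradient
# w.r.t. the flat input vector (which feeds the graph stack's backward).
decoder_backward <- function(gheads, dec, cache) {
  sizes <- c(14L, 28L, 56L, 112L)
  C <- dec$channels
  gtrunk <- vector("list", 4)
  gh_par <- vector("list", 4)
  for (h in 1:4) {
    if (is.null(gheads[[h]])) {
      gh_par[[h]] <- list(W = dec$heads[[h]]$W * 0, b = dec$heads[[h]]$b * 0)
      gtrunk[[h]] <- 0
      next
    }
    ck <- cache$heads[[h]]
    g <- sigmoid_bwd(gheads[[h]], ck$sg$cache)
    bw <- conv2d_bwd(g, dec$heads[[h]], ck$hc$cache)
    gh_par[[h]] <- list(W = bw$gW, b = bw$gb)
    gtrunk[[h]] <- bw$gx
  }
  gblocks <- vector("list", 3)
  g <- gtrunk[[4]]
  for (i in 3:1) {
    ck <- cache$blocks[[i]]
    g <- swish_bwd(g, ck$sw$cache)
    gn <- groupnorm_bwd(g, dec$blocks[[i]]$gn, ck$gn$cache)
    bw <- conv2d_bwd(gn$gx, dec$blocks[[i]]$conv, ck$cv$cache)
    gblocks[[i]] <- list(conv = list(W = bw$gW, b = bw$gb),
                         gn = list(gamma = gn$ggamma, beta = gn$gbeta))
    g <- upsample2_bwd(bw$gx, sizes[i], sizes[i]) + gtrunk[[i]]
  }
  lin <- linear_bwd(as.vector(g), dec$linear, cache$x)
  list(grads = list(linear = list(W = lin$gW, b = lin$gb),
                    blocks = gblocks, heads = gh_par),
       gx = lin$gx)
}
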