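#' Training configuration
#'
#' Settings for the two training stages. Stage 1 fits the encoder
#' (image -> fMRI) with supervised pairs; stage 2 freezes the encoder and
#' fits the graph stack + reconstruction network with a supervised branch
#' (real fMRI -> image) and an optional self-supervised branch (unlabeled
#' image -> frozen encoder -> graph -> decoder -> same image).
#'
#' Desk-scale defaults are sized so a full seeded pipeline (simulate,
#' both stages, reconstruction, evaluation) runs in minutes on one CPU;
#' epochs and widths scale up transparently.
#'
#' @param stage 1 or 2.
#' @param epochs training epochs.
#' @param batch_size paired-batch size.
#' @param batch_size_unlabeled self-supervised batch size (stage 2).
#' @param lr Adam learning rate.
#' @param seed stage seed (controls init and batch shuffling).
#' @param K number of stacked node-edge interaction blocks.
#' @param channels,groups reconstruction-trunk width and group-norm groups.
#' @param ssl enable the self-supervised branch in stage 2.
#' @param roi_subset `"VC"`, `"LVC"`, `"HVC"`, or a character vector of ROI
#'   names; the study is restricted accordingly before training.
#' @param average_test_repeats average repeated test recordings before
#'   decoding (the conventional choice) rather than using single trials.
#' @return object of class `train_config`.
#' @export
train_config <- function(stage = 1, epochs = if (stage == 1) 10 else 10,
                         batch_size = if (stage == 1) 8 else 4,
                         batch_size_unlabeled = 4,
                         lr = if (stage == 1) 1e-4 else 1e-3,
                         seed = 1, K = 2, channels = 16,
                         groups = 8, ssl = TRUE, roi_subset = "VC",
                         average_test_repeats = TRUE) {
  if (!stage %in% c(1, 2)) stop_input("stage must be 1 or 2")
  if (epochs < 1 || batch_size < 1) stop_input("epochs and batch sizes must be positive")
  if (length(roi_subset) == 1 && roi_subset %in% names(roi_sets))
    roi_subset <- roi_sets[[roi_subset]]
  if (length(roi_subset) == 0) stop_input("roi_subset must be non-empty")
  structure(list(stage = as.integer(stage), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 batch_size_unlabeled = as.integer(batch_size_unlabeled),
                 lr = lr, seed = as.integer(seed), K = as.integer(K),
                 channels = as.integer(channels), groups = as.integer(groups),
                 ssl = isTRUE(ssl), roi_subset = roi_subset,
                 average_test_repeats = isTRUE(average_test_repeats)),
            class = "train_config")
}

apply_roi_subset <- function(study, cfg) {
  md <- study$metadata
  if (setequal(cfg$roi_subset, md$roi_names)) return(study)
  subset_rois(study, intersect(md$roi_names, cfg$roi_subset))
}

#' Stage 1: train the encoder
#'
#' Minimizes the sum of the fMRI mean-squared-error and negative-cosine
#' losses over the training pairs with Adam. The feature backbone is
#' frozen throughout (its checksum is recorded before and after). Padded
#' target positions are masked out of both the prediction and the loss.
#'
#' @param study a [study_container()].
#' @param cfg a stage-1 [train_config()].
#' @param backbone a [tiny_backbone()].
#' @param loss_cfg a [loss_config()].
#' @param init_encoder optional [encoder_params()] to warm-start from
#'   (resume training, e.g. a fine-tuning phase at a lower learning rate).
#' @return list with `encoder` ([encoder_params()]), `backbone`, `history`
#'   (data.frame epoch/loss/mse/cossim), `backbone_checksum`
#'   (before/after), `roi_names`, `voxel_counts`.
#' @export
train_encoder <- function(study, cfg = train_config(stage = 1),
                          backbone = tiny_backbone(),
                          loss_cfg = loss_config(), init_encoder = NULL) {
  if (cfg$stage != 1) stop_input("train_encoder needs a stage-1 config")
  study <- apply_roi_subset(study, cfg)
  n <- length(study$train_pairs)
  if (n == 0) stop_input("empty train split")
  md <- study$metadata
  counts <- as.integer(md$voxel_counts)
  R <- length(counts); D <- max(counts)

  ck_before <- params_checksum(backbone$params)
  feats <- lapply(study$train_pairs, function(p)
    backbone_forward(backbone, p$image)$features)
  targets <- lapply(study$train_pairs, function(p) flatten_nodes(p$fmri))
  mask <- as.numeric(t(vapply(seq_len(R), function(r)
    as.numeric(seq_len(D) <= counts[r]), numeric(D))))

  set.seed(cfg$seed)
  enc <- if (is.null(init_encoder)) encoder_params(backbone, R, D)
         else init_encoder   # warm start, e.g. to resume at a lower rate
  opt <- adam_init(enc[c("branches", "fuse")], lr = cfg$lr)
  history <- data.frame()
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- ep_mse <- ep_cos <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      m <- length(idx)
      gbr <- NULL
      gout_mat <- matrix(0, R * D, m)
      x_mat <- matrix(0, ncol(enc$fuse$W), m)
      bl <- bm <- bc <- 0
      for (s in seq_len(m)) {
        i <- idx[s]
        fwd <- encoder_forward(enc, backbone, feats[[i]])
        fe <- fwd$fe * mask
        el <- encoder_loss(fe, targets[[i]], loss_cfg, grad = TRUE)
        bm <- bm + loss_f_mse(fe, targets[[i]])
        bc <- bc + loss_f_cossim(fe, targets[[i]])
        bl <- bl + el$loss
        gfe <- el$grad * mask
        gout_mat[, s] <- gfe
        x_mat[, s] <- fwd$cache$x
        g <- encoder_backward_branches(enc, backbone, gfe, fwd$cache)
        gbr <- if (is.null(gbr)) g else tree_map2(`+`, gbr, g)
      }
      gacc <- list(branches = tree_scale(gbr, 1 / m),
                   fuse = list(W = tcrossprod(gout_mat, x_mat) / m,
                               b = rowSums(gout_mat) / m))
      st <- adam_step(opt, enc[c("branches", "fuse")], gacc)
      opt <- st$opt
      enc$branches <- st$params$branches
      enc$fuse <- st$params$fuse
      ep_loss <- ep_loss + bl / m; ep_mse <- ep_mse + bm / m
      ep_cos <- ep_cos + bc / m; nb <- nb + 1
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / nb, mse = ep_mse / nb,
      cossim = ep_cos / nb))
  }
  ck_after <- params_checksum(backbone$params)
  list(encoder = enc, backbone = backbone, history = history,
       backbone_checksum = list(before = ck_before, after = ck_after),
       roi_names = md$roi_names, voxel_counts = counts,
       config = cfg)
}

# scale a gradient tree by 1/m
tree_scale <- function(tree, s) tree_map2(function(a, b) a * s, tree, tree)

#' Stage 2: train the graph stack and reconstruction network
#'
#' Each optimization step combines a supervised batch (real fMRI ->
#' connectivity -> graph blocks -> decoder, against the stimulus image's
#' pyramid) and, when enabled, a self-supervised batch (unlabeled image ->
#' frozen encoder -> estimated fMRI -> same decoding path, against the
#' unlabeled image's own pyramid). Both branches use the identical loss
#' composition and their batch-mean losses are summed per step. The
#' encoder and backbone are never updated; their checksums are asserted
#' bit-identical before and after.
#'
#' @param study a [study_container()].
#' @param encoder_bundle the result of [train_encoder()] (or `NULL` when
#'   `cfg$ssl` is `FALSE`).
#' @param cfg a stage-2 [train_config()].
#' @param loss_cfg a [loss_config()].
#' @return list with `gnn` ([nei_gnn_params()]), `dec`
#'   ([recon_net_params()]), `history`, `encoder_checksum` (before/after),
#'   plus the frozen encoder bundle and configs for downstream use.
#' @export
train_decoder <- function(study, encoder_bundle, cfg = train_config(stage = 2),
                          loss_cfg = loss_config()) {
  if (cfg$stage != 2) stop_input("train_decoder needs a stage-2 config")
  study <- apply_roi_subset(study, cfg)
  md <- study$metadata
  counts <- as.integer(md$voxel_counts)
  R <- length(counts); D <- max(counts)
  n <- length(study$train_pairs)
  if (n == 0) stop_input("empty train split")

  use_ssl <- cfg$ssl
  if (use_ssl && is.null(encoder_bundle))
    stop_input("stage-2 training with ssl = TRUE needs a stage-1 encoder bundle")
  if (!is.null(encoder_bundle) &&
      !identical(encoder_bundle$roi_names, md$roi_names))
    stop_input("encoder was trained for a different ROI set")
  n_unlab <- length(study$unlabeled_images)
  if (use_ssl && n_unlab == 0) {
    warning("unlabeled pool is empty; disabling the self-supervised branch")
    use_ssl <- FALSE
  }

  enc_ck_before <- if (!is.null(encoder_bundle))
    params_checksum(encoder_bundle$encoder[c("branches", "fuse")]) else NULL

  # precompute supervised inputs/targets (incl. static perceptual features)
  pbb <- loss_cfg$perceptual_backbone
  sup_nodes <- lapply(study$train_pairs, function(p) p$fmri$vectors)
  sup_pyr <- lapply(study$train_pairs, function(p) build_pyramid(p$image))
  sup_feats <- lapply(study$train_pairs, function(p)
    backbone_forward(pbb, p$image)$features)
  # frozen-encoder estimates and targets for the self-supervised branch
  if (use_ssl) {
    ssl_nodes <- lapply(study$unlabeled_images, function(im)
      encode_image(im, encoder_bundle$backbone, encoder_bundle$encoder,
                   md$roi_names, counts)$vectors)
    ssl_pyr <- lapply(study$unlabeled_images, build_pyramid)
    ssl_feats <- lapply(study$unlabeled_images, function(im)
      backbone_forward(pbb, im)$features)
  }

  set.seed(cfg$seed + 1L)
  gnn <- nei_gnn_params(R, D, K = cfg$K)
  dec <- recon_net_params(R, D, channels = cfg$channels, groups = cfg$groups)
  ptree <- list(gnn = unclass(gnn), dec = dec[c("linear", "blocks", "heads")])
  opt <- adam_init(ptree, lr = cfg$lr)

  branch_pass <- function(nodes, pyr_r, ref_feats) {
    gf <- stack_forward_cached(nodes, gnn)
    df <- decoder_forward(gf$nodes, dec, with_cache = TRUE)
    lg <- decoder_branch_loss_grad(df$heads, pyr_r, loss_cfg, ref_feats)
    db <- decoder_backward(lg$gheads, dec, df$cache)
    ggnn <- stack_backward(gf, gnn, unflatten_nodes(db$gx, R, D))
    list(loss = lg$loss, grads = list(gnn = unclass(ggnn), dec = db$grads))
  }

  history <- data.frame()
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    if (use_ssl) ord_u <- sample.int(n_unlab)
    ep_sl <- ep_ssl <- 0; nb <- 0; u_ptr <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      gacc <- NULL; l_sl <- 0
      for (i in idx) {
        bp <- branch_pass(sup_nodes[[i]], sup_pyr[[i]], sup_feats[[i]])
        l_sl <- l_sl + bp$loss
        gacc <- if (is.null(gacc)) bp$grads else tree_map2(`+`, gacc, bp$grads)
      }
      gacc <- tree_scale(gacc, 1 / length(idx))
      l_sl <- l_sl / length(idx)
      l_ssl <- 0
      if (use_ssl) {
        gu <- NULL
        take <- min(cfg$batch_size_unlabeled, n_unlab)
        uidx <- ord_u[((u_ptr + seq_len(take) - 1) %% n_unlab) + 1]
        u_ptr <- u_ptr + take
        for (j in uidx) {
          bp <- branch_pass(ssl_nodes[[j]], ssl_pyr[[j]], ssl_feats[[j]])
          l_ssl <- l_ssl + bp$loss
          gu <- if (is.null(gu)) bp$grads else tree_map2(`+`, gu, bp$grads)
        }
        gacc <- tree_map2(`+`, gacc, tree_scale(gu, 1 / take))
        l_ssl <- l_ssl / take
      }
      st <- adam_step(opt, list(gnn = unclass(gnn),
                                dec = dec[c("linear", "blocks", "heads")]),
                      gacc)
      opt <- st$opt
      for (k in seq_along(gnn)) gnn[[k]] <- st$params$gnn[[k]]
      dec$linear <- st$params$dec$linear
      dec$blocks <- st$params$dec$blocks
      dec$heads <- st$params$dec$heads
      ep_sl <- ep_sl + l_sl; ep_ssl <- ep_ssl + l_ssl; nb <- nb + 1
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = (ep_sl + ep_ssl) / nb, loss_sl = ep_sl / nb,
      loss_ssl = if (use_ssl) ep_ssl / nb else NA_real_))
  }

  enc_ck_after <- if (!is.null(encoder_bundle))
    params_checksum(encoder_bundle$encoder[c("branches", "fuse")]) else NULL
  list(gnn = gnn, dec = dec, history = history,
       encoder_checksum = list(before = enc_ck_before, after = enc_ck_after),
       encoder_bundle = encoder_bundle, config = cfg,
       roi_names = md$roi_names, voxel_counts = counts, ssl_used = use_ssl)
}

#' Reconstruct test stimuli from recorded fMRI
#'
#' For every test stimulus: (optionally repeat-averaged) real fMRI ->
#' cosine connectivity -> graph blocks -> reconstruction network; the 112
#' pixel head is the reconstruction. The encoder plays no role at test
#' time. Pure and deterministic given the trained parameters.
#'
#' @param study a [study_container()].
#' @param model the result of [train_decoder()].
#' @param average average the repeated recordings before decoding (the
#'   conventional choice) or decode only the first repeat. Defaults to the
#'   training config's `average_test_repeats`.
#' @return list of `112 x 112 x 3` reconstructions, one per test stimulus.
#' @seealso [reconstruct_trials()] for per-trial decoding of every repeat.
#' @export
reconstruct <- function(study, model,
                        average = model$config$average_test_repeats %||% TRUE) {
  study <- apply_roi_subset(study, model$config)
  if (!identical(model$roi_names, study$metadata$roi_names))
    stop_input("model was trained for a different ROI set")
  lapply(study$test_repeats, function(reps) {
    s <- if (average) average_repeats(reps) else reps[[1]]
    decode_signal(s, model)
  })
}

#' @rdname reconstruct
#' @export
reconstruct_trials <- function(study, model) {
  study <- apply_roi_subset(study, model$config)
  lapply(study$test_repeats, function(reps)
    lapply(reps, function(s) decode_signal(s, model)))
}

decode_signal <- function(signal_set, model) {
  nodes <- stack_forward(signal_set, model$gnn)
  final_reconstruction(decode_nodes(flatten_nodes(nodes), model$dec))
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single RDS archive holding every parameter group
#' (encoder + backbone identifier, graph blocks, reconstruction network)
#' together with the configs and seeds that produced them.
#'
#' @param model result of [train_encoder()] or [train_decoder()].
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "neirecon-checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_input("checkpoint not found: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "neirecon-checkpoint"))
    stop_input("not a neirecon checkpoint: %s", path)
  obj$model
}
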