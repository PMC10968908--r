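#' Synthetic study specification
#'
#' Defines a fully synthetic study in the style of a generic-object-decoding
#' experiment: a train split of single presentations, a test split with
#' repeated presentations, an unlabeled image pool, seven ROIs with unequal
#' voxel counts, and a known linear image-to-fMRI forward map observed under
#' additive Gaussian noise at a controlled signal-to-noise ratio.
#'
#' The SNR convention is a per-ROI variance ratio: `Var(signal) /
#' Var(noise)`, where the signal variance is the across-stimulus variance of
#' the noiseless response averaged over that ROI's voxels. [snr_estimate()]
#' is the matching estimator.
#'
#' @param n_train,n_test,n_repeats split sizes (test stimuli are each
#'   recorded `n_repeats` times).
#' @param n_unlabeled size of the unlabeled image pool for the
#'   self-supervised branch.
#' @param roi_voxel_counts integer vector of voxels per ROI.
#' @param roi_names ROI identifiers (default the seven visual-cortex ROIs).
#' @param snr positive variance ratio Var(signal)/Var(noise) per ROI
#'   (`Inf` gives the noise-free limit).
#' @param image_size stimulus side length; the pipeline is built around 112.
#' @param latent_dim side length of the coarse latent grid from which smooth
#'   random images are generated.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_train = 64, n_test = 10, n_repeats = 5,
                           n_unlabeled = 32,
                           roi_voxel_counts = c(20, 24, 18, 16, 12, 14, 8),
                           roi_names = roi_sets$VC, snr = 1.0,
                           image_size = 112, latent_dim = 6, seed = 1) {
  spec <- structure(
    list(n_train = as.integer(n_train), n_test = as.integer(n_test),
         n_repeats = as.integer(n_repeats),
         n_unlabeled = as.integer(n_unlabeled),
         roi_voxel_counts = as.integer(roi_voxel_counts),
         roi_names = as.character(roi_names), snr = as.numeric(snr),
         image_size = as.integer(image_size),
         latent_dim = as.integer(latent_dim), seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

#' @rdname synthetic_spec
#' @param spec object to validate.
#' @export
validate_synthetic_spec <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop_input("not a synthetic_spec")
  if (spec$n_train < 1) stop_input("n_train must be >= 1")
  if (spec$n_test < 1) stop_input("n_test must be >= 1")
  if (spec$n_repeats < 1) stop_input("n_repeats must be >= 1")
  if (spec$n_unlabeled < 0) stop_input("n_unlabeled must be >= 0")
  if (is.na(spec$snr) || spec$snr <= 0)
    stop_input("snr must be > 0 (Inf gives the noise-free limit)")
  if (any(spec$roi_voxel_counts < 1)) stop_input("voxel counts must be >= 1")
  if (length(spec$roi_voxel_counts) < 2) stop_input("need >= 2 ROIs")
  if (length(spec$roi_names) != length(spec$roi_voxel_counts))
    stop_input("roi_names and roi_voxel_counts lengths differ")
  if (spec$image_size != 112)
    stop_input("image_size is fixed to 112 in this pipeline")
  if (spec$latent_dim < 2) stop_input("latent_dim must be >= 2")
  invisible(spec)
}

# Smooth random image: coarse Gaussian latent grid, cubic-upsampled, then
# squashed into (0, 1) with a logistic map.
random_smooth_image <- function(latent_dim, size = 112) {
  z <- array(rnorm(latent_dim * latent_dim * 3), c(latent_dim, latent_dim, 3))
  plogis(2 * resize_cubic(z, size))
}

# Forward-model feature: the centred, flattened 14 x 14 pyramid level.
forward_features <- function(image) as.vector(resize_cubic(image, 14)) - 0.5

#' Generate a synthetic study with a known forward model
#'
#' Images are smooth random fields (low-frequency Gaussian latents pushed
#' through a logistic squashing map). The fMRI response of each ROI is a
#' fixed random linear map of the image's coarse (14 x 14) representation
#' plus zero-mean Gaussian noise whose per-ROI variance is set so that
#' `Var(signal)/Var(noise) = spec$snr`. The ground-truth map is returned
#' alongside the study so recovery can be tested downstream.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `study` (a [study_container()]) and `truth`
#'   (per-ROI operators, noise scales, and the feature description).
#' @export
generate_study <- function(spec) {
  validate_synthetic_spec(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  R <- length(spec$roi_voxel_counts)
  P <- 14 * 14 * 3
  gen_images <- function(n) lapply(seq_len(n), function(i)
    random_smooth_image(spec$latent_dim, spec$image_size))
  train_imgs <- gen_images(spec$n_train)
  test_imgs <- gen_images(spec$n_test)
  unlab_imgs <- gen_images(spec$n_unlabeled)

  operators <- lapply(seq_len(R), function(r)
    matrix(rnorm(spec$roi_voxel_counts[r] * P, sd = 1 / sqrt(P)),
           spec$roi_voxel_counts[r], P))

  signal_for <- function(img) {
    x <- forward_features(img)
    lapply(operators, function(A) as.vector(A %*% x))
  }
  train_sig <- lapply(train_imgs, signal_for)
  test_sig <- lapply(test_imgs, signal_for)

  # per-ROI noise scale from the empirical signal variance over all stimuli
  all_sig <- c(train_sig, test_sig)
  noise_sd <- vapply(seq_len(R), function(r) {
    m <- do.call(rbind, lapply(all_sig, `[[`, r))  # stimuli x voxels
    v_signal <- mean(apply(m, 2, var))
    sqrt(v_signal / spec$snr)
  }, numeric(1))

  noisy <- function(sig) align_rois(lapply(seq_len(R), function(r)
    sig[[r]] + rnorm(length(sig[[r]]), sd = noise_sd[r])), spec$roi_names)

  train_pairs <- lapply(seq_len(spec$n_train), function(i)
    list(image = train_imgs[[i]], fmri = noisy(train_sig[[i]])))
  test_repeats <- lapply(seq_len(spec$n_test), function(i)
    lapply(seq_len(spec$n_repeats), function(k) noisy(test_sig[[i]])))

  study <- study_container(
    train_pairs, test_imgs, test_repeats, unlab_imgs,
    metadata = list(subject = sprintf("synthetic-seed%d", spec$seed),
                    roi_names = spec$roi_names,
                    voxel_counts = spec$roi_voxel_counts,
                    seed = spec$seed, snr = spec$snr))
  truth <- list(operators = operators, noise_sd = noise_sd,
                feature = "centred 14x14 cubic pyramid level, flattened")
  list(study = study, truth = truth)
}

#' Estimate per-ROI signal-to-noise ratio from repeated recordings
#'
#' For each ROI, the across-stimulus variance of per-stimulus repeat means
#' is compared with the mean within-stimulus variance across repeats. The
#' repeat-mean variance overstates the signal variance by `sigma^2 / m`
#' (`m` repeats), so that term is subtracted before dividing, making the
#' estimator consistent for the generator's variance-ratio convention.
#' A noise-free container yields `Inf`.
#'
#' @param container a [study_container()] whose test stimuli all have at
#'   least 2 repeats.
#' @return named numeric vector, one estimate per ROI.
#' @export
snr_estimate <- function(container) {
  validate_study(container)
  nrep <- vapply(container$test_repeats, length, integer(1))
  if (any(nrep < 2))
    stop_input("snr_estimate needs >= 2 repeats per test stimulus")
  md <- container$metadata
  R <- length(md$roi_names)
  counts <- as.integer(md$voxel_counts)
  est <- vapply(seq_len(R), function(r) {
    vox <- seq_len(counts[r])
    per_stim <- lapply(container$test_repeats, function(reps) {
      m <- do.call(rbind, lapply(reps, function(s) s$vectors[r, vox]))
      list(mean = colMeans(m), within = mean(apply(m, 2, var)), m = nrow(m))
    })
    means <- do.call(rbind, lapply(per_stim, `[[`, "mean"))
    num <- mean(apply(means, 2, var))
    within <- mean(vapply(per_stim, `[[`, numeric(1), "within"))
    if (within == 0) return(Inf)
    correction <- mean(vapply(per_stim, function(p) p$within / p$m, numeric(1)))
    max(num - correction, 0) / within
  }, numeric(1))
  setNames(est, md$roi_names)
}
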