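#' Pipeline configuration
#'
#' A single nested configuration for the full pipeline (simulate, stage-1
#' encoder training, stage-2 decoder training, reconstruction,
#' evaluation), loadable from YAML. One global seed fans out
#' deterministically to stage seeds (spec: seed, encoder: seed + 1000,
#' decoder: seed + 2000, evaluation: seed + 3000) so individual stages can
#' be rerun in isolation.
#'
#' @param config a named list (e.g. from [yaml::read_yaml()]) with any of
#'   the sections `seed`, `spec`, `train` (sub-sections `encoder`,
#'   `decoder`), `loss`, `eval`, `paths`. Missing fields take package
#'   defaults; unknown keys are rejected.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  rep <- validate_config(config)
  if (length(rep$errors))
    stop_input("invalid pipeline config:\n  %s",
               paste(rep$errors, collapse = "\n  "))
  rep$config
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' Pure schema validation with actionable messages; no side effects.
#' Returns both the error list and the fully defaulted configuration.
#'
#' @param config named list (or YAML path).
#' @return list with `errors` (character), `notes` (character, e.g.
#'   defaulted sections) and `config` (defaults filled in).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errors <- character(0); notes <- character(0)
  known <- c("seed", "spec", "train", "loss", "eval", "paths")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    errors <- c(errors, sprintf("unknown top-level key: %s", unknown))

  seed <- config$seed %||% 1L
  if (!is.numeric(seed)) errors <- c(errors, "seed must be an integer")

  spec_def <- list(n_train = 64, n_test = 10, n_repeats = 5,
                   n_unlabeled = 32,
                   roi_voxel_counts = c(20, 24, 18, 16, 12, 14, 8),
                   roi_names = roi_sets$VC, snr = 1.0, image_size = 112,
                   latent_dim = 6)
  if (is.null(config$spec)) notes <- c(notes, "spec: defaults used")
  unknown <- setdiff(names(config$spec), c(names(spec_def), "seed"))
  if (length(unknown)) errors <- c(errors, sprintf("unknown spec key: %s", unknown))
  spec_cfg <- modifyList(spec_def, config$spec %||% list())
  if (!is.null(spec_cfg$snr) && (!is.numeric(spec_cfg$snr) || spec_cfg$snr <= 0))
    errors <- c(errors, "spec$snr must be a positive number")
  if (spec_cfg$n_train < 1) errors <- c(errors, "spec$n_train must be >= 1")

  tr_def <- list(
    encoder = list(epochs = 10, batch_size = 8, lr = 1e-4),
    decoder = list(epochs = 10, batch_size = 4, batch_size_unlabeled = 4,
                   lr = 1e-3, K = 2, channels = 16, groups = 8, ssl = TRUE,
                   roi_subset = "VC"))
  if (is.null(config$train)) notes <- c(notes, "train: defaults used")
  for (st in names(config$train %||% list())) {
    if (!st %in% c("encoder", "decoder")) {
      errors <- c(errors, sprintf("unknown train section: %s", st)); next
    }
    unknown <- setdiff(names(config$train[[st]]), names(tr_def[[st]]))
    if (length(unknown))
      errors <- c(errors, sprintf("unknown train$%s key: %s", st, unknown))
  }
  tr_cfg <- modifyList(tr_def, config$train %||% list())
  if (tr_cfg$decoder$K < 0) errors <- c(errors, "train$decoder$K must be >= 0")

  loss_def <- list(term_weights = c(mse = 1, cossim = 1, mae = 1, per = 1,
                                    tv = 0.002),
                   scales_constrained = c(14, 28, 56, 112),
                   perceptual_layers = 1:4)
  if (is.null(config$loss)) notes <- c(notes, "loss: defaults used")
  unknown <- setdiff(names(config$loss), names(loss_def))
  if (length(unknown)) errors <- c(errors, sprintf("unknown loss key: %s", unknown))
  loss_cfg <- modifyList(loss_def, config$loss %||% list())
  if (!all(unlist(loss_cfg$scales_constrained) %in% c(14, 28, 56, 112)))
    errors <- c(errors, "loss$scales_constrained must be within {14,28,56,112}")

  eval_def <- list(n_values = c(2, 5, 10), similarities = c("mse", "ssim"),
                   repetitions = 10)
  if (is.null(config$eval)) notes <- c(notes, "eval: defaults used")
  unknown <- setdiff(names(config$eval), names(eval_def))
  if (length(unknown)) errors <- c(errors, sprintf("unknown eval key: %s", unknown))
  eval_cfg <- modifyList(eval_def, config$eval %||% list())
  if (any(unlist(eval_cfg$n_values) > spec_cfg$n_test))
    errors <- c(errors,
                sprintf("eval$n_values contains %d > spec$n_test = %d",
                        max(unlist(eval_cfg$n_values)), spec_cfg$n_test))

  paths_cfg <- modifyList(list(out_dir = "neirecon-run"),
                          config$paths %||% list())

  full <- structure(list(seed = as.integer(seed), spec = spec_cfg,
                         train = tr_cfg, loss = loss_cfg, eval = eval_cfg,
                         paths = paths_cfg),
                    class = "pipeline_config")
  list(errors = errors, notes = notes, config = full)
}

config_to_spec <- function(cfg)
  synthetic_spec(n_train = cfg$spec$n_train, n_test = cfg$spec$n_test,
                 n_repeats = cfg$spec$n_repeats,
                 n_unlabeled = cfg$spec$n_unlabeled,
                 roi_voxel_counts = cfg$spec$roi_voxel_counts,
                 roi_names = cfg$spec$roi_names, snr = cfg$spec$snr,
                 latent_dim = cfg$spec$latent_dim, seed = cfg$seed)

config_to_loss <- function(cfg, backbone = tiny_backbone())
  loss_config(perceptual_backbone = backbone,
              perceptual_layers = cfg$loss$perceptual_layers,
              term_weights = unlist(cfg$loss$term_weights),
              scales_constrained = unlist(cfg$loss$scales_constrained))

#' Run the full pipeline
#'
#' simulate -> train encoder -> train decoder -> reconstruct -> evaluate,
#' deterministically from one seed. When `out_dir` is set, artifacts are
#' written: `study.rds`, `encoder.rds`, `decoder.rds`, reconstruction PNGs
#' with an index CSV (if the `png` package is installed), `metrics.json`,
#' and a `manifest.json` recording the config hash and all stage seeds.
#'
#' @param config a [pipeline_config()], a named list, or a YAML path.
#' @param out_dir output directory (`NULL` = keep everything in memory).
#' @param quiet suppress progress messages.
#' @return list with `study`, `encoder`, `decoder`, `recons`, `metrics`,
#'   `seeds`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cfg <- config
  seeds <- list(spec = cfg$seed, encoder = cfg$seed + 1000L,
                decoder = cfg$seed + 2000L, eval = cfg$seed + 3000L)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[simulate] generating synthetic study (seed %d)", seeds$spec)
  gen <- generate_study(config_to_spec(cfg))
  study <- gen$study

  backbone <- tiny_backbone()
  loss_cfg <- config_to_loss(cfg, backbone)

  say("[stage 1] training encoder (%d epochs)", cfg$train$encoder$epochs)
  enc_cfg <- train_config(stage = 1, epochs = cfg$train$encoder$epochs,
                          batch_size = cfg$train$encoder$batch_size,
                          lr = cfg$train$encoder$lr, seed = seeds$encoder,
                          roi_subset = cfg$train$decoder$roi_subset)
  enc <- train_encoder(study, enc_cfg, backbone, loss_cfg)

  say("[stage 2] training decoder (%d epochs, K = %d)",
      cfg$train$decoder$epochs, cfg$train$decoder$K)
  dec_cfg <- train_config(stage = 2, epochs = cfg$train$decoder$epochs,
                          batch_size = cfg$train$decoder$batch_size,
                          batch_size_unlabeled = cfg$train$decoder$batch_size_unlabeled,
                          lr = cfg$train$decoder$lr, seed = seeds$decoder,
                          K = cfg$train$decoder$K,
                          channels = cfg$train$decoder$channels,
                          groups = cfg$train$decoder$groups,
                          ssl = cfg$train$decoder$ssl,
                          roi_subset = cfg$train$decoder$roi_subset)
  dec <- train_decoder(study, enc, dec_cfg, loss_cfg)

  say("[reconstruct] decoding %d test stimuli", length(study$test_stimuli))
  recons <- reconstruct(study, dec)

  say("[evaluate] n-way identification")
  metrics <- evaluate_reconstructions(
    recons, study$test_stimuli, n_values = unlist(cfg$eval$n_values),
    similarities = unlist(cfg$eval$similarities),
    repetitions = cfg$eval$repetitions, seed = seeds$eval)

  result <- list(study = study, encoder = enc, decoder = dec,
                 recons = recons, metrics = metrics, seeds = seeds,
                 config = cfg)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir, quiet)
  result
}

write_pipeline_artifacts <- function(result, out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_study(result$study, file.path(out_dir, "study.rds"))
  save_checkpoint(result$encoder, file.path(out_dir, "encoder.rds"))
  save_checkpoint(result$decoder, file.path(out_dir, "decoder.rds"))
  jsonlite::write_json(result$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (requireNamespace("png", quietly = TRUE))
    write_images_png(result$recons, file.path(out_dir, "recon"), "recon")
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass_deep(result$config), cfg_file)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_file)),
                   seeds = result$seeds,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  if (!quiet) message(sprintf("artifacts written to %s", out_dir))
  invisible(out_dir)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
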