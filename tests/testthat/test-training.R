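# Training tests run at deliberately tiny problem sizes (few pairs, narrow
# trunk) so the whole file stays fast on one CPU; the full desk-scale run
# lives in the acceptance suite.

test_that("encoder training descends and is seeded-reproducible", {
  gen <- tiny_study(n_train = 8, seed = 41)
  cfg <- train_config(stage = 1, epochs = 3, batch_size = 4, lr = 1e-4,
                      seed = 5, roi_subset = gen$study$metadata$roi_names)
  run1 <- train_encoder(gen$study, cfg)
  expect_lt(tail(run1$history$loss, 1), run1$history$loss[1])
  run2 <- train_encoder(gen$study, cfg)
  expect_equal(tail(run1$history$loss, 1), tail(run2$history$loss, 1),
               tolerance = 1e-6)
  # backbone untouched
  expect_identical(run1$backbone_checksum$before, run1$backbone_checksum$after)
  expect_error(train_encoder(gen$study, train_config(stage = 2)), "stage-1")
})

test_that("an over-capacity encoder drives the cosine term toward -1", {
  # noise-free pairs, hugely overparameterized encoder; a short two-phase
  # schedule (coarse then fine learning rate) approaches perfect alignment
  gen <- tiny_study(n_train = 2, snr = Inf, seed = 42)
  rois <- gen$study$metadata$roi_names
  p1 <- train_encoder(gen$study, train_config(
    stage = 1, epochs = 150, batch_size = 1, lr = 1e-4, seed = 6,
    roi_subset = rois))
  p2 <- train_encoder(gen$study, train_config(
    stage = 1, epochs = 80, batch_size = 1, lr = 1e-5, seed = 7,
    roi_subset = rois), init_encoder = p1$encoder)
  expect_lt(tail(p2$history$cossim, 1), -0.9)
})

test_that("stage 2 freezes the encoder and reacts to the SSL branch", {
  gen <- tiny_study(n_train = 6, n_unlabeled = 4, seed = 43)
  st <- gen$study
  enc_cfg <- train_config(stage = 1, epochs = 2, batch_size = 4, lr = 1e-4,
                          seed = 7, roi_subset = st$metadata$roi_names)
  enc <- train_encoder(st, enc_cfg)
  base <- train_config(stage = 2, epochs = 1, batch_size = 3,
                       batch_size_unlabeled = 3, lr = 3e-4, seed = 8,
                       channels = 16, groups = 4,
                       roi_subset = st$metadata$roi_names)
  dec <- train_decoder(st, enc, base)
  expect_identical(dec$encoder_checksum$before, dec$encoder_checksum$after)
  expect_true(dec$ssl_used)

  no_ssl <- base; no_ssl$ssl <- FALSE
  dec2 <- train_decoder(st, enc, no_ssl)
  expect_false(isTRUE(all.equal(dec$history$loss_sl, dec2$history$loss_sl)))

  # an empty unlabeled pool downgrades SSL with a warning
  st2 <- st; st2$unlabeled_images <- list()
  expect_warning(d3 <- train_decoder(st2, enc, base), "unlabeled")
  expect_false(d3$ssl_used)
})

test_that("reconstruction is pure, complete and repeat-aware", {
  gen <- tiny_study(n_train = 6, n_test = 3, n_repeats = 3, seed = 44)
  st <- gen$study
  cfg <- train_config(stage = 2, epochs = 1, batch_size = 3, lr = 3e-4,
                      seed = 9, ssl = FALSE, channels = 16, groups = 4,
                      roi_subset = st$metadata$roi_names)
  dec <- train_decoder(st, NULL, cfg)
  r1 <- reconstruct(st, dec)
  expect_length(r1, 3)
  expect_identical(r1, reconstruct(st, dec))
  for (im in r1) expect_equal(dim(im), c(112, 112, 3))
  # averaging the repeats changes the decoded input, hence the output
  r_first <- reconstruct(st, dec, average = FALSE)
  expect_false(identical(r1, r_first))
  trials <- reconstruct_trials(st, dec)
  expect_length(trials[[1]], 3)
  expect_identical(trials[[1]][[1]], r_first[[1]])
})

test_that("a tiny decoder memorizes noise-free pairs to low MAE", {
  gen <- tiny_study(n_train = 2, n_test = 2, snr = Inf, seed = 51)
  cfg <- train_config(stage = 2, epochs = 100, batch_size = 1, lr = 1e-3,
                      seed = 9, ssl = FALSE, channels = 16, groups = 4,
                      roi_subset = gen$study$metadata$roi_names)
  dec <- train_decoder(gen$study, NULL, cfg)
  pyr_r <- build_pyramid(gen$study$train_pairs[[1]]$image)
  nodes <- stack_forward(gen$study$train_pairs[[1]]$fmri, dec$gnn)
  pe <- decode_nodes(neirecon:::flatten_nodes(nodes), dec$dec)
  expect_lt(loss_i_mae(pe[["112"]], pyr_r[["112"]]), 0.05)
})

test_that("reconstructions sit closer to their own stimuli than to others", {
  gen <- generate_study(synthetic_spec(
    n_train = 48, n_test = 6, n_repeats = 2, n_unlabeled = 0,
    roi_voxel_counts = c(6, 9, 5, 7), roi_names = paste0("ROI", 1:4),
    snr = Inf, latent_dim = 3, seed = 52))
  st <- gen$study
  cfg <- train_config(stage = 2, epochs = 3, batch_size = 1, lr = 1e-3,
                      seed = 10, ssl = FALSE, channels = 8, groups = 4,
                      roi_subset = st$metadata$roi_names)
  dec <- train_decoder(st, NULL, cfg)
  rec <- reconstruct(st, dec)
  matched <- mean(mapply(function(r, g) mean((r - g)^2), rec,
                         st$test_stimuli))
  shuffled <- mean(sapply(1:5, function(k)
    mean(mapply(function(r, g) mean((r - g)^2), rec,
                st$test_stimuli[c((1 + k):6, seq_len(k))]))))
  expect_lt(matched, shuffled)
})

test_that("checkpoints round-trip trained models", {
  gen <- tiny_study(n_train = 4, seed = 45)
  cfg <- train_config(stage = 2, epochs = 1, batch_size = 2, lr = 3e-4,
                      seed = 10, ssl = FALSE, channels = 16, groups = 4,
                      roi_subset = gen$study$metadata$roi_names)
  dec <- train_decoder(gen$study, NULL, cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(dec, path)
  back <- load_checkpoint(path)
  expect_identical(back$dec$linear$W, dec$dec$linear$W)
  expect_identical(reconstruct(gen$study, back), reconstruct(gen$study, dec))
  expect_error(load_checkpoint(tempfile()), "not found")
})
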