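test_that("single trials pass and fail as the tie-inclusive rule dictates", {
  gt <- random_image(16, seed = 1)
  d1 <- random_image(16, seed = 2)
  d2 <- random_image(16, seed = 3)
  # recon identical to the target passes under both backends
  expect_true(n_way_trial(gt, gt, list(d1, d2), "mse"))
  expect_true(n_way_trial(gt, gt, list(d1, d2), "ssim"))
  # recon identical to a distractor and far from the target fails under MSE
  expect_false(n_way_trial(d1, gt, list(d1), "mse"))
  expect_error(n_way_trial(gt, gt, list(), "mse"), "distractor")
})

test_that("trials match exhaustive hand computation on tiny candidates", {
  # 2 x 2 single-channel images, MSE by hand
  r <- array(c(0.1, 0.2, 0.3, 0.4), c(2, 2, 1))
  g1 <- array(c(0.1, 0.2, 0.3, 0.5), c(2, 2, 1))  # mse = 0.01/4
  g2 <- array(c(0.5, 0.5, 0.5, 0.5), c(2, 2, 1))  # mse = (0.16+0.09+0.04+0.01)/4
  expect_equal(image_similarity(r, g1, "mse"), 0.0025)
  expect_equal(image_similarity(r, g2, "mse"), 0.075)
  expect_true(n_way_trial(r, g1, list(g2), "mse"))
  expect_false(n_way_trial(r, g2, list(g1), "mse"))
  # 12 x 12 images for the SSIM backend, checked against the loop reference
  a <- random_image(12, seed = 4)
  b <- random_image(12, seed = 5)
  cands <- list(a, b, 0.5 * a + 0.5 * b)
  sims <- vapply(cands, function(g) ssim(a, g), numeric(1))
  refs <- vapply(cands, function(g) ref_ssim(a, g), numeric(1))
  expect_equal(sims, refs, tolerance = 1e-6)
  expect_equal(n_way_trial(a, cands[[1]], cands[2:3], "ssim"),
               sims[1] >= max(sims[2:3]))
})

test_that("ssim matches the windowed reference implementation", {
  for (seed in 1:5) {
    x <- random_image(16, seed = seed)
    y <- if (seed %% 2) random_image(16, seed = seed + 100)
         else pmin(x + 0.1, 1)
    expect_equal(ssim(x, y), ref_ssim(x, y), tolerance = 1e-6)
  }
  x <- random_image(16, seed = 9)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_error(ssim(random_image(8), random_image(8)), "at least 11")
})

test_that("perfect reconstructions give 100 percent for every n", {
  gts <- lapply(1:12, function(i) random_image(28, seed = i))
  for (n in c(2, 5, 10)) for (sim in c("mse", "ssim")) {
    cfg <- n_way_config(n = n, repetitions = 3, similarity = sim, seed = 1)
    expect_equal(n_way_accuracy(gts, gts, cfg), 100)
  }
})

test_that("accuracy is seeded-deterministic and validates inputs", {
  recons <- lapply(1:8, function(i) random_image(16, seed = i))
  gts <- lapply(1:8, function(i) random_image(16, seed = i + 50))
  cfg <- n_way_config(n = 5, repetitions = 4, similarity = "mse", seed = 7)
  expect_identical(n_way_accuracy(recons, gts, cfg),
                   n_way_accuracy(recons, gts, cfg))
  expect_error(n_way_accuracy(recons[1:3], gts, cfg), "lengths differ")
  expect_error(n_way_accuracy(recons[1:3], gts[1:3], cfg), "at least n")
})

test_that("image metrics cover self-similarity and constant offsets", {
  imgs <- lapply(1:4, function(i) random_image(16, seed = i))
  m <- image_metrics(imgs, imgs, embedder = function(im) as.vector(im))
  expect_equal(m$raw_mse, 0)
  expect_equal(m$raw_ssim, 1, tolerance = 1e-12)
  expect_equal(m$embed_distance, 0, tolerance = 1e-6)

  pair <- image_metrics(list(array(0.2, c(16, 16, 3))),
                        list(array(0.3, c(16, 16, 3))))
  expect_equal(pair$raw_mse, 0.01, tolerance = 1e-12)
  # embedder omitted -> metric omitted
  expect_null(image_metrics(imgs, imgs)$embed_distance)
})

test_that("evaluation is side-effect free on the global RNG stream", {
  recons <- lapply(1:6, function(i) random_image(16, seed = i))
  gts <- lapply(1:6, function(i) random_image(16, seed = i + 50))
  cfg <- n_way_config(n = 3, repetitions = 4, similarity = "mse", seed = 3)
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(n_way_accuracy(recons, gts, cfg)); after <- rnorm(3)
  expect_identical(before, after)
})
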