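test_that("align_rois pads to the maximum length and preserves prefixes", {
  set.seed(1)
  v <- list(a = rnorm(3), b = rnorm(5))
  s <- align_rois(v)
  expect_equal(s$D, 5)
  expect_equal(s$vectors[1, 1:3], v$a)
  expect_equal(s$vectors[1, 4:5], c(0, 0))
  expect_equal(s$vectors[2, ], v$b)
  expect_equal(rowSums(s$masks), c(3, 5), ignore_attr = TRUE)
  # zero padding is inert: aligned dot product equals the prefix overlap
  direct <- sum(v$a[1:3] * v$b[1:3])
  expect_equal(sum(s$vectors[1, ] * s$vectors[2, ]), direct)

  eq <- align_rois(list(rnorm(5), rnorm(5)))
  expect_equal(eq$D, 5)
  expect_true(all(eq$masks == 1))
})

test_that("align_rois is idempotent and rejects bad input", {
  s <- random_roi_set(3, c(4, 6, 5), seed = 2)
  expect_identical(align_rois(s), s)
  expect_error(align_rois(list()), "non-empty")
  expect_error(align_rois(list(rnorm(3))), "at least 2")
  expect_error(align_rois(list(rnorm(3), numeric(0))), "empty ROI vector")
})

test_that("padding stays inert for dot products across random sets", {
  for (seed in 1:20) {
    set.seed(seed)
    lens <- sample(2:9, 5, replace = TRUE)
    raw <- lapply(lens, rnorm)
    s <- align_rois(raw)
    i <- sample(5, 1); j <- sample(5, 1)
    ov <- min(lens[i], lens[j])
    expect_equal(sum(s$vectors[i, ] * s$vectors[j, ]),
                 sum(raw[[i]][1:ov] * raw[[j]][1:ov]))
  }
})

test_that("average_repeats matches a direct loop mean", {
  s1 <- random_roi_set(3, c(4, 6, 5), seed = 3)
  expect_equal(average_repeats(list(s1))$vectors, s1$vectors)

  neg <- roi_signal_set(-s1$vectors, s1$masks, s1$voxel_counts, s1$roi_names)
  expect_true(all(average_repeats(list(s1, neg))$vectors == 0))

  set.seed(4)
  reps <- lapply(1:35, function(i) {
    v <- s1$vectors * 0
    v[s1$masks == 1] <- rnorm(sum(s1$masks))
    roi_signal_set(v, s1$masks, s1$voxel_counts, s1$roi_names)
  })
  acc <- 0
  for (r in reps) acc <- acc + r$vectors
  expect_equal(average_repeats(reps)$vectors, acc / 35, tolerance = 1e-12)
  expect_error(average_repeats(list()), "non-empty")
})

test_that("build_pyramid produces the four scales with cubic downsampling", {
  gray <- array(0.5, c(112, 112, 3))
  p <- build_pyramid(gray)
  for (s in c("14", "28", "56", "112"))
    expect_equal(p[[s]], array(0.5, c(as.integer(s), as.integer(s), 3)))

  img <- random_image(seed = 5)
  p <- build_pyramid(img)
  expect_identical(p[["112"]], img)
  validate_pyramid(p)
  expect_error(build_pyramid(random_image(56)), "112")
})

test_that("cubic downsampling matches an independent per-pixel reference", {
  ramp1 <- matrix(rep(seq(0, 1, length.out = 112), each = 112), 112, 112)
  img <- array(c(ramp1, ramp1, ramp1), c(112, 112, 3))
  p <- build_pyramid(img)
  for (s in c(14, 28, 56)) {
    ref <- pmin(pmax(ref_resize_cubic(img, s), 0), 1)
    expect_lt(max(abs(p[[as.character(s)]] - ref)), 1e-6)
  }
  # and on a non-trivial smooth image
  set.seed(6)
  sm <- plogis(resize_cubic(array(rnorm(8 * 8 * 3), c(8, 8, 3)), 112))
  expect_lt(max(abs(resize_cubic(sm, 28) - ref_resize_cubic(sm, 28))), 1e-6)
})

test_that("study containers round-trip exactly and reject malformed files", {
  gen <- tiny_study(n_train = 3, n_test = 2, seed = 7)
  study <- gen$study
  path <- tempfile(fileext = ".rds")
  write_study(study, path)
  back <- read_study(path)
  expect_identical(back$train_pairs, study$train_pairs)
  expect_identical(back$test_repeats, study$test_repeats)
  expect_identical(back$metadata, study$metadata)

  # a test stimulus with zero repeats is a format error
  bad <- readRDS(path)
  bad$test_repeats[[1]] <- list()
  p2 <- tempfile(fileext = ".rds"); saveRDS(bad, p2)
  expect_error(read_study(p2), "repeats")

  # mask / voxel_count mismatch is a format error
  bad <- readRDS(path)
  bad$train_pairs[[1]]$fmri$masks[1, 1] <- 0
  p3 <- tempfile(fileext = ".rds"); saveRDS(bad, p3)
  expect_error(read_study(p3), "mask|voxel")

  # missing split is a format error naming the field
  bad <- readRDS(path)
  bad$train_pairs <- NULL
  p4 <- tempfile(fileext = ".rds"); saveRDS(bad, p4)
  expect_error(read_study(p4), "train_pairs")
})

test_that("ROI subsetting re-aligns and keeps recordings consistent", {
  gen <- tiny_study(seed = 8)
  sub <- subset_rois(gen$study, c("ROI2", "ROI4"))
  expect_equal(sub$metadata$roi_names, c("ROI2", "ROI4"))
  expect_equal(max(sub$metadata$voxel_counts), sub$train_pairs[[1]]$fmri$D)
  full <- gen$study$train_pairs[[1]]$fmri
  expect_equal(sub$train_pairs[[1]]$fmri$vectors[1, 1:9], full$vectors[2, 1:9])
  expect_error(subset_rois(gen$study, c("ROI1", "nope")), "unknown ROI")
})
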