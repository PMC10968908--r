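test_that("fMRI losses hit their closed-form values", {
  s <- random_roi_set(3, c(4, 6, 5), seed = 1)
  expect_equal(loss_f_mse(s, s), 0)
  v <- neirecon:::flatten_nodes(s)
  expect_equal(loss_f_mse(v, v + 0.3), 0.09)
  expect_equal(loss_f_cossim(v, v), -1, tolerance = 1e-6)
  expect_equal(loss_f_cossim(v, -v), 1, tolerance = 1e-6)

  set.seed(2)
  a <- rnorm(100); b <- rnorm(100)
  ref_mse <- 0
  for (i in 1:100) ref_mse <- ref_mse + (a[i] - b[i])^2
  expect_equal(loss_f_mse(a, b), ref_mse / 100, tolerance = 1e-12)
  ref_cos <- -sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)) + 1e-8)
  expect_equal(loss_f_cossim(a, b), ref_cos, tolerance = 1e-10)
})

test_that("encoder loss is the weighted sum of its two terms", {
  set.seed(3)
  a <- rnorm(60); b <- rnorm(60)
  expect_equal(encoder_loss(a, b), loss_f_mse(a, b) + loss_f_cossim(a, b))
  expect_equal(encoder_loss(a, a), -1, tolerance = 1e-6)
  cfg <- loss_config(term_weights = c(mse = 2, cossim = 0))
  expect_equal(encoder_loss(a, b, cfg), 2 * loss_f_mse(a, b))
})

test_that("image MAE and TV match definitions and loop references", {
  im <- random_image(14, seed = 4)
  expect_equal(loss_i_mae(im, im), 0)
  expect_equal(loss_i_mae(im, pmin(im + 0.25, 1.25)), 0.25)
  im2 <- random_image(14, seed = 5)
  expect_equal(loss_i_mae(im, im2), mean(abs(im - im2)), tolerance = 1e-12)

  expect_equal(loss_i_tv(array(0.7, c(5, 5, 3))), 0)
  m <- matrix(c(0, 0, 1, 1), 2, 2)     # columns (0,0) and (1,1)
  expect_equal(loss_i_tv(m), 1)
  for (seed in 6:10) {
    img <- random_image(7, seed = seed)
    expect_equal(loss_i_tv(img), ref_tv(img), tolerance = 1e-10)
  }
})

test_that("perceptual loss averages per-position feature cosines", {
  img <- random_image(seed = 11)
  cfg <- loss_config()
  expect_equal(loss_i_perceptual(img, img, cfg), -1, tolerance = 1e-8)
  expect_error(loss_i_perceptual(random_image(56), random_image(56), cfg),
               "112")

  # nested-loop reference on another pair
  other <- random_image(seed = 12)
  bb <- cfg$perceptual_backbone
  fe <- backbone_forward(bb, img)$features
  fr <- backbone_forward(bb, other)$features
  ref <- 0
  for (l in 1:4) {
    u <- fe[[l]]; v <- fr[[l]]
    cs <- numeric(nrow(u))
    for (p in seq_len(nrow(u)))
      cs[p] <- sum(u[p, ] * v[p, ]) /
        (sqrt(sum(u[p, ]^2)) * sqrt(sum(v[p, ]^2)) + 1e-8)
    ref <- ref - mean(cs) / 4
  }
  expect_equal(loss_i_perceptual(img, other, cfg), ref, tolerance = 1e-8)
})

test_that("the decoder branch loss composes terms over constrained scales", {
  img <- random_image(seed = 13)
  pyr <- build_pyramid(img)
  cfg <- loss_config()
  # identical constant pyramids: MAE 0, TV 0, perceptual -1
  const <- build_pyramid(array(0.4, c(112, 112, 3)))
  expect_equal(decoder_loss(const, const, cfg), -1, tolerance = 1e-6)

  other <- build_pyramid(random_image(seed = 14))
  w <- cfg$term_weights
  ref <- w[["per"]] * loss_i_perceptual(pyr[["112"]], other[["112"]], cfg)
  for (s in c("14", "28", "56", "112"))
    ref <- ref + w[["mae"]] * loss_i_mae(pyr[[s]], other[[s]]) +
      w[["tv"]] * loss_i_tv(pyr[[s]])
  expect_equal(decoder_loss(pyr, other, cfg), ref, tolerance = 1e-10)

  # removing scale 28 removes exactly that scale's MAE + TV terms
  cfg28 <- loss_config(scales_constrained = c(14, 56, 112))
  expect_equal(decoder_loss(pyr, other, cfg28),
               ref - w[["mae"]] * loss_i_mae(pyr[["28"]], other[["28"]]) -
                 w[["tv"]] * loss_i_tv(pyr[["28"]]), tolerance = 1e-10)
})

test_that("loss gradients agree with finite differences", {
  set.seed(15)
  a <- rnorm(40); b <- rnorm(40)
  eps <- 1e-6
  for (fn in list(loss_f_mse, loss_f_cossim)) {
    g <- fn(a, b, grad = TRUE)
    for (i in c(3, 17)) {
      ap <- a; ap[i] <- ap[i] + eps; am <- a; am[i] <- am[i] - eps
      expect_equal(g$grad[i], (fn(ap, b) - fn(am, b)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
  im <- random_image(8, seed = 16); im2 <- random_image(8, seed = 17)
  g <- loss_i_tv(im, grad = TRUE)
  for (i in c(5, 100)) {
    ip <- im; ip[i] <- ip[i] + eps; im_ <- im; im_[i] <- im_[i] - eps
    expect_equal(g$grad[i], (loss_i_tv(ip) - loss_i_tv(im_)) / (2 * eps),
                 tolerance = 1e-4)
  }
  g <- loss_i_mae(im, im2, grad = TRUE)
  expect_equal(g$grad, sign(im - im2) / length(im), ignore_attr = TRUE)

  big <- random_image(seed = 18); big2 <- random_image(seed = 19)
  cfg <- loss_config()
  g <- loss_i_perceptual(big, big2, cfg, grad = TRUE)
  for (i in c(2000, 30011)) {
    ip <- big; ip[i] <- ip[i] + 1e-5; im_ <- big; im_[i] <- im_[i] - 1e-5
    num <- (loss_i_perceptual(ip, big2, cfg) -
              loss_i_perceptual(im_, big2, cfg)) / 2e-5
    expect_equal(g$grad[i], num, tolerance = 1e-3)
  }
})

test_that("losses are bounded as expected", {
  set.seed(20)
  for (trial in 1:5) {
    a <- rnorm(30); b <- rnorm(30)
    expect_gte(encoder_loss(a, b), -1)
    expect_gte(loss_f_mse(a, b), 0)
    expect_true(abs(loss_f_cossim(a, b)) <= 1 + 1e-12)
  }
  p1 <- build_pyramid(random_image(seed = 21))
  p2 <- build_pyramid(random_image(seed = 22))
  expect_gte(decoder_loss(p1, p2), -1)
})
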