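test_that("screening maps follow the windowed-variance saliency rule", {
  set.seed(51)
  # textured structural vs constant companion -> map1 everywhere 1
  m <- rand_img(16); i <- matrix(0.4, 16, 16)
  sm <- screening_maps(m, i, 7)
  expect_true(all(sm$map1 == 1))
  expect_true(all(sm$map2 == 0))
  # identical inputs tie -> both 0.5
  sm2 <- screening_maps(m, m, 7)
  expect_true(all(sm2$map1 == 0.5))
  # complement invariant
  m2 <- rand_img(16); i2 <- rand_img(16)
  sm3 <- screening_maps(m2, i2, 5)
  expect_true(all(sm3$map1 + sm3$map2 == 1))
  # constant fallback mode
  smc <- screening_maps(m2, i2, constant = TRUE)
  expect_true(all(smc$map1 == 0.5))
})

test_that("screening maps match a per-pixel windowed-variance oracle", {
  set.seed(52)
  m <- rand_img(12); i <- rand_img(12)
  sm <- screening_maps(m, i, 5)
  for (r in seq(1, 12, by = 3)) for (cc in seq(1, 12, by = 3)) {
    vm <- oracle_window_variance(m, r, cc, 5)
    vi <- oracle_window_variance(i, r, cc, 5)
    want <- if (vm > vi) 1 else if (vm < vi) 0 else 0.5
    expect_equal(sm$map1[r, cc], want, tolerance = 1e-9)
  }
})

test_that("adversarial and discriminator losses reproduce hand arithmetic", {
  lb <- adversarial_labels()
  expect_equal(adversarial_loss(rep(1, 4), lb), 0)
  expect_equal(adversarial_loss(rep(0, 4), lb), 1)
  expect_equal(adversarial_loss(c(0.5, 0.5), lb), 0.25)
  expect_error(adversarial_loss(numeric(0), lb), "empty")

  expect_equal(discriminator_loss(c(0, 0), c(1, 1), lb), 0)
  expect_equal(discriminator_loss(rep(0.5, 3), rep(0.5, 3), lb), 0.5)
  expect_equal(discriminator_loss(1, 0, lb), 2)
  expect_error(discriminator_loss(c(0.1), c(0.2, 0.3), lb), "equal length")
  expect_error(adversarial_labels(a = 1, b = 0), "a < b")
})

test_that("pixel loss attains its documented minimizers and arithmetic", {
  set.seed(53)
  m <- rand_img(8); i <- rand_img(8)
  one <- list(map1 = matrix(1, 8, 8), map2 = matrix(0, 8, 8))
  expect_equal(pixel_loss(m, m, i, one), 0)
  swap <- list(map1 = matrix(0, 8, 8), map2 = matrix(1, 8, 8))
  expect_equal(pixel_loss(i, m, i, swap), 0)
  half <- list(map1 = matrix(0.5, 1, 1), map2 = matrix(0.5, 1, 1))
  expect_equal(pixel_loss(matrix(0.5), matrix(0), matrix(1), half), 0.25)
})

test_that("gradient loss vanishes where documented and matches a pixel loop", {
  set.seed(54)
  m <- rand_img(10); y <- rand_img(10)
  one <- list(map1 = matrix(1, 10, 10), map2 = matrix(0, 10, 10))
  expect_equal(gradient_loss(m, m, y, one), 0)
  cm <- matrix(0.3, 10, 10)
  half <- list(map1 = matrix(0.5, 10, 10), map2 = matrix(0.5, 10, 10))
  expect_equal(gradient_loss(cm, cm * 0 + 0.9, cm * 0 + 0.1, half), 0)

  f <- rand_img(10)
  maps <- screening_maps(m, y, 5)
  lf <- oracle_laplacian(f); lm <- oracle_laplacian(m)
  ly <- oracle_laplacian(y)
  ref <- mean(maps$map1 * (lf - lm)^2 + maps$map2 * (lf - ly)^2)
  expect_equal(gradient_loss(f, m, y, maps), ref, tolerance = 1e-12)
})

test_that("losses are symmetric under source and map swap", {
  set.seed(55)
  m <- rand_img(9); i <- rand_img(9); f <- rand_img(9)
  maps <- screening_maps(m, i, 3)
  swapped <- list(map1 = maps$map2, map2 = maps$map1)
  expect_equal(pixel_loss(f, m, i, maps), pixel_loss(f, i, m, swapped),
               tolerance = 1e-14)
  expect_equal(gradient_loss(f, m, i, maps),
               gradient_loss(f, i, m, swapped), tolerance = 1e-14)
})

test_that("total generator loss is affine in its components", {
  expect_equal(generator_total(0.1, 0.2, 0.3, loss_weights(1, 1)), 0.6)
  expect_equal(generator_total(0.7, 5, 9, loss_weights(0, 0)), 0.7)
  w <- loss_weights(2, 1)
  d <- generator_total(0.1, 0.2, 0.3, w) -
    generator_total(0.1, 0, 0.3, w)
  expect_equal(d, 2 * 0.2)
})

test_that("weight calibration equalizes component magnitudes", {
  w <- calibrate_loss_weights(0.5, 0.1, 2)
  expect_equal(w$lambda1 * 0.1, 0.5)
  expect_equal(w$lambda2 * 2, 0.5)
  expect_equal(calibrate_loss_weights(0.5, 0, 0)$lambda1, 1)
})

test_that("graph-side losses agree with the numeric loss API", {
  ns <- asNamespace("fusegan")
  set.seed(56)
  gcfg <- generator_config(base_channels = 4)
  gen <- generator_new(gcfg)
  disc <- discriminator_new(discriminator_config(c(4L, 4L)))
  m <- rand_img(16); y <- rand_img(16)
  maps <- screening_maps(m, y, 7)
  pr <- list(m = m, y = y, maps = maps,
             lap_m = unclass(laplacian(m)), lap_y = unclass(laplacian(y)))
  tc <- train_config(gen = gcfg, disc = discriminator_config(c(4L, 4L)))
  ns$ag_tape_reset(FALSE)
  gs <- ns$gen_sample_graph(gen, disc, pr, tc, ns$laplacian_kernel(4L))
  fused <- generator_forward(gen, m, y)
  score <- discriminator_forward(disc, fused_gradient(fused))
  expect_equal(gs$lgan, adversarial_loss(score), tolerance = 1e-10)
  expect_equal(gs$lpix, pixel_loss(fused, m, y, maps), tolerance = 1e-10)
  expect_equal(gs$lgrad, gradient_loss(fused, m, y, maps),
               tolerance = 1e-10)
})
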