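ns <- asNamespace("fusegan")

small_gen <- function(seed = 41, ...) {
  set.seed(seed)
  generator_new(generator_config(base_channels = 4), ...)
}

test_that("generator preserves spatial size, emits [0,1], and is deterministic", {
  gen <- small_gen()
  set.seed(42)
  m <- rand_img(20, 24); y <- rand_img(20, 24)
  f1 <- generator_forward(gen, m, y)
  expect_identical(dim(f1), c(20L, 24L))
  expect_true(all(f1 >= 0 & f1 <= 1))
  f2 <- generator_forward(gen, m, y)
  expect_identical(unclass(f1), unclass(f2))
  expect_error(generator_forward(gen, m, rand_img(10)), "height and width")
})

test_that("the two branches carry independent weights", {
  gen <- small_gen()
  set.seed(43)
  m <- rand_img(16); y <- rand_img(16)
  fa <- generator_forward(gen, m, y)
  fb <- generator_forward(gen, y, m)
  expect_gt(max(abs(unclass(fa) - unclass(fb))), 1e-6)
})

test_that("bpdb preserves shape and collapses to zero with zero weights", {
  set.seed(44)
  bp <- ns$bpdb_new(4L)
  x <- array(rnorm(4 * 10 * 12), c(4, 10, 12))
  out <- bpdb_forward(bp, x)
  expect_identical(dim(out), dim(x))
  expect_true(all(is.finite(out)))
  for (l in unname(bp)) { l$W[] <- 0; l$b[] <- 0 }
  expect_true(all(bpdb_forward(bp, x) == 0))
  expect_error(bpdb_forward(bp, array(0, c(3, 8, 8))), "channels")
})

test_that("cbam preserves shape, gates multiplicatively, and bounds with sigmoid", {
  set.seed(45)
  cb <- ns$cbam_new(4L, gate = "sigmoid")
  x <- array(rnorm(4 * 9 * 9), c(4, 9, 9))
  x[2, , ] <- 0
  out <- cbam_forward(cb, x)
  expect_identical(dim(out), dim(x))
  expect_true(all(abs(out) <= abs(x) + 1e-12))   # gates in (0,1)
  expect_true(all(out[2, , ] == 0))              # zero channel stays zero

  cb_elu <- ns$cbam_new(4L, gate = "ELU")
  out2 <- cbam_forward(cb_elu, x)
  expect_identical(dim(out2), dim(x))
  expect_true(all(is.finite(out2)))
  expect_error(ns$cbam_new(1L), "at least 2")
})

test_that("discriminator emits a deterministic probability and batches consistently", {
  set.seed(46)
  disc <- discriminator_new(discriminator_config(c(4L, 8L)))
  maps <- lapply(1:4, function(i) unclass(fused_gradient(rand_img(16))))
  p1 <- vapply(maps, function(g) discriminator_forward(disc, g), numeric(1))
  expect_true(all(p1 >= 0 & p1 <= 1))
  p2 <- vapply(maps, function(g) discriminator_forward(disc, g), numeric(1))
  expect_identical(p1, p2)
  expect_error(discriminator_forward(disc, matrix(c(Inf, rep(0, 255)), 16)),
               "non-finite")
})

test_that("parameter counts equal the closed-form count for a small config", {
  gen <- small_gen()
  # per branch: ext 40+148; bpdb 7x148; cbam 5+8+3  -> 1240
  # composite bpdb at 8 channels: 7x584; cbam 9+16+3; head 292+37
  expect_identical(n_params(gen), 2L * 1240L + 4088L + 28L + 292L + 37L)
  disc <- discriminator_new(discriminator_config(c(4L, 4L)))
  expect_identical(n_params(disc), 40L + 148L + 5L)
})

test_that("total-loss gradients are finite for every generator parameter", {
  set.seed(47)
  gcfg <- generator_config(base_channels = 4)
  gen <- generator_new(gcfg)
  disc <- discriminator_new(discriminator_config(c(4L, 4L)))
  tc <- train_config(gen = gcfg, disc = discriminator_config(c(4L, 4L)))
  kern <- ns$laplacian_kernel(4L)
  gl <- ns$generator_layers(gen)
  ns$zero_grads(gl)
  for (s in 1:2) {
    m <- rand_img(16); y <- rand_img(16)
    pr <- list(m = m, y = y, maps = screening_maps(m, y, 3),
               lap_m = unclass(laplacian(m)),
               lap_y = unclass(laplacian(y)))
    ns$ag_tape_reset(TRUE)
    gs <- ns$gen_sample_graph(gen, disc, pr, tc, kern)
    ns$ag_backward(gs$total, seed = 0.5)
  }
  for (l in gl) {
    expect_false(is.null(l$gW))
    expect_true(all(is.finite(l$gW)), label = "finite weight gradients")
    expect_true(all(is.finite(l$gb)), label = "finite bias gradients")
  }
})

test_that("ablation flags skip blocks without changing shapes", {
  gen0 <- small_gen(ablation = list(use_bpdb = FALSE, use_cbam = FALSE))
  set.seed(48)
  m <- rand_img(16); y <- rand_img(16)
  f <- generator_forward(gen0, m, y)
  expect_identical(dim(f), dim(m))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("config validation rejects degenerate settings", {
  expect_error(generator_config(base_channels = 2), ">= 4")
  expect_error(generator_config(conv_kernel = 4), "odd")
  expect_error(discriminator_config(integer(0)), "empty")
})
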