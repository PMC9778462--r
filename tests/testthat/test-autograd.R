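# The compiled conv kernels and the tape are the load-bearing machinery of
# the whole package, so they get a dual check: compiled vs pure-R lowering,
# and analytic vs finite-difference gradients through the full graph.

ns <- asNamespace("fusegan")

test_that("compiled convolution matches the pure-R im2col lowering", {
  set.seed(31)
  cases <- expand.grid(C = c(1L, 3L), Cout = c(1L, 4L), k = c(1L, 3L),
                       stride = c(1L, 2L))
  for (r in seq_len(nrow(cases))) {
    cs <- cases[r, ]
    if (cs$k == 1L && cs$stride == 2L) next
    x <- array(rnorm(cs$C * 12 * 10), c(cs$C, 12, 10))
    W <- matrix(rnorm(cs$Cout * cs$C * cs$k^2), cs$Cout)
    b <- rnorm(cs$Cout)
    pad <- (cs$k - 1L) %/% 2L
    y_cpp <- ns$cpp_conv_fwd(x, W, b, cs$k, cs$stride, pad)
    y_r <- ns$r_conv_fwd(x, W, b, cs$k, cs$stride, pad)
    expect_equal(dim(y_cpp), dim(y_r))
    expect_equal(as.vector(y_cpp), as.vector(y_r), tolerance = 1e-12)
  }
})

test_that("conv backward agrees with finite differences for weights and input", {
  set.seed(32)
  x <- array(rnorm(2 * 7 * 6), c(2, 7, 6))
  W <- matrix(rnorm(3 * 2 * 9), 3)
  b <- rnorm(3)
  dy <- array(rnorm(3 * 7 * 6), c(3, 7, 6))
  bwd <- ns$cpp_conv_bwd(x, W, dy, 3L, 1L, 1L)
  lossf <- function(xx, WW, bb)
    sum(ns$cpp_conv_fwd(xx, WW, bb, 3L, 1L, 1L) * dy)
  eps <- 1e-6
  for (ii in sample(length(W), 5)) {
    Wp <- W; Wp[ii] <- W[ii] + eps
    Wm <- W; Wm[ii] <- W[ii] - eps
    expect_equal(bwd$dW[ii], (lossf(x, Wp, b) - lossf(x, Wm, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (ii in sample(length(x), 5)) {
    xp <- x; xp[ii] <- x[ii] + eps
    xm <- x; xm[ii] <- x[ii] - eps
    expect_equal(as.vector(bwd$dx)[ii],
                 (lossf(xp, W, b) - lossf(xm, W, b)) / (2 * eps),
                 tolerance = 1e-5)
  }
  expect_equal(as.vector(bwd$db), apply(dy, 1, sum), tolerance = 1e-10)
})

test_that("analytic gradients of the full generator loss match finite differences", {
  set.seed(33)
  gcfg <- generator_config(base_channels = 4)
  gen <- generator_new(gcfg)
  disc <- discriminator_new(discriminator_config(c(4L, 4L)))
  m <- rand_img(16); y <- rand_img(16)
  pr <- list(m = m, y = y, maps = screening_maps(m, y, 3),
             lap_m = unclass(laplacian(m)), lap_y = unclass(laplacian(y)),
             grad2 = unclass(joint_gradient(m, y)))
  tc <- train_config(gen = gcfg, disc = discriminator_config(c(4L, 4L)))
  kern <- ns$laplacian_kernel(4L)
  lossval <- function() {
    ns$ag_tape_reset(FALSE)
    ns$gen_sample_graph(gen, disc, pr, tc, kern)$total$value
  }
  gl <- ns$generator_layers(gen)
  ns$zero_grads(gl)
  ns$zero_grads(ns$discriminator_layers(disc))
  ns$ag_tape_reset(TRUE)
  gs <- ns$gen_sample_graph(gen, disc, pr, tc, kern)
  ns$ag_backward(gs$total)
  eps <- 1e-5
  for (li in c(1L, 5L, 11L, 14L, 20L, length(gl))) {
    l <- gl[[li]]
    for (ii in sample(length(l$W), 2)) {
      w0 <- l$W[ii]
      l$W[ii] <- w0 + eps; fp <- lossval()
      l$W[ii] <- w0 - eps; fm <- lossval()
      l$W[ii] <- w0
      num <- (fp - fm) / (2 * eps)
      expect_lt(abs(l$gW[ii] - num) /
                  max(1e-6, abs(num) + abs(l$gW[ii])), 1e-4)
    }
  }
})

test_that("adam descends a simple convex objective", {
  set.seed(34)
  l <- ns$fc_layer(3L, 1L)
  opt <- ns$adam_new(list(l), lr = 0.05)
  target <- c(1, -2, 0.5)
  lossq <- function() sum((drop(l$W) - target)^2)
  l0 <- lossq()
  for (i in 1:200) {
    ns$zero_grads(list(l))
    ns$layer_acc(l, matrix(2 * (drop(l$W) - target), 1), 0)
    ns$adam_step(opt)
  }
  expect_lt(lossq(), 0.05 * l0)
})
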