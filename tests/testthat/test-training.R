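# Small-but-real training runs: tiny nets (4 base channels, 2-layer
# discriminator) on 24x24 phantoms keep each run in the hundred-millisecond
# range while exercising the full optimization path.

ns <- asNamespace("fusegan")

tiny_cfg <- function(epochs = 1L, seed = 5L, ...) {
  train_config(batch_size = 2L, epochs = epochs, seed = seed,
               gen = generator_config(base_channels = 4),
               disc = discriminator_config(c(4L, 4L)), ...)
}

test_that("split_dataset gives the 7:2:1 partition and is reproducible", {
  recs <- as.list(1:10)
  parts <- split_dataset(recs, c(0.7, 0.2, 0.1), seed = 2)
  expect_length(parts$train, 7)
  expect_length(parts$val, 2)
  expect_length(parts$test, 1)
  all_items <- c(unlist(parts$train), unlist(parts$val),
                 unlist(parts$test))
  expect_setequal(all_items, 1:10)
  expect_length(all_items, 10)
  parts2 <- split_dataset(recs, c(0.7, 0.2, 0.1), seed = 2)
  expect_identical(parts, parts2)
  expect_error(split_dataset(as.list(1:2), c(0.7, 0.2, 0.1)),
               "fewer records")
  expect_error(split_dataset(recs, c(0.5, 0.2)), "sum to 1")
})

test_that("a short run finishes with finite logged losses and exact update ratio", {
  recs <- make_records(4, size = 24, seed0 = 1)
  ck <- train(tiny_cfg(epochs = 2L), recs)
  expect_s3_class(ck, "fg_checkpoint")
  expect_true(all(is.finite(as.matrix(ck$log[, -1]))))
  expect_named(ck$log, c("step", "epoch", "l_gan", "l_pixel", "l_grad",
                         "l_total", "l_d"))
  expect_identical(unname(ck$counters["disc_updates"]),
                   2L * unname(ck$counters["gen_updates"]))
})

test_that("a fixed seed reproduces final weights bit for bit", {
  ns <- asNamespace("fusegan")
  recs <- make_records(4, size = 24, seed0 = 11)
  ck1 <- train(tiny_cfg(seed = 77L), recs)
  ck2 <- train(tiny_cfg(seed = 77L), recs)
  w1 <- ns$net_export(ns$generator_layers(ck1$generator))
  w2 <- ns$net_export(ns$generator_layers(ck2$generator))
  expect_identical(w1, w2)
  ck3 <- train(tiny_cfg(seed = 78L), recs)
  w3 <- ns$net_export(ns$generator_layers(ck3$generator))
  expect_false(identical(w1, w3))
})

test_that("fuse_pair routes color companions through YCbCr with exact chroma", {
  recs <- make_records(2, size = 24, seed0 = 21)
  ck <- train(tiny_cfg(), recs)
  out <- fuse_pair(ck, recs[[1]]$structural, recs[[1]]$companion)
  expect_s3_class(out, "color_image")
  chroma_in <- rgb_to_ycbcr(recs[[1]]$companion)
  chroma_out <- rgb_to_ycbcr(out)
  # chroma is untouched wherever the recombined pixel stays in gamut
  fy <- generator_forward(ck$generator, recs[[1]]$structural, chroma_in$y)
  raw <- cbind(as.vector(unclass(fy)), as.vector(chroma_in$cb) - 0.5,
               as.vector(chroma_in$cr) - 0.5) %*% t(ns$.ycbcr_inv)
  ok <- rowSums(raw < -1e-9 | raw > 1 + 1e-9) == 0
  expect_gt(mean(ok), 0.5)
  expect_lt(max(abs((chroma_out$cb - chroma_in$cb)[ok])), 1e-5)
  expect_lt(max(abs((chroma_out$cr - chroma_in$cr)[ok])), 1e-5)

  ct <- rgb_to_ycbcr(recs[[2]]$companion)$y
  outg <- fuse_pair(ck, recs[[2]]$structural, ct)
  expect_s3_class(outg, "gray_image")
  expect_true(all(outg >= 0 & outg <= 1))
  outg2 <- fuse_pair(ck, recs[[2]]$structural, ct)
  expect_identical(unclass(outg), unclass(outg2))
})

test_that("checkpoints survive a save/load round trip", {
  recs <- make_records(2, size = 24, seed0 = 31)
  ck <- train(tiny_cfg(), recs)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  f1 <- fuse_pair(ck, recs[[1]]$structural, recs[[1]]$companion)
  f2 <- fuse_pair(ck2, recs[[1]]$structural, recs[[1]]$companion)
  expect_identical(unclass(f1), unclass(f2))
  expect_identical(ck2$counters, ck$counters)
})

test_that("weight calibration on the first batch equalizes loss components", {
  recs <- make_records(2, size = 24, seed0 = 41)
  ck <- train(tiny_cfg(calibrate_weights = TRUE), recs)
  first <- ck$log[1, ]
  expect_equal(unname(ck$cfg$weights$lambda1) * first$l_pixel, first$l_gan,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(ck$cfg$weights$lambda2) * first$l_grad, first$l_gan,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the ablation harness emits one full metric row per configuration", {
  recs_tr <- make_records(2, size = 24, seed0 = 51)
  recs_te <- make_records(1, size = 24, seed0 = 61)
  grid <- data.frame(label = c("a", "b"), use_bpdb = c(FALSE, TRUE))
  tab <- run_ablation(tiny_cfg(), recs_tr, recs_te, grid = grid)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("ag", "ei", "q_abf", "q_cv") %in% names(tab)))
  expect_true(all(is.finite(as.matrix(tab[, c("ag", "ei", "q_abf",
                                              "q_cv")]))))
})

test_that("empty training sets are rejected", {
  expect_error(train(tiny_cfg(), list()), "empty")
})
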