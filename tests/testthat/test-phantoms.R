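test_that("phantom generation is deterministic per seed", {
  sp <- phantom_spec(size = c(32, 32), seed = 9)
  expect_identical(unclass(make_structural(sp)), unclass(make_structural(sp)))
  expect_identical(unclass(make_functional(sp)), unclass(make_functional(sp)))
  sp2 <- phantom_spec(size = c(32, 32), seed = 10)
  expect_gt(max(abs(unclass(make_structural(sp)) -
                    unclass(make_structural(sp2)))), 0)
})

test_that("degenerate specs yield constant or black images", {
  spc <- phantom_spec(size = c(24, 24), n_structures = 0, texture_freq = 0,
                      noise_sd = 0, seed = 1)
  s <- make_structural(spc)
  expect_equal(max(s) - min(s), 0)
  spb <- phantom_spec(size = c(24, 24), n_blobs = 0, seed = 1)
  f <- make_functional(spb)
  expect_true(all(unclass(f) == 0))
})

test_that("functional phantoms honor the exact-zero background fraction", {
  for (seed in 1:5) {
    sp <- phantom_spec(size = c(48, 48), background_fraction = 0.6,
                       seed = seed)
    f <- unclass(make_functional(sp))
    zero_px <- sum(f[, , 1] == 0 & f[, , 2] == 0 & f[, , 3] == 0)
    expect_gte(zero_px, 0.6 * 48 * 48)
  }
})

test_that("structural phantoms are sharper than functional luminance", {
  ags <- vapply(1:8, function(seed) {
    sp <- phantom_spec(size = c(48, 48), seed = seed)
    s <- make_structural(sp)
    y <- rgb_to_ycbcr(make_functional(sp))$y
    average_gradient(s) - average_gradient(y)
  }, numeric(1))
  expect_true(all(ags > 0))
})

test_that("the joint gradient of a pair is dominated by the structural member", {
  fr <- vapply(1:5, function(seed) {
    sp <- phantom_spec(seed = seed)   # default 256 x 256 conditions
    m <- unclass(make_structural(sp))
    y <- unclass(rgb_to_ycbcr(make_functional(sp))$y)
    mean(abs(unclass(laplacian(m))) >= abs(unclass(laplacian(y))))
  }, numeric(1))
  expect_true(all(fr >= 0.9))
})

test_that("co-registration places functional activity inside the anatomy", {
  sp <- phantom_spec(size = c(64, 64), seed = 4, noise_sd = 0,
                     texture_freq = 0)
  s <- unclass(make_structural(sp))
  y <- unclass(rgb_to_ycbcr(make_functional(sp))$y)
  active <- y > 0.2
  expect_gt(mean(s[active] > 0), 0.8)
})

test_that("datasets round-trip through disk byte-identically", {
  sp <- phantom_spec(size = c(24, 24), seed = 3)
  d1 <- file.path(tempdir(), "ph1"); d2 <- file.path(tempdir(), "ph2")
  mf <- make_dataset(sp, 3, d1)
  expect_equal(nrow(mf), 3)
  expect_length(list.files(d1, pattern = "\\.png$"), 6)
  make_dataset(sp, 3, d2)
  for (fn in list.files(d1, pattern = "\\.png$")) {
    expect_identical(readBin(file.path(d1, fn), "raw", 1e6),
                     readBin(file.path(d2, fn), "raw", 1e6))
  }
  recs <- load_dataset(d1)
  expect_length(recs, 3)
  expect_s3_class(recs[[1]]$structural, "gray_image")
  expect_s3_class(recs[[1]]$companion, "color_image")
  expect_true(all(unclass(recs[[1]]$structural) >= 0 &
                  unclass(recs[[1]]$structural) <= 1))
  expect_identical(dim(unclass(recs[[1]]$structural)), c(24L, 24L))
})

test_that("spec validation rejects impossible geometries", {
  expect_error(phantom_spec(size = c(8, 64)), ">= 16")
  expect_error(phantom_spec(background_fraction = 1), "background_fraction")
  expect_error(phantom_spec(noise_sd = -1), "negative")
})
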