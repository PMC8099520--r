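test_that("plane packing fills top bit positions and zeros the rest", {
  img <- matrix(255L, 16, 16)
  st <- decompose_bitplanes(img)
  # predicting b7 from b8 alone: only the top bit can be set
  expect_true(all(pack_planes(bitplane_stack(st$planes[1]), 7) == 128L))
  # all-zero planes pack to zero whatever the target
  st0 <- decompose_bitplanes(matrix(0L, 16, 16))
  expect_true(all(pack_planes(bitplane_stack(st0$planes[1:7]), 1) == 0L))
  # top-two-bit packing: b8=1, b7=0 -> 128
  img2 <- matrix(128L, 16, 16)  # bits 10...
  st2 <- decompose_bitplanes(img2)
  expect_true(all(pack_planes(bitplane_stack(st2$planes[1:2]), 6) == 128L))
  # independent bit-arithmetic oracle on a random image
  img3 <- random_gray_image(16, 44)
  st3 <- decompose_bitplanes(img3)
  for (target in c(7L, 4L, 1L)) {
    packed <- pack_planes(bitplane_stack(st3$planes[1:(8 - target)]), target)
    oracle <- (img3 %/% 2^target) * 2^target    # keep bits above the target
    expect_true(all(packed == oracle))
  }
  expect_error(pack_planes(bitplane_stack(st3$planes[1:2]), 4), "missing")
})

test_that("the l1 term matches direct summation", {
  y <- matrix(rnorm(64), 8, 8)
  expect_equal(l1_term(y, y), 0)
  expect_equal(l1_term(matrix(1, 4, 4), matrix(0, 4, 4)), 1)
  g <- matrix(rnorm(64), 8, 8)
  expect_equal(l1_term(y, g), sum(abs(y - g)) / 64)
  expect_error(l1_term(y, matrix(0, 4, 4)), "shape")
})

test_that("the combined objective balances GAN and l1 losses linearly", {
  expect_equal(combined_objective(0.7, 123, lambda_l1 = 0), 0.7)
  expect_equal(combined_objective(0.5, 0.01, lambda_l1 = 1e3), 10.5)
  base <- combined_objective(0.2, 0.3, lambda_l1 = 10)
  doubled <- combined_objective(0.2, 0.3, lambda_l1 = 20)
  expect_equal(doubled - 0.2, 2 * (base - 0.2))
  expect_error(combined_objective(0.1, 0.1, lambda_l1 = -1), "non-negative")
})

test_that("prediction is deterministic and produces a well-formed plane", {
  bank <- tiny_trained_bank()
  img <- generate_phantoms(1, 32, seed = 900)[[1]]
  st <- decompose_bitplanes(img)
  top <- bitplane_stack(st$planes[1:2])
  s1 <- predict_plane(bank, top, 6)
  s2 <- predict_plane(bank, top, 6)
  expect_identical(s1$bits, s2$bits)
  expect_true(all(s1$bits %in% c(0L, 1L)))
  expect_equal(dim(s1$bits), c(32L, 32L))
  expect_equal(s1$layer, 6L)
  expect_error(predict_plane(bank, top, 5), "missing")
  empty <- predictor_bank(list())
  expect_error(predict_plane(empty, top, 6), "no predictor")
})

test_that("an input-independent target stays at the chance floor", {
  bank <- tiny_trained_bank()
  set.seed(1234)
  disagree <- 0; total <- 0
  for (i in 1:2) {
    img <- random_gray_image(256, 5000 + i)
    st <- decompose_bitplanes(img)
    s <- predict_plane(bank, bitplane_stack(st$planes[1]), 7)
    coin <- matrix(rbinom(256^2, 1L, 0.5), 256, 256)  # independent of input
    disagree <- disagree + sum(s$bits != coin)
    total <- total + 256^2
  }
  expect_gte(total, 1e5)
  expect_gt(disagree / total, 0.47)
  expect_lt(disagree / total, 0.53)
})

test_that("a saved bank reloads to bit-identical predictions and metadata", {
  bank <- tiny_trained_bank()
  dir <- withr::local_tempdir()
  save_bank(bank, dir)
  back <- load_bank(dir)
  expect_identical(back$layers, bank$layers)
  img <- generate_phantoms(1, 32, seed = 901)[[1]]
  st <- decompose_bitplanes(img)
  for (layer in c(7L, 4L, 1L)) {
    top <- bitplane_stack(st$planes[1:(8 - layer)])
    expect_identical(predict_plane(back, top, layer)$bits,
                     predict_plane(bank, top, layer)$bits)
  }
  # config metadata survives the round trip
  p0 <- bank$predictors[["5"]]; p1 <- back$predictors[["5"]]
  expect_equal(p1$cfg$epochs, p0$cfg$epochs)
  expect_equal(p1$cfg$learning_rate, p0$cfg$learning_rate)
  expect_equal(p1$cfg$lambda_l1, p0$cfg$lambda_l1)
  expect_identical(p1$fingerprint, p0$fingerprint)

  # version tag is checked
  man <- file.path(dir, "manifest.txt")
  txt <- readLines(man)
  writeLines(sub("^format: .*", "format: pitcodec-bank-99", txt), man)
  expect_error(load_bank(dir), "format version")
  expect_error(load_bank(withr::local_tempdir()), "manifest")
})

test_that("training rejects degenerate inputs", {
  cfg <- train_config(epochs = 1)
  expect_error(train_predictor(list(), 7, cfg), "empty")
  expect_error(train_predictor(list(matrix(0L, 24, 24)), 7, cfg),
               "divisible by 16")
  expect_error(train_config(epochs = 0), "positive")
  expect_error(train_config(lambda_l1 = -2), "non-negative")
})
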