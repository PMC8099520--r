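test_that("phantom corpora are reproducible and in range", {
  a <- generate_phantoms(3, 32, seed = 10)
  b <- generate_phantoms(3, 32, seed = 10)
  expect_identical(a, b)
  c_ <- generate_phantoms(3, 32, seed = 11)
  expect_false(identical(a, c_))
  for (im in a) {
    expect_true(all(im >= 0L & im <= 255L))
    expect_equal(dim(im), c(32L, 32L))
  }
  expect_error(generate_phantoms(2, 24), "divisible by 16")
})

test_that("a structure-free noiseless phantom has constant low planes", {
  im <- generate_phantoms(1, 32, n_arcs = 0, n_blobs = 0, noise_sd = 0,
                          bg_cells = 2, seed = 3)[[1]]
  # background is smooth; force it constant to probe the degenerate case
  im[] <- im[1, 1]
  st <- decompose_bitplanes(im)
  b1 <- pitcodec:::stack_plane(st, 1L)$bits
  expect_equal(length(unique(as.vector(b1))), 1L)
})

test_that("bit-plane busyness increases from the top plane to the bottom", {
  imgs <- generate_phantoms(20, 64, seed = 42)
  busy <- sapply(imgs, function(im) {
    st <- decompose_bitplanes(im)
    vapply(st$planes, function(p) plane_busyness(p$bits), 0)
  })                         # 8 x 20, rows are layers b8..b1
  mean_busy <- rowMeans(busy)
  # strictly busier as the layer drops over the informative range; the
  # lowest planes saturate at the coin-flip ceiling of 0.5 where ordering
  # is within measurement noise, so only demand no real reversal there
  expect_true(all(diff(mean_busy[1:6]) > 0))        # b8 -> b3 strict
  expect_true(all(diff(mean_busy) > -0.005))        # saturated tail
  expect_gt(mean_busy[8], 0.45)                     # b1 is essentially random
  expect_lt(mean_busy[1], 0.1)                      # b8 is smooth
})

test_that("residual generator hits its target rate and its extremes", {
  expect_true(all(generate_residual(32, 0, "iid", seed = 1)$bits == 0L))
  expect_true(all(generate_residual(32, 1, "iid", seed = 1)$bits == 1L))
  expect_true(all(generate_residual(32, 0, "clustered", seed = 1)$bits == 0L))
  expect_error(generate_residual(32, 1.2), "\\[0, 1\\]")

  hits <- 0L
  for (seed in 1:20) {
    er <- error_rate(generate_residual(256, 0.1, "iid", seed = seed))
    hits <- hits + (er >= 9 && er <= 11)
  }
  expect_gte(hits, 19L)

  # clustered mode matches the target in expectation
  ers <- vapply(1:10, function(seed)
    error_rate(generate_residual(128, 0.1, "clustered", seed = seed)), 0)
  expect_gt(mean(ers), 9)
  expect_lt(mean(ers), 11)
})

test_that("clustered residuals compress better than i.i.d. at equal rate", {
  cr_cl <- c(); cr_iid <- c()
  for (seed in 1:8) {
    rc <- generate_residual(128, 0.1, "clustered", seed = seed)
    ri <- generate_residual(128, 0.1, "iid", seed = seed)
    cr_cl <- c(cr_cl, compression_ratio(128, compress_residual(rc, 4)$delta_bits))
    cr_iid <- c(cr_iid, compression_ratio(128, compress_residual(ri, 4)$delta_bits))
  }
  expect_gt(mean(cr_cl), mean(cr_iid))
})

test_that("residuals are reproducible per seed", {
  expect_identical(generate_residual(64, 0.1, "clustered", seed = 4)$bits,
                   generate_residual(64, 0.1, "clustered", seed = 4)$bits)
})
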