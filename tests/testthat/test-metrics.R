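test_that("error rate counts the share of 1-bits in percent", {
  expect_equal(error_rate(matrix(0L, 8, 8)), 0)
  expect_equal(error_rate(matrix(1L, 8, 8)), 100)
  bits <- matrix(0L, 256, 256); bits[seq_len(16384)] <- 1L
  expect_equal(error_rate(bits), 25)
})

test_that("compression ratio is raw bits over compressed bits", {
  expect_equal(compression_ratio(256, 65536), 1)
  expect_equal(compression_ratio(256, 32768), 2)
  expect_error(compression_ratio(256, 0), "positive")
  # CR * delta recovers M^2 exactly
  r <- generate_residual(64, 0.07, "clustered", seed = 2)
  cc <- compress_residual(r, 4)
  expect_equal(compression_ratio(64, cc$delta_bits) * cc$delta_bits, 64^2)
})

test_that("an all-zero plane reaches a high compression ratio", {
  cc <- compress_residual(matrix(0L, 256, 256), m = 4)
  expect_equal(cc$r_bits, 4096)                 # one bit per uniform block
  expect_equal(cc$delta_bits, 8 * length(cc$encoded_map) + 4096)
  expect_lte(8 * length(cc$encoded_map), 64)
  expect_gt(compression_ratio(256, cc$delta_bits), 10)
})

test_that("error rate is invariant under complementing both planes", {
  b <- random_plane(32, 0.4, 5)
  s <- random_plane(32, 0.6, 6)
  expect_equal(error_rate(compute_residual(b, s)),
               error_rate(compute_residual(1L - b, 1L - s)))
})

test_that("the benchmark tabulates both methods over a layered corpus", {
  # per-layer error rates stepping up as in lower bit-planes
  p_by_layer <- c(`7` = 0.05, `6` = 0.08, `5` = 0.12, `4` = 0.18,
                  `3` = 0.22, `2` = 0.26, `1` = 0.33)
  corpus <- lapply(1:3, function(img) {
    lapply(7:1, function(layer)
      generate_residual(64, p_by_layer[[as.character(layer)]], "clustered",
                        layer = layer, seed = 100 * img + layer))
  })
  bench <- run_benchmark(corpus, m = 4)
  expect_setequal(unique(bench$method), c("proposed", "arithmetic"))
  expect_equal(nrow(bench), 3 * 7 * 2)
  expect_true(all(bench$CR > 0))
  expect_equal(bench$epsilon / 64^2 * 100, bench$ER)

  summ <- benchmark_summary(bench, M = 64)
  prop <- summ$per_layer[summ$per_layer$method == "proposed", ]
  # coarse monotone trend: high planes compress better than low planes
  expect_gt(prop$mean_CR[prop$layer == 7], prop$mean_CR[prop$layer == 4])
  expect_gt(prop$mean_CR[prop$layer == 4], prop$mean_CR[prop$layer == 1])
  expect_equal(nrow(summ$whole_image), 2)
  expect_true(all(summ$whole_image$whole_image_CR > 0))

  # block-size sweep keeps one row per size
  sweep <- run_benchmark(corpus[[1]], m = c(2, 4, 8), methods = "proposed")
  expect_equal(nrow(sweep), 7 * 3)
  expect_setequal(unique(sweep$m), c(2L, 4L, 8L))
})

test_that("compressed size grows with the error count on fixed structure", {
  d_small <- compress_residual(
    generate_residual(128, 0.04, "clustered", seed = 9), 4)$delta_bits
  d_large <- compress_residual(
    generate_residual(128, 0.25, "clustered", seed = 9), 4)$delta_bits
  expect_lt(d_small, d_large)
})
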