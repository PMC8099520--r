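test_that("decomposition extracts the binary expansion of each pixel", {
  img <- matrix(c(255L, 0L, 200L, 65L), 2, 2)
  st <- decompose_bitplanes(img)
  get_bits <- function(r, c) vapply(st$planes, function(p) p$bits[r, c], 0L)
  expect_equal(get_bits(1, 1), rep(1L, 8))            # 255: ones everywhere
  expect_equal(get_bits(2, 1), rep(0L, 8))            # 0: zeros everywhere
  expect_equal(get_bits(1, 2), c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L))  # 200
  expect_equal(get_bits(2, 2), c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 1L))  # 65
  expect_equal(st$layers, 8:1)
})

test_that("out-of-range and non-integer pixels are rejected", {
  expect_error(decompose_bitplanes(matrix(c(0, 256), 1, 2)), "255")
  expect_error(decompose_bitplanes(matrix(c(-1, 3), 1, 2)), "\\[0, 255\\]")
  expect_error(decompose_bitplanes(matrix(c(0.5, 1), 1, 2)), "integer")
})

test_that("recompose inverts decompose exactly", {
  for (seed in 1:10) {
    img <- random_gray_image(16, seed)
    expect_identical(recompose_bitplanes(decompose_bitplanes(img)), img)
  }
  # all constant images
  for (v in c(0L, 1L, 127L, 128L, 255L)) {
    img <- matrix(v, 4, 4)
    expect_identical(recompose_bitplanes(decompose_bitplanes(img)), img)
  }
  zero <- bitplane_stack(lapply(8:1, function(k)
    bit_plane(matrix(0L, 2, 2), k)))
  expect_true(all(recompose_bitplanes(zero) == 0L))
})

test_that("recompose requires a complete stack", {
  st <- decompose_bitplanes(all_levels_image())
  top <- bitplane_stack(st$planes[1:3])
  expect_error(recompose_bitplanes(top), "incomplete")
})

test_that("stacks must be contiguous, descending from 8, same shape", {
  p8 <- bit_plane(matrix(0L, 2, 2), 8)
  p6 <- bit_plane(matrix(0L, 2, 2), 6)
  expect_error(bitplane_stack(list(p8, p6)), "contiguous")
  expect_error(bitplane_stack(list(p6)), "contiguous")
  p7_big <- bit_plane(matrix(0L, 4, 4), 7)
  expect_error(bitplane_stack(list(p8, p7_big)), "dimensions")
})

test_that("midpoint reconstruction uses the documented quantization levels", {
  st <- decompose_bitplanes(all_levels_image())
  # one plane: intervals [0,127] and [128,255] -> 64 and 192
  r1 <- bpm_reconstruct(bitplane_stack(st$planes[1]))
  expect_setequal(unique(as.vector(r1)), c(64L, 192L))
  expect_equal(r1[all_levels_image() <= 127][1], 64L)
  expect_equal(r1[all_levels_image() >= 128][1], 192L)
  # two planes: codes 00,01,10,11 -> 32, 96, 160, 224
  r2 <- bpm_reconstruct(bitplane_stack(st$planes[1:2]))
  expect_setequal(unique(as.vector(r2)), c(32L, 96L, 160L, 224L))
  expect_equal(unique(r2[all_levels_image() %/% 64 == 2]), 160L)
  expect_equal(unique(r2[all_levels_image() %/% 64 == 0]), 32L)
  # three planes, code 101 -> interval [160,191] -> representative 176
  r3 <- bpm_reconstruct(bitplane_stack(st$planes[1:3]))
  expect_equal(unique(r3[all_levels_image() %/% 32 == 5]), 176L)
  # full stack: exact
  expect_identical(bpm_reconstruct(st), all_levels_image())
})

test_that("reconstruction error is bounded and refines monotonically", {
  img <- random_gray_image(32, 99)
  st <- decompose_bitplanes(img)
  prev_mse <- Inf
  for (k in 1:8) {
    rec <- bpm_reconstruct(bitplane_stack(st$planes[1:k]))
    err <- abs(as.double(rec) - as.double(img))
    if (k < 8) expect_lte(max(err), 2^(8 - k - 1))
    mse <- mean(err^2)
    expect_lte(mse, prev_mse)
    prev_mse <- mse
  }
  expect_equal(prev_mse, 0)
})

test_that("gray images round trip through PNG and PGM, planes through PBM", {
  img <- random_gray_image(16, 7)
  png_path <- withr::local_tempfile(fileext = ".png")
  pgm_path <- withr::local_tempfile(fileext = ".pgm")
  write_gray_image(img, png_path)
  write_gray_image(img, pgm_path)
  expect_identical(read_gray_image(png_path), img)
  expect_identical(read_gray_image(pgm_path), img)

  bits <- random_plane(16, 0.3, seed = 8)
  pbm_path <- withr::local_tempfile(fileext = ".pbm")
  write_pbm(bits, pbm_path)
  expect_identical(read_pbm(pbm_path), bits)
  # non-multiple-of-8 width exercises row padding
  wide <- matrix(rbinom(5 * 13, 1, 0.5), 5, 13)
  write_pbm(wide, pbm_path)
  expect_equal(read_pbm(pbm_path), wide, ignore_attr = FALSE)
})

test_that("multi-channel and 16-bit inputs are rejected", {
  rgb_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(12), c(2, 2, 3)), rgb_path)
  expect_error(read_gray_image(rgb_path), "multi-channel")
  p16 <- withr::local_tempfile(fileext = ".pgm")
  con <- file(p16, "wb")
  writeChar("P5\n2 2\n65535\n", con, eos = NULL)
  writeBin(as.raw(rep(0, 8)), con); close(con)
  expect_error(read_gray_image(p16), "8-bit")
})
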