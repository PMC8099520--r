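test_that("a fully uniform plane yields an all-zero map and one bit per block", {
  cc <- compress_residual(matrix(0L, 4, 4), m = 2)
  expect_identical(cc$L, rep(0L, 4))
  expect_equal(cc$r_bits, 4)                      # one sample bit per block
  expect_identical(decompress_residual(cc)$bits, matrix(0L, 4, 4))
})

test_that("the worked 4x4 example classifies blocks as documented", {
  # blocks 1, 3, 4 uniform; block 2 (top-right) mixed
  bits <- rbind(c(0L, 0L, 1L, 0L),
                c(0L, 0L, 1L, 1L),
                c(1L, 1L, 0L, 0L),
                c(1L, 1L, 0L, 0L))
  cc <- compress_residual(bits, m = 2)
  expect_identical(cc$L, c(0L, 1L, 0L, 0L))
  expect_equal(cc$r_bits, 1 + 4 + 1 + 1)          # 7 bits of recovery sequence
  r <- pitcodec:::`.cpp_unpack_bits`(cc$payload, cc$r_bits)
  expect_identical(r, c(0L, 1L, 0L, 1L, 1L, 1L, 0L))
  expect_identical(decompress_residual(cc)$bits, bits)
})

test_that("pre-entropy stream matches the brute-force classifier bit for bit", {
  cases <- list()
  # exhaustive on 2x2 planes
  combos <- as.matrix(expand.grid(rep(list(0:1), 4)))
  for (i in seq_len(nrow(combos)))
    cases[[length(cases) + 1]] <- list(matrix(as.integer(combos[i, ]), 2, 2), 2L)
  # randomized small planes across sides and block sizes
  set.seed(31)
  for (side in c(4L, 8L)) {
    for (m in c(2L, 4L, if (side == 8L) 8L)) {
      for (rep in 1:25) {
        cases[[length(cases) + 1]] <-
          list(matrix(rbinom(side^2, 1L, runif(1)), side, side), m)
      }
    }
  }
  for (cs in cases) {
    cc <- compress_residual(cs[[1]], cs[[2]])
    oracle <- brute_force_block_stream(cs[[1]], cs[[2]])
    expect_identical(cc$L, oracle$L)
    expect_identical(pitcodec:::`.cpp_unpack_bits`(cc$payload, cc$r_bits),
                     oracle$r)
  }
})

test_that("pre-coding size follows the uniform/mixed block accounting", {
  set.seed(77)
  bits <- matrix(rbinom(256, 1L, 0.3), 16, 16)
  cc <- compress_residual(bits, m = 4)
  n_mixed <- sum(cc$L)
  n_uniform <- 16 - n_mixed
  expect_equal(length(cc$L) + cc$r_bits, 16 + n_uniform + 16 * n_mixed)
})

test_that("compression is lossless for every block size and plane type", {
  planes <- list(
    checker = outer(1:32, 1:32, function(r, c) (r + c) %% 2L),
    single = { z <- matrix(0L, 32, 32); z[17, 5] <- 1L; z },
    ones = matrix(1L, 32, 32),
    random = random_plane(32, 0.37, 12),
    clustered = generate_residual(64, 0.08, "clustered", seed = 3)$bits[1:32, 1:32]
  )
  for (m in c(2L, 4L, 8L, 16L)) {
    for (nm in names(planes)) {
      p <- planes[[nm]]
      storage.mode(p) <- "integer"
      out <- decompress_residual(compress_residual(p, m))
      expect_identical(out$bits, p)
    }
  }
  # larger randomized sweep
  set.seed(99)
  for (rep in 1:20) {
    side <- sample(c(16L, 32L, 48L), 1)
    m <- sample(c(2L, 4L, 8L, 16L), 1)
    if (side %% m != 0L) next
    p <- matrix(rbinom(side^2, 1L, runif(1)), side, side)
    expect_identical(decompress_residual(compress_residual(p, m))$bits, p)
  }
})

test_that("worst case still round trips with the documented expansion", {
  checker <- outer(1:16, 1:16, function(r, c) (r + c) %% 2L)
  storage.mode(checker) <- "integer"
  cc <- compress_residual(checker, m = 4)
  expect_equal(sum(cc$L), 16)                       # every block mixed
  expect_equal(length(cc$L) + cc$r_bits, 16^2 / 16 + 16^2)
  expect_lt(compression_ratio(16, cc$delta_bits), 1)
  expect_identical(decompress_residual(cc)$bits, checker)
})

test_that("block size constraints are enforced", {
  expect_error(compress_residual(matrix(0L, 6, 6), m = 4), "divisible")
  expect_error(compress_residual(matrix(0L, 6, 6), m = 1), "at least 2")
  expect_error(compress_residual(matrix(0L, 4, 6), m = 2), "square")
})

test_that("the .rbc container round trips and rejects corruption", {
  r <- generate_residual(32, 0.1, "clustered", seed = 5)
  cc <- compress_residual(r, 4)
  stream <- write_rbc(cc)
  back <- decompress_residual(stream)
  expect_identical(back$bits, r$bits)

  path <- withr::local_tempfile(fileext = ".rbc")
  write_rbc(cc, path)
  expect_identical(decompress_residual(path)$bits, r$bits)

  bad_magic <- stream; bad_magic[1] <- as.raw(0x58)
  expect_error(decompress_residual(bad_magic), "format tag")
  bad_ver <- stream; bad_ver[4] <- as.raw(9)
  expect_error(decompress_residual(bad_ver), "version")
  truncated <- stream[1:(length(stream) - 1L)]
  expect_error(decompress_residual(truncated), "truncat")
  # recovery sequence one bit short of what the location map demands
  short <- stream
  short[12:15] <- writeBin(cc$r_bits - 1L, raw(), size = 4, endian = "little")
  expect_error(decompress_residual(short), "location map")
})

test_that("whole-plane arithmetic baseline round trips and compresses", {
  r <- generate_residual(64, 0.1, "clustered", seed = 11)
  enc <- whole_plane_arith(r)
  expect_identical(whole_plane_arith_decode(enc, 64), r$bits)
  expect_lte(8 * length(whole_plane_arith(matrix(0L, 64, 64))), 64)
})

test_that("block codec beats whole-plane coding on sparse clustered residuals", {
  # reduced paired comparison at the 256x256 study scale (the acceptance
  # suite runs the full 50-seed sign test)
  wins <- 0L
  for (seed in 1:6) {
    r <- generate_residual(256, 0.1, "clustered", seed = seed)
    delta_block <- compress_residual(r, 4)$delta_bits
    delta_whole <- 8 * length(whole_plane_arith(r))
    wins <- wins + (delta_block < delta_whole)
  }
  expect_gte(wins, 5L)
})
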