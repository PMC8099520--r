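# Shared fixtures, all generated in code.

# a small image containing every gray level
all_levels_image <- function() matrix(0:255, 16L, 16L)

random_gray_image <- function(side, seed) {
  set.seed(seed)
  matrix(sample(0:255, side * side, replace = TRUE), side, side)
}

random_plane <- function(side, p = 0.5, seed = 1) {
  set.seed(seed)
  matrix(rbinom(side * side, 1L, p), side, side)
}

# corpus where bit-plane 7 equals bit-plane 8 exactly (the learnable copy
# task): clear bit 7 of each pixel and set it to the pixel's top bit
copy_task_corpus <- function(n, side, seed) {
  lapply(generate_phantoms(n, side, seed = seed), function(im) {
    b8 <- bitwAnd(bitwShiftR(im, 7L), 1L)
    px <- bitwAnd(im, 191L) + b8 * 64L
    dim(px) <- dim(im)
    as_gray_image(px)
  })
}

# Independent brute-force implementation of the block classification stage:
# scans m x m blocks in raster order with explicit loops and returns the
# pre-entropy stream (location map and recovery-sequence bits). Kept naive
# on purpose — it is the oracle the codec is checked against.
brute_force_block_stream <- function(bits, m) {
  M <- nrow(bits)
  L <- integer(0); r <- integer(0)
  for (br in seq_len(M / m)) {
    for (bc in seq_len(M / m)) {
      blk <- bits[((br - 1) * m + 1):(br * m), ((bc - 1) * m + 1):(bc * m)]
      v <- as.integer(t(blk))          # raster order within the block
      if (all(v == 0L) || all(v == 1L)) {
        L <- c(L, 0L); r <- c(r, v[1])
      } else {
        L <- c(L, 1L); r <- c(r, v)
      }
    }
  }
  list(L = L, r = r)
}

# mean squared error between two gray images
img_mse <- function(a, b) mean((as.double(a) - as.double(b))^2)

# a tiny trained predictor bank, trained once per test run and cached.
# 32x32 phantoms, two-channel-wide generator, one epoch: enough to exercise
# real trained-bank behaviour (the transmission protocol is lossless
# regardless of predictor quality).
.fixture_env <- new.env(parent = emptyenv())

tiny_trained_bank <- function() {
  if (!is.null(.fixture_env$bank)) return(.fixture_env$bank)
  imgs <- generate_phantoms(8, 32, seed = 402)
  cfg <- train_config(epochs = 1L, learning_rate = 1e-3, batch_size = 4L,
                      base_channels = 2L, disc_channels = 2L, seed = 7L)
  .fixture_env$bank <- train_predictor_bank(imgs, 7:1, cfg)
  .fixture_env$bank
}
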