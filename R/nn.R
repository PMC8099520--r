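# Minimal CPU neural-network layers for the bit-plane predictors.
#
# A feature map is an (H*W) x C numeric matrix (column-major spatial raster,
# one column per channel). 3x3 convolutions and 2x2 max pooling run in C++
# (src/nnops.cpp); matrix products use BLAS; everything else is vectorised R.
# All operations are deterministic: inference involves no dropout or noise,
# so sender and receiver produce bit-identical predictions from equal weights.

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, x) dy * (x > 0)

lrelu_fwd <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_bwd <- function(dy, x, slope = 0.2) dy * ifelse(x > 0, 1, slope)

# numerically safe softplus: log(1 + exp(z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- 2x2 up-convolution (transposed conv, stride 2) -------------------------
# weights: Cin x (4*Cout); quadrant q in 0..3 covers output offset
# (dr, dc) = (q %% 2, q %/% 2); columns q*Cout + 1 .. (q+1)*Cout.

.upconv_index_cache <- new.env(parent = emptyenv())

upconv_indices <- function(h, w) {
  key <- paste0(h, "x", w)
  hit <- .upconv_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  H <- 2L * h
  p_out <- 0:(4L * h * w - 1L)
  r <- p_out %% H; c <- p_out %/% H
  idx <- list(
    src = (r %/% 2L) + (c %/% 2L) * h + 1L,
    q   = (r %% 2L) + 2L * (c %% 2L)
  )
  idx$rows_q <- lapply(0:3, function(q) which(idx$q == q))
  idx$src_q  <- lapply(0:3, function(q) idx$src[idx$rows_q[[q + 1L]]])
  .upconv_index_cache[[key]] <- idx
  idx
}

upconv2_fwd <- function(x, h, w, K) {
  cout <- ncol(K) %/% 4L
  z <- x %*% K
  idx <- upconv_indices(h, w)
  y <- matrix(0, 4L * h * w, cout)
  for (q in 0:3) {
    cols <- (q * cout + 1L):((q + 1L) * cout)
    y[idx$rows_q[[q + 1L]], ] <- z[idx$src_q[[q + 1L]], cols, drop = FALSE]
  }
  y
}

upconv2_bwd <- function(x, h, w, K, dy) {
  cout <- ncol(K) %/% 4L
  idx <- upconv_indices(h, w)
  dz <- matrix(0, h * w, 4L * cout)
  for (q in 0:3) {
    cols <- (q * cout + 1L):((q + 1L) * cout)
    dz[idx$src_q[[q + 1L]], cols] <- dy[idx$rows_q[[q + 1L]], , drop = FALSE]
  }
  list(dx = dz %*% t(K), dK = crossprod(x, dz))
}

# ---- parameter initialisation and Adam --------------------------------------

he_init <- function(nrow, ncol, fan_in, gain = 2) {
  matrix(rnorm(nrow * ncol, sd = sqrt(gain / fan_in)), nrow, ncol)
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Adam with pix2pix's beta1 = 0.5 convention; lr is passed per step so the
# midpoint halving schedule lives in the training loop.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
grads_scale <- function(a, s) { for (nm in names(a)) a[[nm]] <- a[[nm]] * s; a }

# ---- U-Net generator --------------------------------------------------------
# Four contracting steps of three 3x3 conv + ReLU layers each, joined by 2x2
# max pooling; a bridge block of three convolutions at the bottom; four
# expansive steps of 2x2 up-convolution, same-size skip concatenation from
# the contracting path, and three 3x3 conv + ReLU layers; a final 1x1
# convolution yields one full-resolution linear output map, regressed onto
# the symmetric bit encoding {-1, +1} and binarized at the range midpoint 0.
# A saturating output nonlinearity is deliberately absent: under the strong
# l1 term it can flatline early in training and strand the generator on a
# constant plane. Channel widths double per contracting step from `base`.

unet_channels <- function(base) c(base, 2L * base, 4L * base, 8L * base, 16L * base)

unet_init <- function(base = 4L, in_channels = 1L) {
  ch <- unet_channels(base)
  p <- list()
  cin <- in_channels
  for (s in 1:4) {
    for (j in 1:3) {
      cout <- ch[s]
      p[[sprintf("enc%d_w%d", s, j)]] <- he_init(9L * cin, cout, 9L * cin)
      p[[sprintf("enc%d_b%d", s, j)]] <- numeric(cout)
      cin <- cout
    }
  }
  for (j in 1:3) {
    p[[sprintf("bridge_w%d", j)]] <- he_init(9L * cin, ch[5], 9L * cin)
    p[[sprintf("bridge_b%d", j)]] <- numeric(ch[5])
    cin <- ch[5]
  }
  for (s in 4:1) {
    p[[sprintf("up%d_K", s)]] <- he_init(cin, 4L * ch[s], cin)
    cin <- 2L * ch[s]  # upconv output concatenated with the skip
    for (j in 1:3) {
      p[[sprintf("dec%d_w%d", s, j)]] <- he_init(9L * cin, ch[s], 9L * cin)
      p[[sprintf("dec%d_b%d", s, j)]] <- numeric(ch[s])
      cin <- ch[s]
    }
  }
  p[["out_w"]] <- he_init(cin, 1L, cin, gain = 0.01)
  p[["out_b"]] <- 0
  p
}

conv_block_fwd <- function(p, prefix, x, H, W, cache) {
  for (j in 1:3) {
    w <- p[[sprintf("%s_w%d", prefix, j)]]
    b <- p[[sprintf("%s_b%d", prefix, j)]]
    pre <- .cpp_conv3x3_fwd(x, H, W, w, b)
    cache[[sprintf("%s_x%d", prefix, j)]] <- x
    cache[[sprintf("%s_pre%d", prefix, j)]] <- pre
    x <- relu_fwd(pre)
  }
  list(x = x, cache = cache)
}

conv_block_bwd <- function(p, prefix, dy, H, W, cache, grads) {
  for (j in 3:1) {
    pre <- cache[[sprintf("%s_pre%d", prefix, j)]]
    xin <- cache[[sprintf("%s_x%d", prefix, j)]]
    d <- relu_bwd(dy, pre)
    g <- .cpp_conv3x3_bwd(xin, H, W, p[[sprintf("%s_w%d", prefix, j)]], d)
    grads[[sprintf("%s_w%d", prefix, j)]] <- g$dw
    grads[[sprintf("%s_b%d", prefix, j)]] <- g$db
    dy <- g$dx
  }
  list(dx = dy, grads = grads)
}

unet_forward <- function(p, x, H, W, keep_cache = FALSE) {
  cache <- list(H = H, W = W)
  skips <- list(); dims <- list()
  h <- H; w <- W
  for (s in 1:4) {
    cb <- conv_block_fwd(p, sprintf("enc%d", s), x, h, w, cache)
    x <- cb$x; cache <- cb$cache
    skips[[s]] <- x; dims[[s]] <- c(h, w)
    mp <- .cpp_maxpool2_fwd(x, h, w)
    cache[[sprintf("pool%d_idx", s)]] <- mp$idx
    cache[[sprintf("pool%d_hw", s)]] <- h * w
    x <- mp$y; h <- h %/% 2L; w <- w %/% 2L
  }
  cb <- conv_block_fwd(p, "bridge", x, h, w, cache)
  x <- cb$x; cache <- cb$cache
  for (s in 4:1) {
    K <- p[[sprintf("up%d_K", s)]]
    cache[[sprintf("up%d_x", s)]] <- x
    cache[[sprintf("up%d_hw", s)]] <- c(h, w)
    x <- upconv2_fwd(x, h, w, K)
    h <- 2L * h; w <- 2L * w
    x <- cbind(skips[[s]], x)                      # skip concatenation
    cb <- conv_block_fwd(p, sprintf("dec%d", s), x, h, w, cache)
    x <- cb$x; cache <- cb$cache
  }
  cache$out_x <- x
  z <- as.vector(x %*% p$out_w) + p$out_b
  y <- matrix(z, ncol = 1L)
  if (keep_cache) list(y = y, cache = cache) else list(y = y)
}

unet_backward <- function(p, cache, dy) {
  grads <- list()
  H <- cache$H; W <- cache$W
  # through the linear 1x1 output conv
  dz <- as.vector(dy)
  grads$out_w <- crossprod(cache$out_x, dz)
  grads$out_b <- sum(dz)
  dx <- dz %*% t(p$out_w)
  h <- H; w <- W
  for (s in 1:4) {
    cb <- conv_block_bwd(p, sprintf("dec%d", s), dx, h, w, cache, grads)
    grads <- cb$grads
    nskip <- ncol(cb$dx) %/% 2L
    dskip <- cb$dx[, seq_len(nskip), drop = FALSE]
    dup <- cb$dx[, (nskip + 1L):ncol(cb$dx), drop = FALSE]
    hw <- cache[[sprintf("up%d_hw", s)]]
    ub <- upconv2_bwd(cache[[sprintf("up%d_x", s)]], hw[1], hw[2],
                      p[[sprintf("up%d_K", s)]], dup)
    grads[[sprintf("up%d_K", s)]] <- ub$dK
    cache[[sprintf("skipgrad%d", s)]] <- dskip
    dx <- ub$dx
    h <- hw[1]; w <- hw[2]
  }
  cb <- conv_block_bwd(p, "bridge", dx, h, w, cache, grads)
  grads <- cb$grads; dx <- cb$dx
  for (s in 4:1) {
    dx <- .cpp_maxpool2_bwd(dx, cache[[sprintf("pool%d_idx", s)]],
                            cache[[sprintf("pool%d_hw", s)]])
    h <- 2L * h; w <- 2L * w
    dx <- dx + cache[[sprintf("skipgrad%d", s)]]
    cb <- conv_block_bwd(p, sprintf("enc%d", s), dx, h, w, cache, grads)
    grads <- cb$grads; dx <- cb$dx
  }
  list(grads = grads, dx = dx)
}

# ---- patch discriminator ----------------------------------------------------
# Conditional patch-wise classifier: input is the packed condition image and
# the (real or generated) plane as two channels. Three 3x3 conv + leaky ReLU
# + 2x2 max pool stages followed by a 1x1 convolution give an (M/8)^2 map of
# patch logits; each element judges one receptive-field patch real or fake.

patchdisc_init <- function(base = 8L, in_channels = 2L, levels = 3L) {
  p <- list()
  cin <- in_channels
  for (s in seq_len(levels)) {
    cout <- base * 2L^(s - 1L)
    p[[sprintf("d%d_w", s)]] <- he_init(9L * cin, cout, 9L * cin)
    p[[sprintf("d%d_b", s)]] <- numeric(cout)
    cin <- cout
  }
  p[["dout_w"]] <- he_init(cin, 1L, cin, gain = 0.01)
  p[["dout_b"]] <- 0
  p
}

patchdisc_forward <- function(p, x, H, W, keep_cache = FALSE) {
  levels <- sum(grepl("^d[0-9]+_w$", names(p)))
  cache <- list(H = H, W = W, levels = levels)
  h <- H; w <- W
  for (s in seq_len(levels)) {
    pre <- .cpp_conv3x3_fwd(x, h, w, p[[sprintf("d%d_w", s)]],
                            p[[sprintf("d%d_b", s)]])
    cache[[sprintf("d%d_x", s)]] <- x
    cache[[sprintf("d%d_pre", s)]] <- pre
    a <- lrelu_fwd(pre)
    mp <- .cpp_maxpool2_fwd(a, h, w)
    cache[[sprintf("d%d_idx", s)]] <- mp$idx
    cache[[sprintf("d%d_hw", s)]] <- h * w
    x <- mp$y; h <- h %/% 2L; w <- w %/% 2L
  }
  cache$dout_x <- x
  z <- as.vector(x %*% p$dout_w) + p$dout_b   # patch logits
  if (keep_cache) list(z = z, cache = cache) else list(z = z)
}

patchdisc_backward <- function(p, cache, dz) {
  grads <- list()
  grads$dout_w <- crossprod(cache$dout_x, dz)
  grads$dout_b <- sum(dz)
  dx <- dz %*% t(p$dout_w)
  for (s in cache$levels:1) {
    dx <- .cpp_maxpool2_bwd(dx, cache[[sprintf("d%d_idx", s)]],
                            cache[[sprintf("d%d_hw", s)]])
    dx <- lrelu_bwd(dx, cache[[sprintf("d%d_pre", s)]])
    hw <- cache[[sprintf("d%d_hw", s)]]
    # recover spatial dims for this level
    side_ratio <- cache$H / cache$W
    h <- as.integer(round(sqrt(hw * side_ratio)))
    w <- as.integer(hw / h)
    g <- .cpp_conv3x3_bwd(cache[[sprintf("d%d_x", s)]], h, w,
                          p[[sprintf("d%d_w", s)]], dx)
    grads[[sprintf("d%d_w", s)]] <- g$dw
    grads[[sprintf("d%d_b", s)]] <- g$db
    dx <- g$dx
  }
  list(grads = grads, dx = dx)
}
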