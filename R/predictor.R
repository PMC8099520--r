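# Conditional-adversarial bit-plane predictors.
#
# One generator per target layer i in 7..1 learns the mapping from the packed
# higher planes b8..b(i+1) to plane b_i. The generator is the U-Net of
# R/nn.R; the discriminator is a conditional patch classifier. Training
# minimises the non-saturating GAN loss plus lambda times the l1 term; the
# trained generators are organised into a predictor bank that sender and
# receiver share, so both sides can reproduce the same synthetic plane and
# exchange only the residual.

#' Pack the available high bit-planes into one 8-bit image
#'
#' The predictor's input format is an ordinary 8-bit image: the provided
#' planes occupy their own (top) bit positions and zeros are appended behind
#' them in the unavailable lower positions. For target layer 7 the packed
#' image is just `b8 * 128`.
#'
#' @param stack A [bitplane_stack] holding layers 8..(target_layer+1).
#' @param target_layer The layer to be predicted, in 1..7.
#' @return Gray image matrix with all bits below `target_layer` zero.
#' @export
pack_planes <- function(stack, target_layer) {
  if (!inherits(stack, "bitplane_stack")) stop("expected a bitplane_stack")
  target_layer <- as.integer(target_layer)
  if (target_layer < 1L || target_layer > 7L)
    stop("target layer must be in 1..7")
  need <- 8:(target_layer + 1L)
  if (!all(need %in% stack$layers))
    stop("stack is missing layers required to predict b", target_layer)
  px <- 0L
  for (k in need) {
    p <- stack_plane(stack, k)
    px <- px + p$bits * bitwShiftL(1L, k - 1L)
  }
  as_gray_image(px)
}

#' Mean absolute (l1) distance between target plane and generator output
#'
#' @param y Target values (matrix or vector).
#' @param g Generator output, same shape.
#' @return Mean over all positions of `|y - g|`.
#' @export
l1_term <- function(y, g) {
  if (!identical(dim(y), dim(g)) || length(y) != length(g))
    stop("shape mismatch between target and generator output")
  mean(abs(y - g))
}

#' Combined generator objective
#'
#' The generator minimises the adversarial loss plus `lambda_l1` times the
#' l1 reconstruction term; `lambda_l1` balances sharpness of the adversarial
#' game against fidelity to the true plane.
#'
#' @param gan_loss Adversarial loss value.
#' @param l1 l1 term value.
#' @param lambda_l1 Non-negative balance weight (default 1e3).
#' @return `gan_loss + lambda_l1 * l1`.
#' @export
combined_objective <- function(gan_loss, l1, lambda_l1 = 1e3) {
  if (lambda_l1 < 0) stop("lambda_l1 must be non-negative")
  gan_loss + lambda_l1 * l1
}

#' Training configuration for a bit-plane predictor
#'
#' Defaults follow the full-scale recipe: 100 epochs, Adam with initial
#' learning rate 2e-4 halved at the training midpoint, batch size 32,
#' lambda_l1 = 1e3. Scaled-down runs (small images, few epochs) should raise
#' the learning rate and shrink the batch so that the number and size of
#' optimiser steps remain adequate; see the methods vignette.
#'
#' @param epochs Number of passes over the corpus.
#' @param learning_rate Initial Adam step size.
#' @param batch_size Minibatch size.
#' @param lambda_l1 Weight of the l1 term in the generator objective.
#' @param base_channels Generator width (channels in the first contracting
#'   step; doubled at each of the four steps).
#' @param disc_channels Discriminator width.
#' @param lr_halve Halve the learning rate from the midpoint epoch on.
#' @param seed Integer seed controlling initialisation and batch order.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 2e-4, batch_size = 32L,
                         lambda_l1 = 1e3, base_channels = 4L,
                         disc_channels = 8L, lr_halve = TRUE, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), learning_rate = learning_rate,
              batch_size = as.integer(batch_size), lambda_l1 = lambda_l1,
              base_channels = as.integer(base_channels),
              disc_channels = as.integer(disc_channels),
              lr_halve = isTRUE(lr_halve), seed = as.integer(seed))
  with(cfg, {
    if (epochs < 1L || learning_rate <= 0 || batch_size < 1L ||
        base_channels < 1L || disc_channels < 1L)
      stop("train_config: all sizes and rates must be positive")
    if (lambda_l1 < 0) stop("train_config: lambda_l1 must be non-negative")
  })
  structure(cfg, class = "train_config")
}

# bits {0,1} -> activation range {-1, +1}; packed 0..255 -> [-1, 1]
scale_bits <- function(bits) matrix(2 * as.vector(bits) - 1, ncol = 1L)
scale_packed <- function(px) matrix(as.vector(px) / 127.5 - 1, ncol = 1L)

# feature-map column vector (column-major) from an image matrix
as_colmap <- function(mat) matrix(as.numeric(mat), ncol = 1L)

#' Train one bit-plane predictor
#'
#' Trains the conditional generator for `target_layer` on a corpus of gray
#' images: inputs are the packed planes above the target, ground truth is the
#' target plane itself. Images must share a side divisible by 16 (four 2x2
#' pooling steps). Training is deterministic given `cfg$seed`.
#'
#' @param images List of gray image matrices.
#' @param target_layer Layer in 1..7 to predict.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `bitplane_predictor` carrying the generator
#'   weights, the configuration, a corpus fingerprint, and the per-epoch loss
#'   trajectory (`$history`: generator objective, its components, and the
#'   discriminator loss).
#' @export
train_predictor <- function(images, target_layer, cfg = train_config(),
                            verbose = FALSE) {
  if (length(images) == 0L) stop("empty training set")
  if (!inherits(cfg, "train_config")) stop("cfg must be a train_config")
  target_layer <- as.integer(target_layer)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  if (H %% 16L != 0L || W %% 16L != 0L)
    stop("image side must be divisible by 16 (four pooling steps)")

  xs <- vector("list", length(images)); ys <- xs
  for (i in seq_along(images)) {
    st <- decompose_bitplanes(images[[i]])
    xs[[i]] <- scale_packed(pack_planes(st, target_layer))
    ys[[i]] <- scale_bits(stack_plane(st, target_layer)$bits)
  }

  set.seed(cfg$seed)
  G <- unet_init(cfg$base_channels, in_channels = 1L)
  D <- patchdisc_init(cfg$disc_channels, in_channels = 2L)
  stG <- adam_state(G); stD <- adam_state(D)
  history <- data.frame(epoch = integer(0), g_total = numeric(0),
                        g_gan = numeric(0), g_l1 = numeric(0),
                        d_loss = numeric(0))

  n <- length(images)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate
    if (cfg$lr_halve && epoch > cfg$epochs / 2) lr <- lr / 2
    ord <- sample.int(n)
    ep <- c(g_total = 0, g_gan = 0, g_l1 = 0, d_loss = 0); nb <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      gD <- NULL; gG <- NULL
      lossD <- 0; lossGan <- 0; lossL1 <- 0
      for (i in idx) {
        x <- xs[[i]]; y <- ys[[i]]
        gen <- unet_forward(G, x, H, W, keep_cache = TRUE)
        g <- gen$y

        # --- discriminator: real pair up, generated pair down
        dr <- patchdisc_forward(D, cbind(x, y), H, W, keep_cache = TRUE)
        df <- patchdisc_forward(D, cbind(x, g), H, W, keep_cache = TRUE)
        np <- length(dr$z)
        lossD <- lossD + 0.5 * (mean(softplus(-dr$z)) + mean(softplus(df$z)))
        dzr <- matrix(0.5 * (sigmoid(dr$z) - 1) / np, ncol = 1L)
        dzf <- matrix(0.5 * sigmoid(df$z) / np, ncol = 1L)
        gD <- grads_add(gD, patchdisc_backward(D, dr$cache, dzr)$grads)
        gD <- grads_add(gD, patchdisc_backward(D, df$cache, dzf)$grads)

        # --- generator: non-saturating GAN term + lambda * l1
        # (D is constant within the batch, so the D(x, g) forward above is
        # reused; only the upstream gradient differs)
        lossGan <- lossGan + mean(softplus(-df$z))
        lossL1 <- lossL1 + l1_term(y, g)
        dz <- matrix((sigmoid(df$z) - 1) / np, ncol = 1L)
        dg_gan <- patchdisc_backward(D, df$cache, dz)$dx[, 2L, drop = FALSE]
        dg_l1 <- cfg$lambda_l1 * sign(g - y) / length(g)
        gG <- grads_add(gG, unet_backward(G, gen$cache, dg_gan + dg_l1)$grads)
      }
      k <- length(idx)
      upd <- adam_step(D, grads_scale(gD, 1 / k), stD, lr)
      D <- upd$params; stD <- upd$state
      upd <- adam_step(G, grads_scale(gG, 1 / k), stG, lr)
      G <- upd$params; stG <- upd$state
      ep <- ep + c(combined_objective(lossGan / k, lossL1 / k, cfg$lambda_l1),
                   lossGan / k, lossL1 / k, lossD / k)
      nb <- nb + 1L
    }
    ep <- ep / nb
    history[nrow(history) + 1L, ] <- c(epoch, ep["g_total"], ep["g_gan"],
                                       ep["g_l1"], ep["d_loss"])
    if (verbose)
      message(sprintf("epoch %d/%d  G %.4f (gan %.4f, l1 %.4f)  D %.4f",
                      epoch, cfg$epochs, ep["g_total"], ep["g_gan"],
                      ep["g_l1"], ep["d_loss"]))
  }

  structure(list(
    layer = target_layer,
    generator = G,
    cfg = cfg,
    side = c(H, W),
    history = history,
    fingerprint = corpus_fingerprint(images)
  ), class = "bitplane_predictor")
}

#' @export
print.bitplane_predictor <- function(x, ...) {
  cat(sprintf(
    "<bitplane_predictor> target b%d, trained on %dx%d, %d epochs, base %d\n",
    x$layer, x$side[1], x$side[2], x$cfg$epochs, x$cfg$base_channels))
  invisible(x)
}

# 32-bit FNV-1a over a text rendering; used for corpus/config fingerprints.
# h is held as a double in [0, 2^32); the xor only touches the low byte.
fnv1a32 <- function(txt) {
  bytes <- if (is.raw(txt)) as.integer(txt) else as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # multiply mod 2^32 without exceeding double precision
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31)) # printable digest; top bit dropped
}

corpus_fingerprint <- function(images) {
  fnv1a32(paste(length(images), nrow(images[[1]]), ncol(images[[1]]),
                sum(vapply(images, function(im) sum(as.double(im)), 0)),
                sep = ":"))
}

config_hash <- function(cfg) {
  fnv1a32(paste(unlist(cfg), collapse = ","))
}

# ---- predictor bank ---------------------------------------------------------

#' Assemble trained predictors into a bank
#'
#' The bank maps each target layer to its trained generator. Sender and
#' receiver hold identical copies; prediction is deterministic, so both sides
#' derive bit-identical synthetic planes from the same received planes.
#'
#' @param predictors List of `bitplane_predictor` objects with distinct
#'   layers.
#' @return An object of class `predictor_bank`.
#' @export
predictor_bank <- function(predictors) {
  layers <- vapply(predictors, function(p) p$layer, integer(1))
  if (anyDuplicated(layers)) stop("duplicate predictor layers in bank")
  names(predictors) <- as.character(layers)
  structure(list(predictors = predictors, layers = sort(layers,
                                                        decreasing = TRUE)),
            class = "predictor_bank")
}

#' @export
print.predictor_bank <- function(x, ...) {
  cat(sprintf("<predictor_bank> predictors for layers: %s\n",
              paste0("b", x$layers, collapse = ", ")))
  invisible(x)
}

#' Train a full predictor bank
#'
#' Convenience wrapper training one predictor per requested layer on the same
#' corpus. Per-layer seeds are derived from `cfg$seed` so the layers do not
#' share an initialisation.
#'
#' @param images Training corpus (list of gray image matrices).
#' @param layers Target layers (default 7..1).
#' @param cfg A [train_config()].
#' @param verbose Print progress.
#' @return A [predictor_bank()].
#' @export
train_predictor_bank <- function(images, layers = 7:1, cfg = train_config(),
                                 verbose = FALSE) {
  preds <- lapply(layers, function(l) {
    cfg_l <- cfg
    cfg_l$seed <- cfg$seed + 101L * (8L - as.integer(l))
    if (verbose) message("training predictor for b", l)
    train_predictor(images, l, cfg_l, verbose = verbose)
  })
  predictor_bank(preds)
}

#' Predict a bit-plane from the already received planes
#'
#' Runs the bank's generator for `target_layer` on the packed higher planes
#' and binarises its output at the midpoint of the activation range (0 for
#' the symmetric tanh output). Inference is deterministic: two calls with the
#' same bank and stack return bit-identical planes.
#'
#' @param bank A [predictor_bank()] (or an [oracle_bank()] test stub).
#' @param stack A [bitplane_stack] holding layers 8..(target_layer+1).
#' @param target_layer Layer to predict.
#' @return The synthetic [bit_plane].
#' @export
predict_plane <- function(bank, stack, target_layer) UseMethod("predict_plane")

#' @export
predict_plane.predictor_bank <- function(bank, stack, target_layer) {
  target_layer <- as.integer(target_layer)
  pred <- bank$predictors[[as.character(target_layer)]]
  if (is.null(pred)) stop("bank has no predictor for layer b", target_layer)
  packed <- pack_planes(stack, target_layer)
  H <- nrow(packed); W <- ncol(packed)
  if (H %% 16L != 0L || W %% 16L != 0L)
    stop("image side must be divisible by 16")
  out <- unet_forward(pred$generator, scale_packed(packed), H, W)$y
  bit_plane(matrix(as.integer(out > 0), H, W), target_layer)
}

#' Oracle predictor stub
#'
#' A drop-in replacement for a trained bank that "predicts" the true plane of
#' a known reference image. Used to exercise the transmission protocol in the
#' best case (all-zero residuals) and to isolate codec behaviour from
#' predictor quality.
#'
#' @param image The reference gray image whose planes are returned.
#' @return An object of class `oracle_bank`.
#' @export
oracle_bank <- function(image) {
  structure(list(stack = decompose_bitplanes(image)), class = "oracle_bank")
}

#' @export
predict_plane.oracle_bank <- function(bank, stack, target_layer) {
  stack_plane(bank$stack, as.integer(target_layer))
}

# ---- bank serialization -----------------------------------------------------

BANK_FORMAT <- "pitcodec-bank-1"

write_params_txt <- function(params, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(params)) {
    p <- params[[nm]]
    d <- if (is.matrix(p)) dim(p) else c(length(p), 0L)
    writeLines(sprintf("param %s %d %d", nm, d[1], d[2]), con)
    writeLines(paste(sprintf("%.17g", as.vector(p)), collapse = " "), con)
  }
}

read_params_txt <- function(path) {
  lines <- readLines(path)
  params <- list()
  i <- 1L
  while (i < length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (hdr[1] != "param") stop("corrupt predictor file: ", path)
    vals <- as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]])
    nr <- as.integer(hdr[3]); nc <- as.integer(hdr[4])
    params[[hdr[2]]] <- if (nc > 0L) matrix(vals, nr, nc)
                        else if (nr == 1L) vals[1] else vals
    i <- i + 2L
  }
  params
}

#' Save / load a predictor bank
#'
#' The bank is written as one plain-text weight file per predictor plus a
#' manifest recording the format version, covered layers, training side,
#' and a configuration hash per predictor. Weights are stored with 17
#' significant digits, so a loaded bank reproduces predictions bit-exactly.
#'
#' @param bank A [predictor_bank()].
#' @param path Directory to write to (created if missing).
#' @return `save_bank` returns `path` invisibly; `load_bank` returns the
#'   reconstructed [predictor_bank()].
#' @export
save_bank <- function(bank, path) {
  if (!inherits(bank, "predictor_bank")) stop("expected a predictor_bank")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  man <- c(paste0("format: ", BANK_FORMAT),
           paste0("layers: ", paste(bank$layers, collapse = " ")))
  for (l in bank$layers) {
    p <- bank$predictors[[as.character(l)]]
    write_params_txt(p$generator, file.path(path, sprintf("predictor_b%d.txt", l)))
    man <- c(man, sprintf(
      "predictor: layer=%d side=%dx%d base=%d epochs=%d lr=%.17g batch=%d lambda=%.17g confighash=%s data=%s",
      l, p$side[1], p$side[2], p$cfg$base_channels, p$cfg$epochs,
      p$cfg$learning_rate, p$cfg$batch_size, p$cfg$lambda_l1,
      config_hash(p$cfg), p$fingerprint))
  }
  writeLines(man, file.path(path, "manifest.txt"))
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  mf <- file.path(path, "manifest.txt")
  if (!file.exists(mf)) stop("not a predictor bank: missing manifest at ", path)
  man <- readLines(mf)
  fmt <- sub("^format: ", "", man[grepl("^format: ", man)])
  if (!identical(fmt, BANK_FORMAT))
    stop("incompatible bank format version: '", fmt, "' (need ", BANK_FORMAT, ")")
  meta <- man[grepl("^predictor: ", man)]
  preds <- lapply(meta, function(ln) {
    kv <- regmatches(ln, gregexpr("[a-z]+=[^ ]+", ln))[[1]]
    f <- function(key) sub(paste0(key, "="), "",
                           kv[startsWith(kv, paste0(key, "="))])
    layer <- as.integer(f("layer"))
    side <- as.integer(strsplit(f("side"), "x")[[1]])
    gen <- read_params_txt(file.path(path, sprintf("predictor_b%d.txt", layer)))
    structure(list(
      layer = layer, generator = gen,
      cfg = train_config(epochs = as.integer(f("epochs")),
                         learning_rate = as.numeric(f("lr")),
                         batch_size = as.integer(f("batch")),
                         lambda_l1 = as.numeric(f("lambda")),
                         base_channels = as.integer(f("base"))),
      side = side, history = NULL, fingerprint = f("data")
    ), class = "bitplane_predictor")
  })
  predictor_bank(preds)
}
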