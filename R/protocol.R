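# End-to-end sender/receiver simulation.
#
# The sender transmits the top plane b8 first (raw or arithmetic coded),
# then for each lower layer predicts the plane from the planes already sent,
# forms the residual against the true plane, and transmits the compressed
# residual. The receiver mirrors the prediction with the shared bank,
# decompresses each residual, flips the predicted bits it marks, and can
# reconstruct a progressively refined image after every plane. Because
# prediction is deterministic and residual coding lossless, the fully
# received image equals the input bit for bit.

plane_checksum <- function(bits) fnv1a32(.cpp_pack_bits(as.integer(t(bits))))

#' Simulate the sender: turn an image into a progressive stream
#'
#' @param image Gray image matrix with side divisible by 16.
#' @param bank A [predictor_bank()] or [oracle_bank()] shared with the
#'   receiver.
#' @param m Block size for residual compression.
#' @param b8_mode How the top plane travels: `"raw"` (`M^2` bits) or
#'   `"arith"` (whole-plane arithmetic coded).
#' @return An object of class `pit_session`: `$stream` (per-layer payloads in
#'   transmission order, layer 8 first), `$manifest` (data frame with layer,
#'   mode, m, delta_bits, ER and a per-plane checksum), `$M`.
#' @export
pit_send <- function(image, bank, m = 4L, b8_mode = c("raw", "arith")) {
  b8_mode <- match.arg(b8_mode)
  image <- as_gray_image(image)
  M <- nrow(image)
  stack <- decompose_bitplanes(image)

  stream <- vector("list", 8L)
  manifest <- data.frame(layer = 8:1, mode = NA_character_, m = NA_integer_,
                         delta_bits = NA_integer_, ER = NA_real_,
                         checksum = NA_character_)
  b8 <- stack_plane(stack, 8L)
  if (b8_mode == "raw") {
    stream[[1]] <- list(layer = 8L, mode = "raw",
                        payload = .cpp_pack_bits(as.integer(t(b8$bits))),
                        n_bits = M * ncol(image))
    manifest$delta_bits[1] <- M * ncol(image)
  } else {
    enc <- whole_plane_arith(b8$bits)
    stream[[1]] <- list(layer = 8L, mode = "arith", payload = enc,
                        n_bits = M * ncol(image))
    manifest$delta_bits[1] <- 8L * length(enc)
  }
  manifest$mode[1] <- b8_mode
  manifest$ER[1] <- NA_real_
  manifest$checksum[1] <- plane_checksum(b8$bits)

  sent <- bitplane_stack(list(b8))
  for (layer in 7:1) {
    true_plane <- stack_plane(stack, layer)
    synthetic <- predict_plane(bank, sent, layer)
    res <- compute_residual(true_plane, synthetic)
    comp <- compress_residual(res, m)
    i <- 9L - layer
    stream[[i]] <- list(layer = layer, mode = "residual",
                        payload = write_rbc(comp))
    manifest$mode[i] <- "residual"
    manifest$m[i] <- as.integer(m)
    manifest$delta_bits[i] <- comp$delta_bits
    manifest$ER[i] <- error_rate(res)
    manifest$checksum[i] <- plane_checksum(true_plane$bits)
    sent <- bitplane_stack(c(sent$planes, list(true_plane)))
  }

  structure(list(stream = stream, manifest = manifest, M = M,
                 m = as.integer(m), b8_mode = b8_mode),
            class = "pit_session")
}

#' @export
print.pit_session <- function(x, ...) {
  cat(sprintf("<pit_session> M=%d m=%d b8=%s  total payload %d bits (CR %.4f)\n",
              x$M, x$m, x$b8_mode, sum(x$manifest$delta_bits),
              8 * x$M^2 / sum(x$manifest$delta_bits)))
  invisible(x)
}

#' Simulate the receiver: progressive reconstruction from a stream
#'
#' Replays the session with the shared bank. After each received plane the
#' image is reconstructed from the planes so far with midpoint quantization,
#' so stopping early yields exactly the coarse progressive-transmission
#' image; after all eight planes the reconstruction is the original image.
#' Each recovered plane is checked against the manifest checksum, so a
#' mismatched bank fails loudly naming the layer instead of corrupting the
#' image silently.
#'
#' @param session A `pit_session` from [pit_send()].
#' @param bank The same predictor bank the sender used.
#' @return List of 8 gray images, coarsest (1 plane) to exact (8 planes).
#' @export
pit_receive <- function(session, bank) {
  if (!inherits(session, "pit_session")) stop("expected a pit_session")
  M <- session$M
  stages <- vector("list", 8L)

  item <- session$stream[[1]]
  bits8 <- if (item$mode == "raw") {
    matrix(.cpp_unpack_bits(item$payload, item$n_bits), M, byrow = TRUE)
  } else whole_plane_arith_decode(item$payload, M)
  b8 <- bit_plane(bits8, 8L)
  check_plane(b8$bits, session$manifest$checksum[1], 8L)
  received <- bitplane_stack(list(b8))
  stages[[1]] <- bpm_reconstruct(received)

  for (layer in 7:1) {
    i <- 9L - layer
    item <- session$stream[[i]]
    synthetic <- predict_plane(bank, received, layer)
    res <- decompress_residual(item$payload)
    plane <- recover_plane(synthetic, res, layer = layer)
    check_plane(plane$bits, session$manifest$checksum[i], layer)
    received <- bitplane_stack(c(received$planes, list(plane)))
    stages[[i]] <- bpm_reconstruct(received)
  }
  stages
}

check_plane <- function(bits, expected, layer) {
  got <- plane_checksum(bits)
  if (!identical(got, expected))
    stop(sprintf(
      "checksum mismatch at layer b%d: sender %s, receiver %s (mismatched bank?)",
      layer, expected, got))
  invisible(TRUE)
}

#' Total payload size of a session
#'
#' @param session A `pit_session`.
#' @param include_headers Include the per-residual container headers.
#' @return Size in bits.
#' @export
session_payload_bits <- function(session, include_headers = FALSE) {
  bits <- sum(session$manifest$delta_bits)
  if (include_headers)
    bits <- bits + 8L * 15L * sum(session$manifest$mode == "residual")
  bits
}
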