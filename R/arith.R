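# R-level surface of the adaptive binary arithmetic coder (see src/arith.cpp
# for the bit-exact contract shared by encoder and decoder).

#' Adaptive binary arithmetic coding
#'
#' Order-0 adaptive coder over the binary alphabet: symbol counts start at
#' one and are updated after each coded bit, so no probability model is
#' transmitted. For near-constant input the output approaches the empirical
#' entropy within a few bytes of coder overhead; for incompressible input it
#' exceeds the input length only marginally.
#'
#' @param bits 0/1 vector (or matrix, flattened in raster scan order:
#'   row by row, left to right).
#' @return Raw vector of coded bytes (empty input codes to zero bytes).
#' @export
arith_encode <- function(bits) {
  if (is.matrix(bits)) bits <- as.vector(t(bits))
  .cpp_arith_encode(as.integer(bits))
}

#' @rdname arith_encode
#' @param bytes Raw vector produced by `arith_encode`.
#' @param n_bits Number of bits to decode (the coded length is not
#'   self-delimiting; callers carry it in their container header).
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
arith_decode <- function(bytes, n_bits) {
  if (!is.raw(bytes)) stop("arith_decode expects a raw vector")
  .cpp_arith_decode(bytes, as.integer(n_bits))
}
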