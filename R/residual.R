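# Residual bit-planes: elementwise disagreement between the true plane B and
# the predicted (synthetic) plane S, and its inversion at the receiver.

#' Construct a residual plane
#'
#' @param bits 0/1 matrix; 1 marks a position where prediction and truth
#'   disagree.
#' @param layer Target layer index in 1..7 (plane b8 is never predicted).
#' @return An object of class `residual_plane`.
#' @export
residual_plane <- function(bits, layer = 7L) {
  bits <- plane_bits(bits)
  layer <- as.integer(layer)
  if (length(layer) != 1L || layer < 1L || layer > 7L)
    stop("residual layer must be a single integer in 1..7")
  structure(list(bits = bits, layer = layer, side = nrow(bits)),
            class = "residual_plane")
}

#' @export
print.residual_plane <- function(x, ...) {
  cat(sprintf("<residual_plane> r%d, %d x %d, ER %.4f%%\n",
              x$layer, nrow(x$bits), ncol(x$bits), 100 * mean(x$bits)))
  invisible(x)
}

#' Residual between an original and a synthetic bit-plane
#'
#' The residual is 0 where the two planes agree and 1 where they differ —
#' the elementwise exclusive-or. Transmitting the residual in place of the
#' original plane is lossless because the receiver reproduces the same
#' synthetic plane and inverts the comparison with [recover_plane()].
#'
#' @param original The true bit-plane (a [bit_plane] or 0/1 matrix).
#' @param synthetic The predicted bit-plane, same shape (and layer, when both
#'   carry one).
#' @return A `residual_plane`.
#' @export
compute_residual <- function(original, synthetic) {
  layer <- NA_integer_
  if (inherits(original, "bit_plane") && inherits(synthetic, "bit_plane")) {
    if (original$layer != synthetic$layer)
      stop("layer mismatch between original and synthetic plane")
    layer <- original$layer
  } else if (inherits(original, "bit_plane")) layer <- original$layer
  else if (inherits(synthetic, "bit_plane")) layer <- synthetic$layer
  b <- plane_bits(original); s <- plane_bits(synthetic)
  if (!identical(dim(b), dim(s)))
    stop("shape mismatch between original and synthetic plane")
  x <- bitwXor(b, s); dim(x) <- dim(b)
  residual_plane(x, if (is.na(layer)) 7L else layer)
}

#' Recover the original bit-plane from the synthetic plane and the residual
#'
#' Where the residual is 0 the synthetic bit is kept; where it is 1 the bit is
#' flipped. `recover_plane(s, compute_residual(b, s))` equals `b` for every
#' pair of planes.
#'
#' @param synthetic Predicted bit-plane (a [bit_plane] or 0/1 matrix).
#' @param residual A `residual_plane` (or 0/1 matrix) of the same shape.
#' @param layer Layer to stamp on the result when `synthetic` is a bare
#'   matrix; defaults to the residual's layer.
#' @return A [bit_plane].
#' @export
recover_plane <- function(synthetic, residual, layer = NULL) {
  if (is.null(layer)) {
    layer <- if (inherits(synthetic, "bit_plane")) synthetic$layer
             else if (inherits(residual, "residual_plane")) residual$layer
             else 7L
  }
  s <- plane_bits(synthetic); r <- plane_bits(residual)
  if (!identical(dim(s), dim(r)))
    stop("shape mismatch between synthetic plane and residual")
  x <- bitwXor(s, r); dim(x) <- dim(s)
  bit_plane(x, layer)
}
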