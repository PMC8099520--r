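#' @useDynLib pitcodec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom sd
#' @importFrom utils write.csv
NULL

# ---- domain types -----------------------------------------------------------

#' Validate an 8-bit grayscale image
#'
#' A gray image is a plain numeric matrix whose entries are integers in
#' \[0, 255\]. Most functions in the package take and return such matrices;
#' this helper enforces the contract and returns the matrix in integer
#' storage mode.
#'
#' @param pixels A matrix of gray levels.
#' @return The validated matrix, storage mode `integer`.
#' @export
as_gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("gray image must be a matrix")
  if (anyNA(pixels)) stop("gray image contains NA")
  v <- as.vector(pixels)
  if (any(v != floor(v))) stop("gray image pixels must be integers")
  if (any(v < 0 | v > 255)) stop("gray image pixels must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  pixels
}

#' Construct a bit-plane
#'
#' @param bits 0/1 matrix.
#' @param layer Integer layer index in 1..8; layer 8 is the most significant
#'   plane (bit weight 128), layer 1 the least (weight 1).
#' @return An object of class `bit_plane` with fields `bits`, `layer`, `side`
#'   (the row count; planes may be rectangular, `side` names the documented
#'   square case).
#' @export
bit_plane <- function(bits, layer) {
  if (!is.matrix(bits)) stop("bit-plane bits must be a matrix")
  if (anyNA(bits) || !all(bits == 0L | bits == 1L))
    stop("bit-plane entries must be 0 or 1")
  layer <- as.integer(layer)
  if (length(layer) != 1L || layer < 1L || layer > 8L)
    stop("bit-plane layer must be a single integer in 1..8")
  storage.mode(bits) <- "integer"
  structure(list(bits = bits, layer = layer, side = nrow(bits)),
            class = "bit_plane")
}

#' @export
print.bit_plane <- function(x, ...) {
  cat(sprintf("<bit_plane> layer b%d, %d x %d, %.2f%% ones\n",
              x$layer, nrow(x$bits), ncol(x$bits), 100 * mean(x$bits)))
  invisible(x)
}

#' Construct a stack of bit-planes
#'
#' Planes must be contiguous and strictly descending starting at layer 8
#' (the progressive transmission order), and share their dimensions.
#'
#' @param planes List of [bit_plane] objects, layer 8 first.
#' @return An object of class `bitplane_stack` with fields `planes`, `layers`
#'   (integer vector, descending), `side`.
#' @export
bitplane_stack <- function(planes) {
  if (length(planes) < 1L) stop("bit-plane stack must hold at least one plane")
  layers <- vapply(planes, function(p) p$layer, integer(1))
  want <- seq.int(8L, by = -1L, length.out = length(planes))
  if (!identical(layers, want))
    stop("stack layers must be contiguous and descending from 8")
  dims <- vapply(planes, function(p) dim(p$bits), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all planes in a stack must share dimensions")
  structure(list(planes = planes, layers = layers, side = dims[1, 1]),
            class = "bitplane_stack")
}

#' @export
print.bitplane_stack <- function(x, ...) {
  cat(sprintf("<bitplane_stack> layers b%d..b%d, %d x %d\n",
              max(x$layers), min(x$layers),
              nrow(x$planes[[1]]$bits), ncol(x$planes[[1]]$bits)))
  invisible(x)
}

# fetch plane of a given layer from a stack, or NULL
stack_plane <- function(stack, layer) {
  i <- match(layer, stack$layers)
  if (is.na(i)) NULL else stack$planes[[i]]
}

# ---- operations -------------------------------------------------------------

#' Decompose an image into its eight bit-planes
#'
#' An 8-bit gray level is written as \eqn{\sum_{k=1}^{8} b_k 2^{k-1}}; plane
#' \eqn{b_8} carries the main content, \eqn{b_1} the subtle detail. Planes are
#' returned most-significant first, the order in which progressive
#' transmission sends them.
#'
#' @param image Gray image matrix (integers in 0..255).
#' @return A [bitplane_stack] holding layers 8 down to 1.
#' @export
#' @examples
#' img <- matrix(c(0L, 255L, 200L, 65L), 2, 2)
#' st <- decompose_bitplanes(img)
#' st$planes[[1]]$bits  # most significant plane
decompose_bitplanes <- function(image) {
  image <- as_gray_image(image)
  planes <- lapply(8:1, function(k) {
    bits <- bitwAnd(bitwShiftR(image, k - 1L), 1L)  # drops dim
    dim(bits) <- dim(image)
    bit_plane(bits, k)
  })
  bitplane_stack(planes)
}

#' Recompose an image from a complete bit-plane stack
#'
#' Exact inverse of [decompose_bitplanes()]: requires all eight layers.
#'
#' @param stack A [bitplane_stack] with layers 8..1.
#' @return Gray image matrix.
#' @export
recompose_bitplanes <- function(stack) {
  if (!inherits(stack, "bitplane_stack")) stop("expected a bitplane_stack")
  if (!identical(stack$layers, 8:1))
    stop("incomplete stack: recompose needs all layers 8..1")
  px <- 0L
  for (p in stack$planes) px <- px + p$bits * bitwShiftL(1L, p$layer - 1L)
  as_gray_image(px)
}

#' Progressive midpoint reconstruction from the top k bit-planes
#'
#' After receiving the top \eqn{k} planes, each pixel is known only up to an
#' interval of width \eqn{2^{8-k}}; the reconstruction represents it by the
#' interval midpoint \eqn{\mathrm{prefix} \cdot 2^{8-k} + 2^{8-k-1}}. With
#' one plane the representatives are 64 and 192; with two they are
#' 32, 96, 160, 224. At \eqn{k = 8} the reconstruction is exact and equals
#' [recompose_bitplanes()].
#'
#' @param stack A [bitplane_stack] holding layers 8..(9-k) for some k in 1..8.
#' @return Gray image matrix of interval representatives.
#' @export
#' @examples
#' img <- matrix(0:255, 16, 16)
#' st <- decompose_bitplanes(img)
#' top1 <- bitplane_stack(st$planes[1])
#' unique(as.vector(bpm_reconstruct(top1)))  # 64 and 192
bpm_reconstruct <- function(stack) {
  if (!inherits(stack, "bitplane_stack")) stop("expected a bitplane_stack")
  k <- length(stack$layers)
  prefix <- 0L
  for (p in stack$planes) prefix <- prefix + p$bits * bitwShiftL(1L, p$layer - 1L)
  if (k == 8L) return(as_gray_image(prefix))
  half <- bitwShiftL(1L, 8L - k - 1L)   # 2^(8-k-1)
  as_gray_image(prefix + half)
}
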