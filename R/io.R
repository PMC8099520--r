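# Image file I/O: 8-bit single-channel PNG, binary PGM (P5) and PBM (P4).
# PNG goes through the png package; the PNM formats are read and written
# directly (header in ASCII, samples binary, raster order row by row).

#' Read an 8-bit grayscale image
#'
#' Accepts single-channel 8-bit PNG or binary PGM (P5). Multi-channel inputs
#' and bit depths above 8 are rejected: the transmission scheme is defined
#' for 8-bit grayscale only.
#'
#' @param path File path; format inferred from content/extension.
#' @return Gray image matrix (integers 0..255).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  magic <- readBin(path, "raw", n = 2L)
  if (identical(magic, as.raw(c(0x89, 0x50)))) {
    arr <- png::readPNG(path, info = TRUE)
    depth <- attr(arr, "info")$bit.depth %||% 8L
    if (depth > 8L) stop("bit depths above 8 are rejected")
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] == 2L) arr <- arr[, , 1L]  # gray + alpha
      else stop("multi-channel PNG rejected: need single-channel grayscale")
    }
    return(as_gray_image(matrix(as.integer(round(arr * 255)),
                                nrow(arr), ncol(arr))))
  }
  if (identical(rawToChar(magic), "P5")) return(read_pgm(path))
  stop("unsupported image format (need 8-bit grayscale PNG or P5 PGM): ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an 8-bit grayscale image
#'
#' @param image Gray image matrix.
#' @param path Output path; `.png` writes PNG, `.pgm` binary PGM (P5).
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image / 255, path)
  } else if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    write_pgm(image, path)
  } else stop("unsupported extension (use .png or .pgm): ", path)
  invisible(path)
}

# PNM headers: magic, whitespace/comment-separated tokens.
read_pnm_tokens <- function(con, n) {
  toks <- character(0)
  while (length(toks) < n) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PNM header")
    if (ch == "#") { repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "\n") break
    }; next }
    if (grepl("[[:space:]]", ch)) next
    tok <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      tok <- paste0(tok, ch)
    }
    toks <- c(toks, tok)
  }
  as.integer(toks)
}

read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (magic != "P5") stop("not a binary PGM (P5) file: ", path)
  hdr <- read_pnm_tokens(con, 3L)  # width height maxval
  if (hdr[3] > 255L) stop("PGM maxval above 255 rejected (8-bit only)")
  n <- hdr[1] * hdr[2]
  px <- as.integer(readBin(con, "raw", n = n))
  if (length(px) < n) stop("truncated PGM raster")
  # raster is row by row; R matrices are column-major
  as_gray_image(t(matrix(px, nrow = hdr[1], ncol = hdr[2])))
}

write_pgm <- function(image, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(image), nrow(image)), con,
            eos = NULL)
  writeBin(as.raw(as.vector(t(image))), con)
  invisible(path)
}

#' Write a binary plane as PBM (P4)
#'
#' Exports a bit-plane or residual plane as a 1-bit PBM image for inspection
#' or for feeding the codec CLI. PBM paints 1-bits black; rows are packed
#' MSB-first and padded to byte boundaries.
#'
#' @param bits 0/1 matrix, or a [bit_plane] / residual plane object.
#' @param path Output path.
#' @export
write_pbm <- function(bits, path) {
  bits <- plane_bits(bits)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(sprintf("P4\n%d %d\n", ncol(bits), nrow(bits)), con, eos = NULL)
  for (r in seq_len(nrow(bits))) {
    row <- bits[r, ]
    pad <- (-length(row)) %% 8
    if (pad) row <- c(row, integer(pad))
    writeBin(.cpp_pack_bits(as.integer(row)), con)
  }
  invisible(path)
}

#' Read a PBM (P4) binary plane
#'
#' @param path PBM file path.
#' @return 0/1 integer matrix.
#' @export
read_pbm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (magic != "P4") stop("not a binary PBM (P4) file: ", path)
  hdr <- read_pnm_tokens(con, 2L)
  w <- hdr[1]; h <- hdr[2]
  bpr <- (w + 7L) %/% 8L
  raw <- readBin(con, "raw", n = bpr * h)
  if (length(raw) < bpr * h) stop("truncated PBM raster")
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    bits <- .cpp_unpack_bits(raw[((r - 1L) * bpr + 1L):(r * bpr)], 8L * bpr)
    out[r, ] <- bits[seq_len(w)]
  }
  out
}

# accept a bare 0/1 matrix or any classed plane with a $bits field
plane_bits <- function(x) {
  if (is.list(x) && !is.null(x$bits)) x <- x$bits
  if (!is.matrix(x)) stop("expected a 0/1 matrix or a plane object")
  if (anyNA(x) || !all(x == 0L | x == 1L)) stop("plane entries must be 0 or 1")
  storage.mode(x) <- "integer"
  x
}
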