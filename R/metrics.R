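# Evaluation metrics: error rate of a residual plane, compression ratio of a
# coded plane, and the proposed-vs-arithmetic benchmark harness.

#' Error rate of a residual bit-plane
#'
#' The percentage of 1-bits (prediction disagreements) in the plane:
#' \eqn{ER = 100 \cdot \epsilon / M^2} where \eqn{\epsilon} is the error-bit
#' count.
#'
#' @param residual A `residual_plane` or 0/1 matrix.
#' @return Error rate in percent.
#' @export
error_rate <- function(residual) {
  bits <- plane_bits(residual)
  100 * sum(bits) / length(bits)
}

#' Compression ratio
#'
#' Raw size over compressed size, \eqn{CR = M^2 / \delta}, with \eqn{\delta}
#' the compressed size in bits. Values above 1 mean the coded plane is
#' smaller than the raw plane.
#'
#' @param M Image side (raw plane is `M^2` bits).
#' @param delta Compressed size in bits; must be positive.
#' @return The ratio `M^2 / delta`.
#' @export
compression_ratio <- function(M, delta) {
  if (any(delta <= 0)) stop("compressed size delta must be positive")
  as.numeric(M)^2 / delta
}

#' Benchmark the block codec against whole-plane arithmetic coding
#'
#' Runs both compressors over per-layer residual planes and tabulates
#' error-bit counts, error rates, compressed sizes and compression ratios.
#'
#' @param residual_sets A list with one element per image; each element is a
#'   list of residual planes (`residual_plane` objects or 0/1 matrices) named
#'   or indexed by target layer 7..1. A single image's list is also accepted.
#' @param m Block size(s) for the proposed codec; a vector sweeps sizes.
#' @param methods Any of `"proposed"` and `"arithmetic"`.
#' @return A data frame with columns `image`, `layer`, `m`, `method`,
#'   `epsilon`, `ER`, `delta`, `CR` (one row per plane, method and block
#'   size; `m` is `NA` for the arithmetic baseline).
#' @seealso [benchmark_summary()] for per-layer and whole-image aggregation.
#' @export
run_benchmark <- function(residual_sets, m = 4L,
                          methods = c("proposed", "arithmetic")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(residual_sets) == 0L) stop("empty benchmark corpus")
  one <- residual_sets[[1]]
  if (is.matrix(one) || inherits(one, "residual_plane"))
    residual_sets <- list(residual_sets)   # a single image's plane list
  rows <- list()
  for (img in seq_along(residual_sets)) {
    planes <- residual_sets[[img]]
    lyrs <- resolve_layers(planes)
    for (j in seq_along(planes)) {
      bits <- plane_bits(planes[[j]])
      M <- nrow(bits)
      eps <- sum(bits)
      er <- 100 * eps / length(bits)
      if ("proposed" %in% methods) {
        for (mm in m) {
          cr <- compress_residual(bits, mm)
          rows[[length(rows) + 1L]] <- data.frame(
            image = img, layer = lyrs[j], m = as.integer(mm),
            method = "proposed", epsilon = eps, ER = er,
            delta = cr$delta_bits,
            CR = compression_ratio(M, cr$delta_bits))
        }
      }
      if ("arithmetic" %in% methods) {
        delta <- 8L * length(whole_plane_arith(bits))
        rows[[length(rows) + 1L]] <- data.frame(
          image = img, layer = lyrs[j], m = NA_integer_,
          method = "arithmetic", epsilon = eps, ER = er,
          delta = delta, CR = compression_ratio(M, delta))
      }
    }
  }
  do.call(rbind, rows)
}

resolve_layers <- function(planes) {
  lyrs <- vapply(seq_along(planes), function(j) {
    p <- planes[[j]]
    if (inherits(p, "residual_plane")) p$layer else NA_integer_
  }, integer(1))
  if (anyNA(lyrs)) {
    nm <- names(planes)
    if (!is.null(nm) && all(grepl("^r?[1-7]$", nm))) {
      lyrs <- as.integer(sub("^r", "", nm))
    } else lyrs[is.na(lyrs)] <- (7:1)[seq_along(planes)][is.na(lyrs)]
  }
  lyrs
}

#' Aggregate a benchmark table
#'
#' Produces per-layer mean ER/CR for each method (and block size), plus a
#' whole-image compression ratio: total raw bits over total compressed bits
#' across the seven coded planes plus the transmitted top plane — a ratio of
#' totals, not a mean of ratios.
#'
#' @param bench A table from [run_benchmark()].
#' @param M Image side.
#' @param b8_bits Cost in bits of transmitting the top plane per image
#'   (default `M^2`, i.e. raw).
#' @return A list with `per_layer` (data frame) and `whole_image` (data
#'   frame of per-method ratios).
#' @export
benchmark_summary <- function(bench, M, b8_bits = M^2) {
  # the arithmetic baseline has no block size; keep its rows under one key
  key <- paste(bench$method, ifelse(is.na(bench$m), "-", bench$m))
  per_layer <- do.call(rbind, lapply(split(bench, list(bench$layer, key),
                                           drop = TRUE), function(d) {
    data.frame(layer = d$layer[1], method = d$method[1], m = d$m[1],
               mean_ER = mean(d$ER), mean_CR = mean(d$CR),
               mean_delta = mean(d$delta))
  }))
  rownames(per_layer) <- NULL
  per_layer <- per_layer[order(per_layer$method, per_layer$m,
                               -per_layer$layer), ]
  n_img <- length(unique(bench$image))
  whole <- do.call(rbind, lapply(split(bench, key), function(d) {
    raw_bits <- n_img * (7 * M^2 + b8_bits)   # seven coded planes + top plane
    comp_bits <- sum(d$delta) + n_img * b8_bits
    data.frame(method = d$method[1], m = d$m[1],
               whole_image_CR = raw_bits / comp_bits)
  }))
  rownames(whole) <- NULL
  list(per_layer = per_layer, whole_image = whole)
}
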