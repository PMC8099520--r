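# Synthetic data: chest-radiograph-like phantoms and structured residual
# planes. The phantoms stand in for real chest films during training and
# evaluation: a smooth low-frequency background (soft tissue), two
# high-contrast elliptical fields (lungs) and curvilinear arcs (ribs), plus
# mild sensor noise. Their high bit-planes are smooth and their low planes
# texture-rich, which is the premise the whole prediction scheme rests on.

# 3x3 box smoothing with edge replication (used to correlate the noise field)
box_smooth3 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  p <- rbind(m[1, ], m, m[n, ]); p <- cbind(p[, 1], p, p[, k])
  (p[1:n, 1:k] + p[1:n, 2:(k + 1)] + p[1:n, 3:(k + 2)] +
   p[2:(n + 1), 1:k] + p[2:(n + 1), 2:(k + 1)] + p[2:(n + 1), 3:(k + 2)] +
   p[3:(n + 2), 1:k] + p[3:(n + 2), 2:(k + 1)] + p[3:(n + 2), 3:(k + 2)]) / 9
}

# bilinear upsampling of a coarse grid to side n (used for the background)
upsample_bilinear <- function(coarse, nr, nc) {
  cr <- nrow(coarse); cc <- ncol(coarse)
  xi <- seq(1, cr, length.out = nr)
  yi <- seq(1, cc, length.out = nc)
  x0 <- pmin(floor(xi), cr - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), cc - 1L); fy <- yi - y0
  a <- coarse[x0, y0, drop = FALSE]; b <- coarse[x0 + 1, y0, drop = FALSE]
  c_ <- coarse[x0, y0 + 1, drop = FALSE]; d <- coarse[x0 + 1, y0 + 1, drop = FALSE]
  fxm <- matrix(fx, nr, nc); fym <- matrix(fy, nr, nc, byrow = TRUE)
  a * (1 - fxm) * (1 - fym) + b * fxm * (1 - fym) +
    c_ * (1 - fxm) * fym + d * fxm * fym
}

#' Generate chest-phantom grayscale images
#'
#' Produces a reproducible corpus of 8-bit grayscale phantoms emulating the
#' statistical structure of chest radiographs: smooth anatomical background,
#' two lung-field-like elliptical regions with sharp boundaries, rib-like
#' high-contrast arcs, and mild additive Gaussian noise. The same seed gives
#' a bit-identical corpus.
#'
#' @param n_images Number of images.
#' @param side Image side; must be divisible by 16 so the images feed the
#'   predictors directly.
#' @param n_arcs Rib-like arcs per image.
#' @param n_blobs Elliptical fields per image (default 2, the two lungs).
#' @param noise_sd Additive noise standard deviation in gray levels.
#' @param bg_cells Side of the coarse grid generating the smooth background.
#' @param seed Integer seed.
#' @return List of gray image matrices.
#' @export
generate_phantoms <- function(n_images, side = 256L, n_arcs = 6L,
                              n_blobs = 2L, noise_sd = 2, bg_cells = 5L,
                              seed = 1L) {
  side <- as.integer(side)
  if (side %% 16L != 0L) stop("phantom side must be divisible by 16")
  if (n_images < 1L) stop("need at least one image")
  set.seed(seed)
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  lapply(seq_len(n_images), function(i) {
    # smooth background: coarse normal field, bilinearly upsampled,
    # plus a vertical illumination gradient
    coarse <- matrix(rnorm(bg_cells^2), bg_cells, bg_cells)
    img <- 110 + 45 * upsample_bilinear(coarse, side, side) +
      25 * (rows / side - 0.5)

    # lung-field ellipses: sharp sigmoid boundary gives strong edges
    for (b in seq_len(n_blobs)) {
      cx <- side * runif(1, 0.25, 0.75); cy <- side * runif(1, 0.3, 0.7)
      ax <- side * runif(1, 0.12, 0.22); ay <- side * runif(1, 0.18, 0.3)
      amp <- sample(c(-1, 1), 1) * runif(1, 35, 55)
      d <- sqrt(((cols - cx) / ax)^2 + ((rows - cy) / ay)^2)
      img <- img + amp / (1 + exp((d - 1) * 12))
    }

    # rib-like arcs: gaussian-profile stamps along circular arcs
    for (a in seq_len(n_arcs)) {
      r0 <- side * runif(1, 0.3, 0.6)
      cx <- side * runif(1, 0.2, 0.8); cy <- side * runif(1, -0.2, 0.4)
      th <- seq(runif(1, 0.2, 0.8) * pi, runif(1, 1.2, 1.8) * pi,
                length.out = 4L * side %/% 2L)
      amp <- sample(c(-1, 1), 1) * runif(1, 25, 45)
      wdt <- runif(1, 1, 2)
      px <- cy + r0 * sin(th); py <- cx + r0 * cos(th)
      keep <- px >= 1 & px <= side & py >= 1 & py <= side
      stamp_r <- max(1L, ceiling(2 * wdt))
      canvas <- matrix(0, side, side)
      for (j in which(keep)) {
        rr <- max(1L, floor(px[j] - stamp_r)):min(side, ceiling(px[j] + stamp_r))
        cc <- max(1L, floor(py[j] - stamp_r)):min(side, ceiling(py[j] + stamp_r))
        g <- exp(-((rr - px[j])^2 %o% rep(1, length(cc)) +
                   rep(1, length(rr)) %o% (cc - py[j])^2) / (2 * wdt^2))
        canvas[rr, cc] <- pmax(canvas[rr, cc], g)
      }
      img <- img + amp * canvas
    }

    if (noise_sd > 0) {
      # mildly correlated noise, as a blurred detector produces; white noise
      # would drive the two lowest bit-planes to identical coin-flip texture
      z <- box_smooth3(matrix(rnorm(side^2), side, side))
      img <- img + z / sd(z) * noise_sd
    }
    m <- matrix(pmin(pmax(round(img), 0), 255), side, side)
    as_gray_image(m)
  })
}

#' Fraction of 4-neighbour bit transitions in a plane
#'
#' A simple "busyness" measure: the share of horizontally and vertically
#' adjacent pixel pairs whose bits differ. Low planes of natural images are
#' busier than high planes.
#'
#' @param bits 0/1 matrix or plane object.
#' @return Transition fraction in `[0, 1]`.
#' @export
plane_busyness <- function(bits) {
  b <- plane_bits(bits)
  h <- b[, -1L, drop = FALSE] != b[, -ncol(b), drop = FALSE]
  v <- b[-1L, , drop = FALSE] != b[-nrow(b), , drop = FALSE]
  (sum(h) + sum(v)) / (length(h) + length(v))
}

# binary dilation by a square structuring element of radius r (max filter)
dilate_mask <- function(mask, r) {
  if (r < 1L) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    rd <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    cd <- max(1L, 1L - dc):min(nc, nc - dc)
    out[rd, cd] <- out[rd, cd] | mask[rs, cs]
  }
  out
}

# gradient-magnitude edge mask of a gray image; the absolute threshold sits
# well above the sensor-noise gradient floor so that only structural edges
# (blob boundaries, arcs) enter the mask, not background or noise speckle
edge_mask <- function(image, thresh = 12) {
  im <- as.double(image); dim(im) <- dim(image)
  gx <- cbind(im[, -1] - im[, -ncol(im)], 0)
  gy <- rbind(im[-1, ] - im[-nrow(im), ], 0)
  g <- sqrt(gx^2 + gy^2)
  g > thresh
}

#' Generate a structured residual plane
#'
#' Emulates the error geometry of the trained predictors: in `"clustered"`
#' mode error bits concentrate in the vicinity of image edges (the dilated
#' gradient mask of a reference phantom), in `"iid"` mode they fall
#' uniformly. In both modes the expected error rate equals `p`.
#'
#' @param side Plane side (square).
#' @param p Target error rate in `[0, 1]`.
#' @param mode `"clustered"` or `"iid"`.
#' @param edge_dilation Dilation radius of the edge mask (clustered mode).
#' @param reference Optional gray image supplying the edge structure; a
#'   phantom is generated when absent.
#' @param layer Layer stamped on the returned plane.
#' @param seed Integer seed.
#' @return A `residual_plane`.
#' @export
generate_residual <- function(side = 256L, p = 0.1,
                              mode = c("clustered", "iid"),
                              edge_dilation = 2L, reference = NULL,
                              layer = 7L, seed = 1L) {
  mode <- match.arg(mode)
  if (p < 0 || p > 1) stop("target error rate p must lie in [0, 1]")
  side <- as.integer(side)
  if (is.null(reference) && mode == "clustered")
    reference <- generate_phantoms(1L, side = max(side, 16L),
                                   seed = seed + 7919L)[[1]][1:side, 1:side]
  set.seed(seed)
  n <- side^2
  if (mode == "iid" || p %in% c(0, 1)) {
    bits <- matrix(rbinom(n, 1L, p), side, side)
    if (p == 0) bits[] <- 0L
    if (p == 1) bits[] <- 1L
    return(residual_plane(bits, layer))
  }
  em <- edge_mask(reference)
  if (!any(em)) {  # featureless reference: nothing to concentrate around
    bits <- matrix(rbinom(n, 1L, p), side, side)
    return(residual_plane(bits, layer))
  }
  # Elevated flip probability inside the dilated edge mask, near-zero
  # speckle outside; the split keeps the expected error rate exactly p.
  # The in-mask rate is capped at 0.5 — no predictor errs more often than a
  # coin flip, and a denser mask would create solid error regions that
  # compress as spurious uniform blocks. When the target rate needs more
  # errors than the mask can hold at that density, the edge vicinity is
  # widened (larger dilation radius) first: predictors failing harder fail
  # in a wider band around edges. Only when even a wide band cannot absorb
  # the errors does the excess spill across the background, which is how
  # real residuals lose their edge concentration as the error rate grows.
  r_dil <- as.integer(edge_dilation)
  p_out <- p / 50
  repeat {
    mask <- dilate_mask(em, r_dil)
    A <- sum(mask)
    p_in <- (p * n - p_out * (n - A)) / A
    if (p_in <= 0.5 || r_dil >= side %/% 4L) break
    r_dil <- r_dil + 1L
  }
  if (p_in > 0.5) { p_in <- 0.5; p_out <- (p * n - 0.5 * A) / (n - A) }
  if (p_in < p_out) { p_in <- p; p_out <- p }  # mask too large to concentrate
  probs <- ifelse(mask, p_in, p_out)
  bits <- matrix(rbinom(n, 1L, as.vector(probs)), side, side)
  residual_plane(bits, layer)
}
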