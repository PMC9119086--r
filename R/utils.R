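# Shared raster helpers. Image convention throughout: height x width
# matrices; pixel (x, y) = mat[y + 1, x + 1], 0-based continuous
# coordinates with pixel centers at integers.

#' Bilinear image sampling
#'
#' Samples `img` at continuous positions, returning `fill` outside the
#' image support.
#'
#' @param img height x width numeric matrix
#' @param x,y sample positions (0-based pixel coordinates)
#' @param fill value returned outside the image
#' @return numeric vector of samples
#' @export
bilinearSample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- rep(fill, length(x))
  ok <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1
  get <- function(xx, yy) {
    v <- rep(fill, length(xx))
    ins <- xx >= 0 & xx <= w - 1 & yy >= 0 & yy <= h - 1
    v[ins] <- img[cbind(yy[ins] + 1, xx[ins] + 1)]
    v
  }
  if (any(ok)) {
    xs <- x0[ok]; ys <- y0[ok]; gx <- fx[ok]; gy <- fy[ok]
    out[ok] <- (1 - gx) * (1 - gy) * get(xs, ys) +
      gx * (1 - gy) * get(xs + 1, ys) +
      (1 - gx) * gy * get(xs, ys + 1) +
      gx * gy * get(xs + 1, ys + 1)
  }
  out
}

# Isotropic Gaussian blur via EBImage (replicate-style boundary).
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- EBImage::gblur(EBImage::Image(img), sigma = sigma,
                        boundary = "replicate")
  matrix(EBImage::imageData(out), nrow(img), ncol(img))
}

# 2x2 block-mean downsampling (pads the last row/column by replication).
downsample2 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  h2 <- ceiling(h / 2); w2 <- ceiling(w / 2)
  idx <- function(i, n) pmin(i, n)
  (img[idx(2 * (1:h2) - 1, h), idx(2 * (1:w2) - 1, w), drop = FALSE] +
   img[idx(2 * (1:h2), h),     idx(2 * (1:w2) - 1, w), drop = FALSE] +
   img[idx(2 * (1:h2) - 1, h), idx(2 * (1:w2), w), drop = FALSE] +
   img[idx(2 * (1:h2), h),     idx(2 * (1:w2), w), drop = FALSE]) / 4
}

#' Phase-correlation translation between two images
#'
#' Integer-pixel global shift estimate from the cross-power spectrum;
#' optional coarse pre-alignment plumbing for grossly shifted stacks.
#'
#' @param fixed,moving equally sized matrices
#' @return integer `c(dx, dy)`: moving ~ fixed shifted by (dx, dy)
#' @export
phaseCorrelation <- function(fixed, moving) {
  stopifnot(identical(dim(fixed), dim(moving)))
  Fa <- fft(fixed); Fb <- fft(moving)
  cp <- Fa * Conj(Fb)
  denom <- pmax(Mod(cp), 1e-12)
  corr <- Re(fft(cp / denom, inverse = TRUE))
  peak <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  dy <- peak[1] - 1; dx <- peak[2] - 1
  if (dy > nrow(fixed) / 2) dy <- dy - nrow(fixed)
  if (dx > ncol(fixed) / 2) dx <- dx - ncol(fixed)
  c(dx = -dx, dy = -dy)
}

# deterministic seed substreams below 2^31
subSeed <- function(seed, k) {
  (as.integer(seed) * 1103L + k * 12347L) %% 2147480009L
}
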