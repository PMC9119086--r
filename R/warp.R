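# Control-point image deformation: rigid moving-least-squares warping and
# thin-plate-spline warping, both with backward mapping and bilinear
# resampling.

#' Construct a control-point set
#'
#' @param src,dst n x 2 matrices (or 2-column data.frames) of (x, y)
#'   source and target positions
#' @return a validated [ControlPointSet]
#' @export
controlPointSet <- function(src, dst) {
  new("ControlPointSet", src = as.matrix(src), dst = as.matrix(dst))
}

setMethod("show", "ControlPointSet", function(object) {
  cat(sprintf("ControlPointSet: %d control points, mean displacement %.2f px\n",
              nrow(object@src),
              if (nrow(object@src)) mean(sqrt(rowSums((object@dst - object@src)^2))) else 0))
})

#' Evaluate the rigid moving-least-squares map
#'
#' For every evaluation point v, fits the weighted rigid transform (weights
#' `1/|src_i - v|^(2*alphaW)`) that best carries `src` onto `dst` and
#' applies it to v. The map interpolates the control points and reproduces
#' any global rigid motion of the control points exactly. Points
#' coinciding with a source control point map to its target.
#'
#' @param cps a [ControlPointSet]
#' @param pts m x 2 matrix of evaluation points
#' @param alphaW weight falloff exponent
#' @return m x 2 matrix of mapped points
#' @export
mlsRigidMap <- function(cps, pts, alphaW = 1) {
  stopifnot(is(cps, "ControlPointSet"))
  validObject(cps)
  pts <- as.matrix(pts)
  n <- nrow(cps@src)
  if (n == 0) return(pts)
  # complex arithmetic: rotation = normalized sum w * qhat * conj(phat)
  p <- complex(real = cps@src[, 1], imaginary = cps@src[, 2])
  q <- complex(real = cps@dst[, 1], imaginary = cps@dst[, 2])
  v <- complex(real = pts[, 1], imaginary = pts[, 2])
  out <- complex(length(v))
  D <- outer(v, p, function(a, b) Mod(a - b))
  hit <- apply(D, 1, which.min)
  exact <- D[cbind(seq_along(v), hit)] < 1e-9
  W <- 1 / pmax(D, 1e-12)^(2 * alphaW)
  sw <- rowSums(W)
  ps <- as.complex(W %*% p) / sw
  qs <- as.complex(W %*% q) / sw
  if (n == 1) {
    # single handle: pure translation
    out <- v - p[1] + q[1]
  } else {
    mu <- vapply(seq_along(v), function(i) {
      sum(W[i, ] * (q - qs[i]) * Conj(p - ps[i]))
    }, complex(1))
    rot <- ifelse(Mod(mu) < 1e-14, complex(real = 1), mu / Mod(mu))
    out <- qs + rot * (v - ps)
  }
  out[exact] <- q[hit[exact]]
  cbind(x = Re(out), y = Im(out))
}

# Evaluate a backward map on a coarse grid and bilinearly interpolate it to
# every pixel; exact for affine maps.
gridBackwardMap <- function(h, w, gridStep, mapFun) {
  gx <- unique(c(seq(0, w - 1, by = gridStep), w - 1))
  gy <- unique(c(seq(0, h - 1, by = gridStep), h - 1))
  g <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  m <- mapFun(as.matrix(g))
  mx <- matrix(m[, 1], length(gy), length(gx), byrow = TRUE)
  my <- matrix(m[, 2], length(gy), length(gx), byrow = TRUE)
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), w)
  ix <- findInterval(px, gx, rightmost.closed = TRUE)
  iy <- findInterval(py, gy, rightmost.closed = TRUE)
  fx <- (px - gx[ix]) / pmax(gx[pmin(ix + 1, length(gx))] - gx[ix], 1e-12)
  fy <- (py - gy[iy]) / pmax(gy[pmin(iy + 1, length(gy))] - gy[iy], 1e-12)
  fx[ix >= length(gx)] <- 0; ix <- pmin(ix, length(gx) - 1)
  fy[iy >= length(gy)] <- 0; iy <- pmin(iy, length(gy) - 1)
  lerp <- function(M) {
    (1 - fx) * (1 - fy) * M[cbind(iy, ix)] +
      fx * (1 - fy) * M[cbind(iy, ix + 1)] +
      (1 - fx) * fy * M[cbind(iy + 1, ix)] +
      fx * fy * M[cbind(iy + 1, ix + 1)]
  }
  list(x = matrix(lerp(mx), h, w), y = matrix(lerp(my), h, w))
}

#' Warp an image by rigid moving least squares
#'
#' Deforms `image` so that content at `src` control points moves to `dst`.
#' The backward map (output position -> source position) is the rigid MLS
#' map interpolating dst -> src, evaluated on a grid of step `gridStep`
#' and bilinearly interpolated between nodes; pixels mapping outside the
#' source are filled with `fill`.
#'
#' @param image height x width matrix
#' @param cps a [ControlPointSet] (content moves src -> dst)
#' @param gridStep deformation-grid step in pixels
#' @param alphaW MLS weight falloff exponent
#' @param fill value for out-of-source pixels
#' @return the warped matrix
#' @export
mlsRigidWarp <- function(image, cps, gridStep = 8, alphaW = 1, fill = 0) {
  stopifnot(is.matrix(image), is(cps, "ControlPointSet"))
  validObject(cps)
  if (nrow(cps@src) == 0) return(image)
  h <- nrow(image); w <- ncol(image)
  back <- controlPointSet(cps@dst, cps@src)   # backward: dst -> src
  bm <- gridBackwardMap(h, w, gridStep,
                        function(p) mlsRigidMap(back, p, alphaW))
  matrix(bilinearSample(image, as.numeric(bm$x), as.numeric(bm$y), fill),
         h, w)
}

#' Random local distortion by four control points
#'
#' Splits the image into four quadrants by the central cross, samples one
#' control point per quadrant at least `margin` pixels from the quadrant
#' edges, displaces each by a uniform random vector in
#' \[-maxDisp, maxDisp\]^2, and applies the rigid MLS warp. Emulates the
#' nonlinear distortion introduced by section cutting.
#'
#' @param image height x width matrix (quadrants must admit the margin)
#' @param seed integer seed
#' @param maxDisp displacement bound in pixels
#' @param margin minimum distance from quadrant edges
#' @return list with the warped `image` and the ground-truth `cps`
#' @export
mlsRandomDistort <- function(image, seed, maxDisp = 20, margin = 50) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  qx <- c(0, floor(w / 2)); qy <- c(0, floor(h / 2))
  qw <- c(floor(w / 2), w - floor(w / 2))
  qh <- c(floor(h / 2), h - floor(h / 2))
  if (any(qw < 2 * margin) || any(qh < 2 * margin))
    stop("image too small for the quadrant margin")
  draws <- withr::with_seed(as.integer(seed), runif(16))
  src <- matrix(0, 4, 2)
  k <- 1
  for (iy in 1:2) for (ix in 1:2) {
    x0 <- qx[ix] + margin; x1 <- qx[ix] + qw[ix] - 1 - margin
    y0 <- qy[iy] + margin; y1 <- qy[iy] + qh[iy] - 1 - margin
    src[k, ] <- c(x0 + draws[k] * (x1 - x0), y0 + draws[k + 4] * (y1 - y0))
    k <- k + 1
  }
  disp <- matrix(draws[9:16] * 2 * maxDisp - maxDisp, 4, 2)
  cps <- controlPointSet(src, src + disp)
  list(image = mlsRigidWarp(image, cps), cps = cps)
}

#' Thin-plate-spline interpolation map
#'
#' Returns a function mapping points by the thin-plate spline
#' (`r^2 log r` kernel plus affine part) that carries `src` exactly onto
#' `dst`.
#'
#' @param cps a [ControlPointSet] with at least 3 non-collinear src points
#' @return function taking an m x 2 matrix and returning the mapped m x 2
#' @export
tpsMap <- function(cps) {
  stopifnot(is(cps, "ControlPointSet"))
  validObject(cps)
  src <- cps@src; dst <- cps@dst
  n <- nrow(src)
  if (n < 3) stop("thin-plate spline needs at least 3 control points")
  U <- function(r) ifelse(r < 1e-12, 0, r^2 * log(r))
  K <- U(as.matrix(dist(src)))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs), error = function(e)
    stop("degenerate (collinear) control-point configuration"))
  Wc <- coef[1:n, , drop = FALSE]
  Ac <- coef[n + 1:3, , drop = FALSE]
  function(pts) {
    pts <- as.matrix(pts)
    D <- U(outer(seq_len(nrow(pts)), seq_len(n), function(i, j)
      sqrt((pts[i, 1] - src[j, 1])^2 + (pts[i, 2] - src[j, 2])^2)))
    cbind(1, pts) %*% Ac + D %*% Wc
  }
}

#' Warp an image by a thin-plate spline
#'
#' Content at `src` moves to `dst`; resampling is backward (the TPS
#' interpolating dst -> src evaluated at every output pixel) with bilinear
#' sampling.
#'
#' @param image height x width matrix
#' @param cps a [ControlPointSet]
#' @param fill value for out-of-source pixels
#' @return the warped matrix
#' @export
tpsWarp <- function(image, cps, fill = 0) {
  stopifnot(is.matrix(image), is(cps, "ControlPointSet"))
  h <- nrow(image); w <- ncol(image)
  back <- tpsMap(controlPointSet(cps@dst, cps@src))
  pts <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), w))
  m <- back(pts)
  matrix(bilinearSample(image, m[, 1], m[, 2], fill), h, w)
}
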