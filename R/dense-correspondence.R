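# Dense descriptor flow between adjacent sections: per-pixel
# gradient-orientation descriptors matched by a truncated-L1 discrete
# energy, optimized coarse-to-fine with iterated conditional improvement.

#' Construct dense-flow energy parameters
#'
#' @param dataTrunc truncation of the L1 descriptor distance
#' @param eta displacement-magnitude weight
#' @param smoothWeight,smoothTrunc truncated-L1 pairwise weight and cap
#' @param searchRadius maximum |u|, |v| in pixels
#' @param levels pyramid depth (1 = single scale)
#' @param maxSweeps improvement sweeps per level
#' @return a validated [FlowParams]
#' @export
flowParams <- function(dataTrunc = 4 * 128 * 0.04, eta = 0.01,
                       smoothWeight = 2, smoothTrunc = 40,
                       searchRadius = 16L, levels = 3L, maxSweeps = 10L) {
  new("FlowParams", dataTrunc = dataTrunc, eta = eta,
      smoothWeight = smoothWeight, smoothTrunc = smoothTrunc,
      searchRadius = as.integer(searchRadius), levels = as.integer(levels),
      maxSweeps = as.integer(maxSweeps))
}

#' Per-pixel gradient-orientation descriptors
#'
#' Computes, for every pixel, a 128-dimensional histogram of gradient
#' orientations (4x4 spatial cells of 4x4 px over a 16x16 support, 8
#' orientation bins with soft assignment), L2-normalized, clipped at 0.2
#' and renormalized. Pixels with no gradient support get a zero
#' descriptor. Deterministic.
#'
#' @param image height x width grayscale matrix (at least 16x16)
#' @return a [DescriptorField]
#' @export
denseDescriptors <- function(image) {
  stopifnot(is.matrix(image))
  new("DescriptorField", data = .denseSiftCpp(image),
      dim = dim(image))
}

setMethod("show", "DescriptorField", function(object) {
  cat(sprintf("DescriptorField: %dx%d image, %d-d descriptors\n",
              object@dim[1], object@dim[2], ncol(object@data)))
})

setMethod("show", "FlowField", function(object) {
  cat(sprintf("FlowField: %dx%d, |u|<=%d, energy %.4g\n",
              nrow(object@u), ncol(object@u), object@searchRadius,
              object@energy))
})

checkGeom <- function(d1, d2) {
  stopifnot(is(d1, "DescriptorField"), is(d2, "DescriptorField"))
  if (!identical(d1@dim, d2@dim))
    stop("descriptor field geometries do not match")
}

#' Discrete flow energy
#'
#' `sum_p min(||s1(p) - s2(p + w(p))||_1, t) + sum_p eta (|u| + |v|) +
#'  sum_(p,q) min(a|u(p)-u(q)|, d) + min(a|v(p)-v(q)|, d)` over the
#' 4-neighborhood; displacements pointing outside the image pay the data
#' truncation t.
#'
#' @param d1,d2 [DescriptorField]s of the two sections
#' @param flow a [FlowField] (or list with integer matrices `u`, `v`)
#' @param params a [FlowParams]
#' @return the energy value
#' @export
flowEnergy <- function(d1, d2, flow, params = flowParams()) {
  checkGeom(d1, d2)
  u <- if (is(flow, "FlowField")) flow@u else flow$u
  v <- if (is(flow, "FlowField")) flow@v else flow$v
  if (!identical(dim(u), d1@dim) || !identical(dim(v), d1@dim))
    stop("flow geometry does not match the descriptor fields")
  .flowEnergyCpp(d1@data, d2@data, matrix(as.integer(u), nrow(u)),
                 matrix(as.integer(v), nrow(v)),
                 params@dataTrunc, params@eta, params@smoothWeight,
                 params@smoothTrunc)
}

# Downsample a descriptor field by averaging 2x2 pixel blocks and
# renormalizing each descriptor.
downsampleDescriptors <- function(d) {
  h <- d@dim[1]; w <- d@dim[2]
  h2 <- ceiling(h / 2); w2 <- ceiling(w / 2)
  D <- ncol(d@data)
  out <- matrix(0, h2 * w2, D)
  for (k in seq_len(D)) {
    out[, k] <- as.numeric(downsample2(matrix(d@data[, k], h, w)))
  }
  nrm <- sqrt(rowSums(out^2))
  nz <- nrm > 1e-12
  out[nz, ] <- out[nz, ] / nrm[nz]
  new("DescriptorField", data = out, dim = as.integer(c(h2, w2)))
}

#' Match two descriptor fields by coarse-to-fine discrete optimization
#'
#' Builds a descriptor pyramid, initializes the coarsest level with the
#' best constant displacement, and runs iterated-conditional-improvement
#' sweeps at every level (each accepted move strictly lowers the energy;
#' deterministic sweep order). The returned energy never exceeds that of
#' the zero flow.
#'
#' @param d1,d2 [DescriptorField]s of the two sections
#' @param params a [FlowParams]
#' @param window per-pixel move window (+- pixels) during refinement
#' @return a [FlowField]; attribute `"trace"` holds the per-sweep energy
#'   trace of the final level
#' @export
matchFlow <- function(d1, d2, params = flowParams(), window = 2L) {
  checkGeom(d1, d2)
  h <- d1@dim[1]; w <- d1@dim[2]
  levels <- max(1L, min(params@levels,
                        as.integer(floor(log2(min(h, w) / 8))) + 1L))
  pyr1 <- list(d1); pyr2 <- list(d2)
  if (levels > 1) for (l in 2:levels) {
    pyr1[[l]] <- downsampleDescriptors(pyr1[[l - 1]])
    pyr2[[l]] <- downsampleDescriptors(pyr2[[l - 1]])
  }
  u <- v <- NULL
  trace <- NULL
  for (l in levels:1) {
    dl1 <- pyr1[[l]]; dl2 <- pyr2[[l]]
    hl <- dl1@dim[1]; wl <- dl1@dim[2]
    rl <- max(1L, as.integer(ceiling(params@searchRadius / 2^(l - 1))))
    stride <- max(1L, as.integer(min(hl, wl) %/% 32))
    const <- .bestConstantFlowCpp(dl1@data, dl2@data, hl, wl, rl,
                                  params@dataTrunc, params@eta, stride)
    inits <- list(list(u = matrix(as.integer(const[1]), hl, wl),
                       v = matrix(as.integer(const[2]), hl, wl),
                       win = if (is.null(u)) rl else as.integer(window)))
    if (!is.null(u)) {
      # upsampled coarse solution, tried first
      inits <- c(list(list(
        u = matrix(as.integer(pmin(pmax(expandFlow(uPrev, hl, wl) * 2L, -rl), rl)), hl, wl),
        v = matrix(as.integer(pmin(pmax(expandFlow(vPrev, hl, wl) * 2L, -rl), rl)), hl, wl),
        win = as.integer(window))), inits)
    }
    best <- NULL
    for (ini in inits) {
      res <- .flowIcmCpp(dl1@data, dl2@data, ini$u, ini$v, ini$win, rl,
                         params@maxSweeps, params@dataTrunc, params@eta,
                         params@smoothWeight, params@smoothTrunc,
                         hl * wl <= 4096)
      if (is.null(best) ||
          res$trace[length(res$trace)] < best$trace[length(best$trace)] - 1e-12)
        best <- res
    }
    u <- best$u; v <- best$v
    trace <- best$trace
    uPrev <- u; vPrev <- v
  }
  # insurance: never worse than the zero flow
  zero <- matrix(0L, h, w)
  eFlow <- .flowEnergyCpp(d1@data, d2@data, u, v, params@dataTrunc,
                          params@eta, params@smoothWeight, params@smoothTrunc)
  eZero <- .flowEnergyCpp(d1@data, d2@data, zero, zero, params@dataTrunc,
                          params@eta, params@smoothWeight, params@smoothTrunc)
  if (eZero < eFlow) {
    res <- .flowIcmCpp(d1@data, d2@data, zero, zero, as.integer(window),
                       params@searchRadius, params@maxSweeps,
                       params@dataTrunc, params@eta, params@smoothWeight,
                       params@smoothTrunc, h * w <= 4096)
    u <- res$u; v <- res$v
    trace <- res$trace
    eFlow <- trace[length(trace)]
  }
  out <- new("FlowField", u = u, v = v, searchRadius = params@searchRadius,
             energy = eFlow)
  attr(out, "trace") <- trace
  out
}

# nearest-neighbor flow upsampling to (h, w)
expandFlow <- function(f, h, w) {
  ih <- pmin(((seq_len(h) - 1L) %/% 2L) + 1L, nrow(f))
  iw <- pmin(((seq_len(w) - 1L) %/% 2L) + 1L, ncol(f))
  f[ih, iw, drop = FALSE]
}

#' Exact global optimum of the flow energy on tiny instances
#'
#' Computes the certified global minimum of the discrete matching energy
#' by a frontier dynamic program over scanline label states. Feasible only
#' when `labels^width` stays small (e.g. 8x8 images at search radius 1).
#' Serves as an independent optimality reference for [matchFlow()].
#'
#' @param d1,d2 [DescriptorField]s
#' @param params a [FlowParams] (its `searchRadius` defines the label set)
#' @return the optimal energy value
#' @export
flowGlobalEnergy <- function(d1, d2, params = flowParams(searchRadius = 1L)) {
  checkGeom(d1, d2)
  .flowDpExactCpp(d1@data, d2@data, d1@dim[1], d1@dim[2],
                  params@searchRadius, params@dataTrunc, params@eta,
                  params@smoothWeight, params@smoothTrunc)
}

#' Sample grid-vertex correspondences inside a region mask
#'
#' Places a square grid (stride `spacing`, 0-based, starting at 0) and
#' emits, for every vertex p that falls on a selected pixel, the pair
#' (p, p + w(p)); targets outside the image are dropped.
#'
#' @param flow a [FlowField] from section i to i+1
#' @param mask logical matrix (or a [RegionMask]); `NULL` selects everything
#' @param spacing grid stride in pixels (>= 1)
#' @return data.frame with columns x1, y1, x2, y2
#' @export
gridCorrespondences <- function(flow, mask = NULL, spacing = 16) {
  stopifnot(is(flow, "FlowField"))
  if (spacing < 1) stop("spacing must be >= 1")
  h <- nrow(flow@u); w <- ncol(flow@u)
  if (is(mask, "RegionMask")) mask <- mask@mask
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  if (!identical(dim(mask), dim(flow@u)))
    stop("mask geometry does not match the flow")
  xs <- seq(0, w - 1, by = spacing)
  ys <- seq(0, h - 1, by = spacing)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  on <- mask[cbind(g$y + 1, g$x + 1)]
  g <- g[on, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  u <- flow@u[cbind(g$y + 1, g$x + 1)]
  v <- flow@v[cbind(g$y + 1, g$x + 1)]
  out <- data.frame(x1 = g$x, y1 = g$y, x2 = g$x + u, y2 = g$y + v)
  keep <- out$x2 >= 0 & out$x2 <= w - 1 & out$y2 >= 0 & out$y2 <= h - 1
  out[keep, , drop = FALSE]
}
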