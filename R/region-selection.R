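# Stable-region selection: membrane probability map -> watershed label map
# -> per-region roundness -> threshold mask.

#' Membrane probability map of a section image
#'
#' Method `"external"` validates and returns a user-supplied probability
#' map (the intended interface for deep-network segmentations computed
#' outside R). Method `"classical"` produces a dark-ridge response:
#' inverted intensity, band-pass smoothed (difference of Gaussians), and
#' rescaled to \[0, 1\].
#'
#' @param image height x width grayscale matrix
#' @param method `"classical"` or `"external"`
#' @param map for `"external"`: a matrix or path to a TIFF/PNG file with
#'   values in \[0, 1\] and the image's geometry
#' @param sigmaFine,sigmaCoarse band-pass scales (pixels) of the classical
#'   ridge detector
#' @return height x width probability matrix in \[0, 1\]
#' @export
segmentMembranes <- function(image, method = c("classical", "external"),
                             map = NULL, sigmaFine = 1, sigmaCoarse = 4) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (method == "external") {
    if (is.null(map)) stop("method 'external' needs a probability map")
    if (is.character(map)) map <- readSectionImage(map)
    if (!identical(dim(map), dim(image)))
      stop("external probability map geometry does not match the image")
    if (any(!is.finite(map)) || min(map) < 0 || max(map) > 1)
      stop("probability map values must be finite and in [0, 1]")
    return(map)
  }
  inv <- max(image) - image
  resp <- gaussianBlur(inv, sigmaFine) - gaussianBlur(inv, sigmaCoarse)
  resp[resp < 0] <- 0
  top <- max(resp)
  if (top < 1e-8) return(matrix(0, nrow(image), ncol(image)))
  resp / top
}

#' Watershed segmentation of a membrane probability map
#'
#' Floods the probability landscape from its regional minima (region
#' interiors) after suppressing shallow minima of depth below `h`;
#' watershed lines separating distinct regions are relabeled 0 and the
#' 4-connected regions renumbered contiguously from 1 in scan order.
#' Deterministic for fixed input.
#'
#' @param membranes probability matrix in \[0, 1\]
#' @param h minimum basin depth (h-minima suppression)
#' @return integer label matrix; 0 = membrane/boundary
#' @export
watershedRegions <- function(membranes, h = 0.1) {
  stopifnot(is.matrix(membranes))
  if (any(!is.finite(membranes)) || min(membranes) < 0 || max(membranes) > 1)
    stop("membrane probabilities must be finite and in [0, 1]")
  if (diff(range(membranes)) < 1e-9)
    return(matrix(1L, nrow(membranes), ncol(membranes)))
  inv <- 1 - membranes
  ws <- EBImage::watershed(EBImage::Image(inv), tolerance = h, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(ws)),
                nrow(membranes), ncol(membranes))
  # carve 0-valued lines between touching distinct regions
  h0 <- nrow(lab); w0 <- ncol(lab)
  boundary <- matrix(FALSE, h0, w0)
  dif <- function(a, b) a > 0 & b > 0 & a != b
  boundary[-h0, ] <- boundary[-h0, ] | dif(lab[-h0, ], lab[-1, ])
  boundary[-1, ] <- boundary[-1, ] | dif(lab[-1, ], lab[-h0, ])
  boundary[, -w0] <- boundary[, -w0] | dif(lab[, -w0], lab[, -1])
  boundary[, -1] <- boundary[, -1] | dif(lab[, -1], lab[, -w0])
  lab[boundary] <- 0L
  .ccLabel4Cpp(matrix(as.integer(lab > 0), h0, w0))
}

#' Radial boundary profile of a labeled region
#'
#' Takes the region's centroid as origin, bins boundary pixels by polar
#' angle into `nAngles` equal bins, and records the maximum boundary
#' distance per bin (lobes of non-star-convex shapes inflate high-order
#' Fourier content, which is what the roundness index penalizes). Empty
#' bins are filled by circular linear interpolation; more than 25% empty
#' bins is a degenerate region.
#'
#' @param labels integer label matrix
#' @param regionId positive region label
#' @param nAngles number of angular bins
#' @param allowBorder keep regions touching the image border (default they
#'   are an error, as their contour is a field-of-view artifact)
#' @return a [Contour] at latitude pi/2
#' @export
regionBoundaryRadius <- function(labels, regionId, nAngles = 64L,
                                 allowBorder = FALSE) {
  stopifnot(is.matrix(labels))
  sel <- which(labels == regionId, arr.ind = TRUE)
  if (!nrow(sel)) stop(sprintf("region %s does not exist", regionId))
  ys <- sel[, 1] - 1; xs <- sel[, 2] - 1
  h <- nrow(labels); w <- ncol(labels)
  if (!allowBorder && (any(xs == 0 | xs == w - 1 | ys == 0 | ys == h - 1)))
    stop(sprintf("region %s touches the image border", regionId))
  inReg <- matrix(FALSE, h, w)
  inReg[sel] <- TRUE
  pad <- function(dy, dx) {
    yy <- pmin(pmax(sel[, 1] + dy, 1), h)
    xx <- pmin(pmax(sel[, 2] + dx, 1), w)
    inReg[cbind(yy, xx)] & !(sel[, 1] + dy < 1 | sel[, 1] + dy > h |
                             sel[, 2] + dx < 1 | sel[, 2] + dx > w)
  }
  interior <- pad(-1, 0) & pad(1, 0) & pad(0, -1) & pad(0, 1)
  bx <- xs[!interior]; by <- ys[!interior]
  cx <- mean(xs); cy <- mean(ys)
  ang <- atan2(by - cy, bx - cx) %% (2 * pi)
  dist <- sqrt((bx - cx)^2 + (by - cy)^2)
  nAngles <- as.integer(nAngles)
  bin <- (round(ang / (2 * pi) * nAngles) %% nAngles) + 1L
  rho <- rep(NA_real_, nAngles)
  agg <- tapply(dist, bin, max)
  rho[as.integer(names(agg))] <- agg
  nEmpty <- sum(is.na(rho))
  if (nEmpty > 0.25 * nAngles)
    stop(sprintf("region %s is degenerate: %d of %d angular bins empty",
                 regionId, nEmpty, nAngles))
  if (nEmpty > 0) {   # circular linear interpolation across gaps
    idx <- which(!is.na(rho))
    th <- 2 * pi * (idx - 1L) / nAngles
    rho <- approx(c(th, th[1] + 2 * pi), c(rho[idx], rho[idx][1]),
                  xout = 2 * pi * (0:(nAngles - 1L)) / nAngles,
                  rule = 2)$y
  }
  new("Contour", angles = 2 * pi * (0:(nAngles - 1L)) / nAngles,
      radii = rho, origin = c(cx, cy), latitude = pi / 2)
}

#' Select stable round regions by roundness threshold
#'
#' Scores every labeled region with the Fourier roundness index (latitude
#' convention sin(phi0) = 1 for image regions) and keeps regions with
#' `R >= rThres` and area at least `minArea`; border-touching regions are
#' excluded by default. Filtering is deterministic, idempotent, and
#' monotone in the threshold.
#'
#' @param labels integer label matrix (from [watershedRegions()])
#' @param rThres roundness threshold (default 6)
#' @param minArea minimum region area in pixels
#' @param nAngles angular bins of the boundary profile
#' @param nHarm Fourier degrees scored
#' @param excludeBorder drop regions touching the image border
#' @return a [RegionMask]
#' @export
selectRegions <- function(labels, rThres = 6, minArea = 64, nAngles = 64L,
                          nHarm = 20L, excludeBorder = TRUE) {
  stopifnot(is.matrix(labels))
  ids <- sort(unique(as.integer(labels[labels > 0])))
  h <- nrow(labels); w <- ncol(labels)
  rep0 <- data.frame(label = integer(), area = integer(), cx = numeric(),
                     cy = numeric(), R = numeric(), capped = logical(),
                     border = logical(), kept = logical())
  mask <- matrix(FALSE, h, w)
  if (!length(ids))
    return(new("RegionMask", mask = mask, report = rep0, rThres = rThres,
               minArea = minArea))
  rows <- lapply(ids, function(id) {
    sel <- which(labels == id, arr.ind = TRUE)
    xs <- sel[, 2] - 1; ys <- sel[, 1] - 1
    border <- any(xs == 0 | xs == w - 1 | ys == 0 | ys == h - 1)
    out <- data.frame(label = id, area = nrow(sel), cx = mean(xs),
                      cy = mean(ys), R = NA_real_, capped = FALSE,
                      border = border, kept = FALSE)
    if (out$area < minArea || (border && excludeBorder)) return(out)
    ct <- try(regionBoundaryRadius(labels, id, nAngles,
                                   allowBorder = !excludeBorder),
              silent = TRUE)
    if (inherits(ct, "try-error")) return(out)
    ri <- roundnessIndex(contourFourier(ct, nHarm))
    out$R <- ri@R
    out$capped <- ri@capped
    out$kept <- ri@R >= rThres
    out
  })
  report <- do.call(rbind, rows)
  for (id in report$label[report$kept]) mask[labels == id] <- TRUE
  new("RegionMask", mask = mask, report = report, rThres = rThres,
      minArea = minArea)
}

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask: %d of %d regions kept (R >= %g, area >= %g), %d px selected\n",
              sum(object@report$kept), nrow(object@report), object@rThres,
              object@minArea, sum(object@mask)))
})
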