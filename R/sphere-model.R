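# Spherical deformation model: sampling local structures, cutting them into
# adjacent-section contour pairs, and rendering contours.

#' Construct spherical-deformation-model parameters
#'
#' @param p smoothness exponent (> 2); the model's variance law is
#'   `1/lambda_n = alpha + beta * (n^p - 2^p)`.
#' @param alpha global-shape precision (> 0)
#' @param beta local-shape precision (> 0)
#' @param nMax truncation degree of the harmonic series (>= 2). With p = 4
#'   the default 40 leaves a tail below 1e-5 of the total variance.
#' @param meanRadius mean structure radius in pixels (> 0)
#' @return a validated [ShapeParams] object
#' @examples
#' sp <- shapeParams(alpha = 1000, beta = 0.01)
#' lambdaVariance(2:6, sp)
#' @export
shapeParams <- function(p = 4, alpha = 1000, beta = 0.01, nMax = 40L,
                        meanRadius = 150) {
  new("ShapeParams", p = as.numeric(p), alpha = as.numeric(alpha),
      beta = as.numeric(beta), nMax = as.integer(nMax),
      meanRadius = as.numeric(meanRadius))
}

#' Construct an adjacent-section pair specification
#'
#' @param thickness section distance d in pixels
#' @param translation known (dx, dy) shift applied to the second section
#' @param nLandmarks number of equally spaced contour landmarks
#' @return a validated [SectionPairSpec]
#' @export
sectionPairSpec <- function(thickness = 40, translation = c(4.5, 4.5),
                            nLandmarks = 64L) {
  new("SectionPairSpec", thickness = as.numeric(thickness),
      translation = as.numeric(translation),
      nLandmarks = as.integer(nLandmarks))
}

#' Harmonic coefficient variance law
#'
#' `lambda_n = 1 / (alpha + beta * (n^p - 2^p))`: strictly positive and
#' non-increasing in n for valid parameters.
#'
#' @param n harmonic degree(s), each >= 2
#' @param params a [ShapeParams]
#' @return numeric vector of variances lambda_n
#' @export
lambdaVariance <- function(n, params) {
  stopifnot(is(params, "ShapeParams"))
  validObject(params)
  if (any(n < 2)) stop("degree n must be >= 2")
  1 / (params@alpha + params@beta * (n^params@p - 2^params@p))
}

# Flat coefficient layout: n = 2..nMax, within n the order m = -n..n.
coefOffsets <- function(nMax) {
  ns <- 2:nMax
  counts <- 2L * ns + 1L
  list(ns = ns, counts = counts, starts = cumsum(c(0L, counts[-length(counts)])))
}

# Real orthonormal spherical harmonics evaluated at (theta, phi):
# m < 0 -> k_n^|m| P_n^|m|(cos phi) cos(|m| theta)
# m = 0 -> k_n^0 P_n(cos phi)
# m > 0 -> k_n^m P_n^m(cos phi) sin(m theta)
# with k chosen so that sum_m phi_nm^2 = (2n+1)/(4 pi) (addition theorem).
# Returns an npts x ncoef basis matrix in the flat coefficient order.
harmonicBasis <- function(params, theta, phi) {
  stopifnot(length(theta) == length(phi))
  off <- coefOffsets(params@nMax)
  npts <- length(theta)
  B <- matrix(0, npts, sum(off$counts))
  x <- cos(phi)
  for (idx in seq_along(off$ns)) {
    n <- off$ns[idx]
    P <- pracma::legendre(n, x)          # (n+1) x npts, m = 0..n rows
    if (is.null(dim(P))) P <- matrix(P, ncol = 1)
    base <- off$starts[idx]
    k0 <- sqrt((2 * n + 1) / (4 * pi))
    B[, base + n + 1L] <- k0 * P[1L, ]
    for (m in 1:n) {
      km <- sqrt(2 * (2 * n + 1) / (4 * pi)) *
        exp(0.5 * (lgamma(n - m + 1) - lgamma(n + m + 1)))
      pm <- km * P[m + 1L, ]
      B[, base + n + 1L - m] <- pm * cos(m * theta)
      B[, base + n + 1L + m] <- pm * sin(m * theta)
    }
  }
  B
}

# Per-coefficient variances in the flat layout.
coefVariances <- function(params) {
  off <- coefOffsets(params@nMax)
  rep(lambdaVariance(off$ns, params), off$counts)
}

#' Draw a random harmonic surface
#'
#' Samples every coefficient `a_nm` independently from `N(0, lambda_n)`.
#' The draw is a pure function of `(params, seed)`.
#'
#' @param params a [ShapeParams]
#' @param seed integer seed
#' @return a [HarmonicShape]
#' @export
sampleShape <- function(params, seed) {
  stopifnot(is(params, "ShapeParams"))
  validObject(params)
  v <- coefVariances(params)
  a <- withr::with_seed(as.integer(seed), rnorm(length(v))) * sqrt(v)
  new("HarmonicShape", params = params, coeffs = a, seed = as.integer(seed))
}

#' Evaluate the normalized radius function
#'
#' `r(theta, phi) = 1 + sum_{n,m} a_nm phi_nm(theta, phi)`.
#'
#' @param shape a [HarmonicShape]
#' @param theta longitudes in \[0, 2*pi)
#' @param phi latitudes in \[0, pi\] (recycled against theta)
#' @return numeric vector of normalized radii
#' @export
evaluateRadius <- function(shape, theta, phi) {
  stopifnot(is(shape, "HarmonicShape"))
  if (any(theta < 0 | theta >= 2 * pi + 1e-12))
    stop("theta must lie in [0, 2*pi)")
  if (any(phi < 0 | phi > pi)) stop("phi must lie in [0, pi]")
  n <- max(length(theta), length(phi))
  theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  B <- harmonicBasis(shape@params, theta, phi)
  as.numeric(1 + B %*% shape@coeffs)
}

#' Latitudes of two parallel cutting planes
#'
#' The planes are placed symmetrically about the equator at distance d, so
#' `cos(phiS) = d / (2 meanRadius)`, `cos(phiT) = -d / (2 meanRadius)` and
#' `sin(phiS) == sin(phiT)` exactly (the symmetry the accuracy analysis
#' assumes).
#'
#' @param d plane distance (section thickness) in pixels, 0 <= d < 2*meanRadius
#' @param meanRadius mean structure radius in pixels
#' @return named numeric `c(phiS, phiT)`
#' @export
sectionLatitudes <- function(d, meanRadius) {
  if (d < 0) stop("thickness must be >= 0")
  if (d >= 2 * meanRadius)
    stop("planes at distance >= 2*meanRadius do not intersect the structure")
  c(phiS = acos(d / (2 * meanRadius)), phiT = acos(-d / (2 * meanRadius)))
}

#' Cut a harmonic surface at a fixed latitude
#'
#' The contour radius at longitude theta_i = 2*pi*i/N is
#' `rho_i = meanRadius * sin(phi) * r(theta_i, phi)` - the in-plane
#' projection of the radius vector.
#'
#' @param shape a [HarmonicShape]
#' @param phi cutting latitude in (0, pi)
#' @param nPoints number N of equally spaced samples (>= 4)
#' @param origin (x, y) contour origin in pixel coordinates
#' @return a [Contour]
#' @export
projectContour <- function(shape, phi, nPoints = 64L, origin = c(0, 0)) {
  stopifnot(is(shape, "HarmonicShape"))
  nPoints <- as.integer(nPoints)
  if (nPoints < 4L) stop("nPoints must be >= 4")
  if (abs(sin(phi)) < 1e-9)
    stop("degenerate contour: sin(phi) is zero at the pole")
  th <- 2 * pi * (0:(nPoints - 1L)) / nPoints
  r <- evaluateRadius(shape, th, rep(phi, nPoints))
  rho <- shape@params@meanRadius * sin(phi) * r
  new("Contour", angles = th, radii = rho, origin = as.numeric(origin),
      latitude = phi)
}

#' Simulate one adjacent-section contour pair
#'
#' Draws one shape, cuts it at the two symmetric latitudes for the given
#' thickness, and shifts the second contour's origin by the specification's
#' translation. Landmark i of both contours sits at the same longitude.
#'
#' @param params a [ShapeParams]
#' @param spec a [SectionPairSpec]
#' @param seed integer seed
#' @param origin (x, y) origin of the first contour
#' @return list with elements `S`, `T` (the two [Contour]s) and `shape`
#' @export
makeSectionPair <- function(params, spec, seed, origin = c(0, 0)) {
  stopifnot(is(spec, "SectionPairSpec"))
  validObject(spec)
  shape <- sampleShape(params, seed)
  lat <- sectionLatitudes(spec@thickness, params@meanRadius)
  S <- projectContour(shape, lat[["phiS"]], spec@nLandmarks, origin)
  Tc <- projectContour(shape, lat[["phiT"]], spec@nLandmarks,
                       origin + spec@translation)
  list(S = S, T = Tc, shape = shape)
}

# Radius profile lookup: circular linear interpolation of rho at angle a.
contourRadiusAt <- function(contour, a) {
  n <- length(contour@angles)
  th <- c(contour@angles, 2 * pi)
  rho <- c(contour@radii, contour@radii[1])
  a <- a %% (2 * pi)
  approx(th, rho, xout = a, rule = 2)$y
}

#' Rasterize a contour as a grayscale image
#'
#' Fills the star-shaped region bounded by the contour: light background,
#' dark interior, and a darker 2-px boundary band drawn just inside the
#' contour (so the non-background area equals the enclosed area). No
#' anti-aliasing, so the result is deterministic.
#'
#' @param contour a [Contour]
#' @param canvas (height, width) in pixels
#' @param fill named list of gray levels `background`, `interior`, `border`
#' @return a height x width numeric matrix in \[0, 1\]
#' @export
renderContourImage <- function(contour, canvas = c(256L, 256L),
                               fill = list(background = 0.85,
                                           interior = 0.55, border = 0.15)) {
  stopifnot(is(contour, "Contour"))
  h <- canvas[1]; w <- canvas[2]
  ox <- contour@origin[1]; oy <- contour@origin[2]
  rmax <- max(contour@radii)
  if (ox - rmax < -0.5 || oy - rmax < -0.5 ||
      ox + rmax > w - 0.5 || oy + rmax > h - 0.5)
    stop("contour exceeds the canvas bounds")
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  dx <- xs - ox; dy <- ys - oy
  dist <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  rho <- matrix(contourRadiusAt(contour, as.numeric(ang)), h, w)
  img <- matrix(fill$background, h, w)
  img[dist <= rho] <- fill$interior
  img[dist <= rho & rho - dist <= 2] <- fill$border
  img
}

#' Default simulation grid of (alpha, beta) subsets
#'
#' The synthetic study design spans 121 parameter subsets: an 11 x 11
#' logarithmic grid in alpha and beta at fixed p, covering near-circular
#' through visibly irregular structures.
#'
#' @param alphaValues,betaValues grid axis values
#' @param pairsPerSubset simulated pairs per subset in the full design
#' @return data.frame with columns subset, alpha, beta, pairsPerSubset
#' @export
sphericalDatasetGrid <- function(alphaValues = 10^seq(1, 5, length.out = 11),
                                 betaValues = 10^seq(-4, 0, length.out = 11),
                                 pairsPerSubset = 1000L) {
  g <- expand.grid(alpha = alphaValues, beta = betaValues,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(subset = seq_len(nrow(g)), g,
             pairsPerSubset = as.integer(pairsPerSubset))
}

#' @describeIn shapeParams display method
#' @param object a ShapeParams
#' @export
setMethod("show", "ShapeParams", function(object) {
  cat(sprintf(
    "ShapeParams: p=%g alpha=%g beta=%g nMax=%d meanRadius=%g px\n",
    object@p, object@alpha, object@beta, object@nMax, object@meanRadius))
})

setMethod("show", "HarmonicShape", function(object) {
  cat(sprintf("HarmonicShape: %d coefficients (n = 2..%d), seed %d\n",
              length(object@coeffs), object@params@nMax, object@seed))
})

setMethod("show", "Contour", function(object) {
  cat(sprintf(
    "Contour: %d samples, origin (%.2f, %.2f), latitude %.3f rad, mean radius %.2f px\n",
    length(object@radii), object@origin[1], object@origin[2],
    object@latitude, mean(object@radii)))
})
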