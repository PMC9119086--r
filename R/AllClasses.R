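#' @import methods
#' @importFrom stats rnorm runif sd var approx fft median dnorm dist
#' @importFrom utils head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib morphoreg, .registration = TRUE
NULL

# ---- spherical deformation model ------------------------------------------

#' Parameters of the spherical deformation model
#'
#' The surface of a local structure is `r(theta, phi) = 1 + sum a_nm phi_nm`,
#' with independent Gaussian coefficients `a_nm ~ N(0, lambda_n)` and
#' `1/lambda_n = alpha + beta * (n^p - 2^p)`. `p` controls smoothness,
#' `alpha` the global (low-degree) and `beta` the local (high-degree) shape
#' precision; `meanRadius` converts normalized radii to pixels.
#'
#' @slot p smoothness exponent, > 2 (dimensionless)
#' @slot alpha global-shape precision, > 0
#' @slot beta local-shape precision, > 0
#' @slot nMax truncation degree of the harmonic series, >= 2
#' @slot meanRadius mean radius of the structure in pixels, > 0
#' @exportClass ShapeParams
setClass("ShapeParams",
  representation(p = "numeric", alpha = "numeric", beta = "numeric",
                 nMax = "integer", meanRadius = "numeric"),
  prototype(p = 4, alpha = 1000, beta = 0.01, nMax = 40L, meanRadius = 150))

setValidity("ShapeParams", function(object) {
  msg <- NULL
  if (length(object@p) != 1 || !is.finite(object@p) || object@p <= 2)
    msg <- c(msg, "'p' must be a single finite value > 2")
  if (length(object@alpha) != 1 || !is.finite(object@alpha) || object@alpha <= 0)
    msg <- c(msg, "'alpha' must be a single finite value > 0")
  if (length(object@beta) != 1 || !is.finite(object@beta) || object@beta <= 0)
    msg <- c(msg, "'beta' must be a single finite value > 0")
  if (length(object@nMax) != 1 || object@nMax < 2L)
    msg <- c(msg, "'nMax' must be an integer >= 2")
  if (length(object@meanRadius) != 1 || !is.finite(object@meanRadius) ||
      object@meanRadius <= 0)
    msg <- c(msg, "'meanRadius' must be a single finite value > 0")
  if (is.null(msg)) TRUE else msg
})

#' A sampled harmonic surface
#'
#' Truncated real spherical-harmonic expansion of one local structure.
#' Coefficients are stored flat in the fixed order n = 2..nMax, m = -n..n.
#'
#' @slot params the generating [ShapeParams]
#' @slot coeffs flat numeric coefficient vector a_nm
#' @slot seed integer seed the shape was drawn with
#' @exportClass HarmonicShape
setClass("HarmonicShape",
  representation(params = "ShapeParams", coeffs = "numeric", seed = "integer"))

setValidity("HarmonicShape", function(object) {
  n <- object@params@nMax
  want <- sum(2L * (2:n) + 1L)
  if (length(object@coeffs) != want)
    return(sprintf("coefficient vector has length %d, expected %d",
                   length(object@coeffs), want))
  if (!all(is.finite(object@coeffs))) return("coefficients must be finite")
  TRUE
})

#' Geometry of an adjacent-section pair
#'
#' @slot thickness section distance d in pixels, 0 <= d < 2 * meanRadius
#' @slot translation known (dx, dy) shift of the second section, pixels
#' @slot nLandmarks number of equally spaced contour landmarks, >= 4
#' @exportClass SectionPairSpec
setClass("SectionPairSpec",
  representation(thickness = "numeric", translation = "numeric",
                 nLandmarks = "integer"),
  prototype(thickness = 40, translation = c(4.5, 4.5), nLandmarks = 64L))

setValidity("SectionPairSpec", function(object) {
  msg <- NULL
  if (length(object@thickness) != 1 || object@thickness < 0)
    msg <- c(msg, "'thickness' must be a single value >= 0")
  if (length(object@translation) != 2 || !all(is.finite(object@translation)))
    msg <- c(msg, "'translation' must be a finite length-2 vector")
  if (length(object@nLandmarks) != 1 || object@nLandmarks < 4L)
    msg <- c(msg, "'nLandmarks' must be an integer >= 4")
  if (is.null(msg)) TRUE else msg
})

#' Planar contour sampled at equally spaced polar angles
#'
#' Radii are distances from `origin` to the contour at angles `angles`
#' (counterclockwise from +x; x = column rightward, y = row downward,
#' 0-based continuous pixel coordinates). `latitude` records the cutting
#' latitude phi of the generating structure (pi/2 for real image regions).
#' Radii may be non-positive in the large-fluctuation regime of the model.
#'
#' @slot angles equally spaced angles in \[0, 2*pi)
#' @slot radii radius samples in pixels
#' @slot origin length-2 (x, y) origin
#' @slot latitude latitude phi in (0, pi)
#' @exportClass Contour
setClass("Contour",
  representation(angles = "numeric", radii = "numeric", origin = "numeric",
                 latitude = "numeric"))

setValidity("Contour", function(object) {
  n <- length(object@angles)
  if (n < 4) return("a contour needs at least 4 samples")
  if (length(object@radii) != n) return("angles and radii lengths differ")
  if (!all(is.finite(object@radii))) return("radii must be finite")
  step <- 2 * pi / n
  if (max(abs(diff(object@angles) - step)) > 1e-9 ||
      abs(object@angles[1]) > 1e-9)
    return("angles must be 2*pi*i/N for i = 0..N-1")
  if (length(object@origin) != 2 || !all(is.finite(object@origin)))
    return("origin must be a finite length-2 vector")
  if (length(object@latitude) != 1 || object@latitude <= 0 ||
      object@latitude >= pi)
    return("latitude must lie in (0, pi)")
  TRUE
})

# ---- accuracy theory -------------------------------------------------------

#' Fourier spectrum of a contour's normalized radius function
#'
#' @slot n harmonic degrees 1..nHarm
#' @slot bnc cosine coefficients
#' @slot bns sine coefficients
#' @slot bn squared magnitudes bnc^2 + bns^2
#' @slot sinPhi0 sine of the latitude used in the defining integral
#' @exportClass FourierSpectrum
setClass("FourierSpectrum",
  representation(n = "integer", bnc = "numeric", bns = "numeric",
                 bn = "numeric", sinPhi0 = "numeric"))

setValidity("FourierSpectrum", function(object) {
  k <- length(object@n)
  if (length(object@bnc) != k || length(object@bns) != k ||
      length(object@bn) != k)
    return("coefficient vectors must share the degree range")
  if (any(object@bn < 0)) return("bn must be non-negative")
  if (max(abs(object@bn - (object@bnc^2 + object@bns^2))) > 1e-12)
    return("bn must equal bnc^2 + bns^2")
  TRUE
})

#' Contour roundness index
#'
#' `R = -log(sum bn)`; capped at `-log(1e-12)` for numerically perfect
#' circles. Larger R means rounder.
#'
#' @slot R the index value (natural log scale)
#' @slot nHarm number of degrees summed
#' @slot capped TRUE if the perfect-circle cap was applied
#' @exportClass RoundnessIndex
setClass("RoundnessIndex",
  representation(R = "numeric", nHarm = "integer", capped = "logical"))

#' Translation estimate between two landmark sets
#'
#' @slot dt,ds estimated x and y translation in pixels
#' @slot nLandmarks number of landmark pairs used
#' @slot cost value of the squared-difference cost at the optimum
#' @exportClass TranslationEstimate
setClass("TranslationEstimate",
  representation(dt = "numeric", ds = "numeric", nLandmarks = "integer",
                 cost = "numeric"))

# ---- region selection ------------------------------------------------------

#' Stable-region selection result
#'
#' @slot mask logical matrix of selected pixels
#' @slot report per-region data.frame (label, area, cx, cy, R, capped,
#'   border, kept)
#' @slot rThres,minArea the thresholds that produced the mask
#' @exportClass RegionMask
setClass("RegionMask",
  representation(mask = "matrix", report = "data.frame", rThres = "numeric",
                 minArea = "numeric"))

# ---- dense correspondence --------------------------------------------------

#' Per-pixel gradient-orientation descriptor field
#'
#' One L2-normalized 128-vector (4x4 spatial cells x 8 orientation bins over
#' a 16x16 support) per pixel, rows indexed by pixel in column-major image
#' order.
#'
#' @slot data npixel x 128 numeric matrix
#' @slot dim image (height, width)
#' @exportClass DescriptorField
setClass("DescriptorField",
  representation(data = "matrix", dim = "integer"))

setValidity("DescriptorField", function(object) {
  if (nrow(object@data) != prod(object@dim))
    return("descriptor rows must match image pixels")
  TRUE
})

#' Parameters of the dense-flow discrete energy
#'
#' Data term: truncated L1 descriptor distance (truncation `dataTrunc`);
#' `eta` weights displacement magnitude; `smoothWeight`/`smoothTrunc` are
#' the truncated-L1 pairwise weight and cap over the 4-neighborhood.
#'
#' @slot dataTrunc data-term truncation t
#' @slot eta displacement-magnitude weight
#' @slot smoothWeight pairwise weight
#' @slot smoothTrunc pairwise truncation
#' @slot searchRadius maximum |u|, |v| in pixels
#' @slot levels pyramid depth
#' @slot maxSweeps maximum improvement sweeps per level
#' @exportClass FlowParams
setClass("FlowParams",
  representation(dataTrunc = "numeric", eta = "numeric",
                 smoothWeight = "numeric", smoothTrunc = "numeric",
                 searchRadius = "integer", levels = "integer",
                 maxSweeps = "integer"),
  prototype(dataTrunc = 4 * 128 * 0.04, eta = 0.01, smoothWeight = 2,
            smoothTrunc = 40, searchRadius = 16L, levels = 3L,
            maxSweeps = 10L))

setValidity("FlowParams", function(object) {
  if (object@dataTrunc < 0 || object@eta < 0 || object@smoothWeight < 0 ||
      object@smoothTrunc < 0)
    return("energy weights must be >= 0")
  if (object@searchRadius < 1L) return("searchRadius must be >= 1")
  if (object@levels < 1L) return("levels must be >= 1")
  TRUE
})

#' Integer displacement field between two sections
#'
#' `u`/`v` give, per pixel of the first section, the column/row displacement
#' of its match in the second section.
#'
#' @slot u,v integer displacement matrices
#' @slot searchRadius search radius the field was computed with
#' @slot energy value of the discrete matching energy
#' @exportClass FlowField
setClass("FlowField",
  representation(u = "matrix", v = "matrix", searchRadius = "integer",
                 energy = "numeric"))

setValidity("FlowField", function(object) {
  if (!identical(dim(object@u), dim(object@v)))
    return("u and v must share dimensions")
  if (max(abs(object@u), abs(object@v)) > object@searchRadius)
    return("displacements exceed the search radius")
  TRUE
})

# ---- stack optimization ----------------------------------------------------

#' Matched point pairs across adjacent sections
#'
#' @slot pairs data.frame with columns pair (index i of the (i, i+1) pair),
#'   x1, y1 (point in section i), x2, y2 (point in section i+1)
#' @slot nSections number of sections spanned
#' @exportClass CorrespondenceSet
setClass("CorrespondenceSet",
  representation(pairs = "data.frame", nSections = "integer"))

setValidity("CorrespondenceSet", function(object) {
  p <- object@pairs
  need <- c("pair", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(p))) return("pairs needs columns pair,x1,y1,x2,y2")
  if (nrow(p)) {
    if (!all(vapply(p[need], function(z) all(is.finite(z)), TRUE)))
      return("coordinates must be finite")
    if (any(p$pair < 1 | p$pair >= object@nSections))
      return("pair indices must lie in 1..nSections-1")
    for (i in unique(p$pair)) {
      sub <- p[p$pair == i, c("x1", "y1")]
      if (anyDuplicated(sub)) return("duplicate source points within a pair")
    }
  }
  TRUE
})

#' Parameters of the whole-stack displacement adjustment
#'
#' @slot lambda smoothness weight (>= 0); each within-section edge carries
#'   weight lambda/dist (or lambda*dist if `invDist` is FALSE)
#' @slot k mutual k-nearest-neighbor degree
#' @slot radius neighbor search radius in pixels
#' @slot invDist TRUE for lambda/dist edge weights (default)
#' @exportClass StackEnergyParams
setClass("StackEnergyParams",
  representation(lambda = "numeric", k = "integer", radius = "numeric",
                 invDist = "logical"),
  prototype(lambda = 1, k = 4L, radius = 48, invDist = TRUE))

setValidity("StackEnergyParams", function(object) {
  if (object@lambda < 0) return("lambda must be >= 0")
  if (object@k < 0L) return("k must be >= 0")
  if (object@radius <= 0) return("radius must be > 0")
  TRUE
})

#' Solution of the constrained displacement adjustment
#'
#' @slot points data.frame (section, x, y, u, v, chain): per control point,
#'   its displacement and the constraint chain it belongs to
#' @slot energy achieved quadratic energy
#' @slot residual max constraint residual (sup norm, pixels)
#' @slot nContradictions chains containing more than one point of a section
#' @exportClass DisplacementSolution
setClass("DisplacementSolution",
  representation(points = "data.frame", energy = "numeric",
                 residual = "numeric", nContradictions = "integer"))

# ---- warping ---------------------------------------------------------------

#' Control-point pairs for image warping
#'
#' @slot src n x 2 source positions (x, y)
#' @slot dst n x 2 target positions (x, y)
#' @exportClass ControlPointSet
setClass("ControlPointSet", representation(src = "matrix", dst = "matrix"))

setValidity("ControlPointSet", function(object) {
  if (ncol(object@src) != 2 || ncol(object@dst) != 2)
    return("src and dst must be n x 2 matrices")
  if (nrow(object@src) != nrow(object@dst))
    return("src and dst must have equal point counts")
  if (!all(is.finite(object@src)) || !all(is.finite(object@dst)))
    return("control points must be finite")
  if (nrow(object@src) && anyDuplicated(round(object@src, 9)))
    return("duplicate src control points")
  TRUE
})

# ---- phantom ---------------------------------------------------------------

#' Specification of a synthetic EM-like phantom stack
#'
#' Tubular structures are sequences of sphere-like cross-sections; each
#' tube's roundness is controlled by its own (alpha, beta) and its
#' section-to-section drift by `driftSd`.
#'
#' @slot nSections,height,width stack geometry
#' @slot tubes per-tube data.frame (alpha, beta, p, radius, driftSd, gray)
#' @slot noiseSd background Gaussian noise standard deviation (gray units)
#' @slot seed integer seed
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(nSections = "integer", height = "integer", width = "integer",
                 tubes = "data.frame", noiseSd = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@nSections < 2L) return("need at least 2 sections")
  if (object@height < 32L || object@width < 32L) return("canvas too small")
  need <- c("alpha", "beta", "p", "radius", "driftSd", "gray")
  if (!all(need %in% names(object@tubes)))
    return("tubes needs columns alpha,beta,p,radius,driftSd,gray")
  if (any(object@tubes$radius * 2 + 8 > min(object@height, object@width)))
    return("tubes do not fit the canvas")
  TRUE
})

#' Synthetic stack with ground truth
#'
#' @slot images grayscale stack, array (height, width, nSections), values
#'   in \[0, 1\]
#' @slot labels integer ground-truth label stack (0 = background/membrane)
#' @slot membranes ground-truth membrane indicator stack
#' @slot gtFlow list (one per adjacent pair) of (height, width, 2) arrays:
#'   true displacement from section i to i+1, NA where undefined
#' @slot gtTransforms per-section list of applied deformation descriptions
#' @slot tubeCenters list (per section) of n_tubes x 2 center matrices
#' @exportClass PhantomStack
setClass("PhantomStack",
  representation(images = "array", labels = "array", membranes = "array",
                 gtFlow = "list", gtTransforms = "list",
                 tubeCenters = "list"))

setValidity("PhantomStack", function(object) {
  d <- dim(object@images)
  if (length(d) != 3) return("images must be a 3-d array")
  if (!identical(dim(object@labels), d) ||
      !identical(dim(object@membranes), d))
    return("labels/membranes must match image geometry")
  if (length(object@gtFlow) != d[3] - 1L)
    return("gtFlow needs one entry per adjacent pair")
  TRUE
})
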