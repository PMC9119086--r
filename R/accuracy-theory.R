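# Registration-accuracy theory: radial covariance on the sphere, the closed
# form for the second moment of the translation estimate, Fourier-coefficient
# statistics of contour projections, and the roundness index.

# Legendre polynomials P_2..P_nMax at x, accumulated as
# sum_n lambda_n (2n+1)/(4 pi) P_n(x); three-term recursion, vectorized.
legendreSeries <- function(x, lambda, nMax) {
  out <- numeric(length(x))
  pm1 <- rep(1, length(x))   # P_0
  p0 <- x                    # P_1
  for (n in 2:nMax) {
    pn <- ((2 * n - 1) * x * p0 - (n - 1) * pm1) / n
    out <- out + lambda[n - 1] * (2 * n + 1) / (4 * pi) * pn
    pm1 <- p0
    p0 <- pn
  }
  out
}

#' Cosine of the spatial angle between two directions
#'
#' Dot product of the unit direction vectors
#' `omega(theta, phi) = (cos theta sin phi, sin theta sin phi, cos phi)`.
#'
#' @param theta1,phi1,theta2,phi2 spherical angles (radians); vectors recycle
#' @return cos(psi) in \[-1, 1\]
#' @export
spatialAngleCos <- function(theta1, phi1, theta2, phi2) {
  cp <- cos(phi1) * cos(phi2) +
    sin(phi1) * sin(phi2) * cos(theta1 - theta2)
  pmin(1, pmax(-1, cp))
}

#' Radial covariance of the spherical deformation model
#'
#' `Cov(r(w1), r(w2)) = sum_n lambda_n (2n+1)/(4 pi) P_n(cos psi)` - a
#' function of the spatial angle alone, by the addition theorem.
#'
#' @param cosPsi cosine(s) of the spatial angle, |cosPsi| <= 1
#' @param params a [ShapeParams]
#' @return covariance values (same shape as `cosPsi`)
#' @export
radialCovariance <- function(cosPsi, params) {
  stopifnot(is(params, "ShapeParams"))
  if (any(abs(cosPsi) > 1 + 1e-9)) stop("|cosPsi| must be <= 1")
  x <- pmin(pmax(cosPsi, -1), 1)   # argument order preserves dim()
  lam <- lambdaVariance(2:params@nMax, params)
  out <- legendreSeries(as.numeric(x), lam, params@nMax)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Closed-form second moment of the translation estimate
#'
#' For N landmarks at theta_i = 2*pi*i/N on the two symmetric cuts, the
#' x-axis estimation error has second moment
#' `meanRadius^2 sin^2(phi) / N^2 * sum_ij 2 cos(theta_i) cos(theta_j)
#'  (Cov_iTjT - Cov_iSjT)`,
#' where the covariances follow [radialCovariance()] across same-section and
#' cross-section direction pairs.
#'
#' @param params a [ShapeParams]
#' @param spec a [SectionPairSpec]
#' @return theoretical `E[(dt_hat - dt)^2]` in squared pixels
#' @export
theoreticalTranslationVariance <- function(params, spec) {
  stopifnot(is(params, "ShapeParams"), is(spec, "SectionPairSpec"))
  lat <- sectionLatitudes(spec@thickness, params@meanRadius)
  N <- spec@nLandmarks
  th <- 2 * pi * (0:(N - 1)) / N
  cTT <- radialCovariance(
    outer(th, th, function(a, b)
      spatialAngleCos(a, lat[["phiT"]], b, lat[["phiT"]])), params)
  cST <- radialCovariance(
    outer(th, th, function(a, b)
      spatialAngleCos(a, lat[["phiS"]], b, lat[["phiT"]])), params)
  ct <- cos(th)
  val <- params@meanRadius^2 * sin(lat[["phiS"]])^2 / N^2 *
    sum(outer(ct, ct) * 2 * (cTT - cST))
  max(val, 0)
}

#' Fourier spectrum of a contour
#'
#' Applies the Fourier transform to the contour's normalized radius
#' function: with `rnorm_i = rho_i / mean(rho)`,
#' `bns_n = sin(phi0)/pi * integral rnorm(theta) sin(n theta) dtheta`
#' (periodic trapezoid quadrature over the equally spaced samples), likewise
#' the cosine coefficients, and `bn = bnc^2 + bns^2`. Normalizing by the
#' mean radius makes the spectrum (and the roundness index) scale-invariant.
#'
#' @param contour a [Contour]
#' @param nHarm number of degrees (needs at least 2*nHarm+1 samples)
#' @return a [FourierSpectrum]
#' @export
contourFourier <- function(contour, nHarm = 20L) {
  stopifnot(is(contour, "Contour"))
  nHarm <- as.integer(nHarm)
  if (nHarm < 1L) stop("nHarm must be >= 1")
  N <- length(contour@radii)
  if (N < 2L * nHarm + 1L)
    stop("too few contour samples for the requested degrees (aliasing)")
  m <- mean(contour@radii)
  if (abs(m) < 1e-12) stop("contour mean radius is zero")
  rn <- contour@radii / m
  s0 <- sin(contour@latitude)
  dth <- 2 * pi / N
  ns <- 1:nHarm
  # equally spaced periodic samples: trapezoid == rectangle rule
  bns <- vapply(ns, function(n)
    s0 / pi * sum(rn * sin(n * contour@angles)) * dth, 0)
  bnc <- vapply(ns, function(n)
    s0 / pi * sum(rn * cos(n * contour@angles)) * dth, 0)
  new("FourierSpectrum", n = ns, bnc = bnc, bns = bns,
      bn = bnc^2 + bns^2, sinPhi0 = s0)
}

#' Variance of a contour Fourier coefficient under the shape model
#'
#' `kappa_n = Var(bns_n) = sin^2(phi0) sum_{l>=n} (k_l^n P_l^n(cos phi0))^2
#' lambda_l`. The default returns the leading `l = n` term,
#' `C_n lambda_n` - a good approximation whenever the variance law decays
#' fast past degree n; `exact = TRUE` sums the series to the truncation
#' degree.
#'
#' @param n Fourier degree, >= 2
#' @param params a [ShapeParams]
#' @param phi0 latitude of the projection (default equator)
#' @param exact sum the full series instead of the leading term
#' @return kappa_n
#' @export
kappaApprox <- function(n, params, phi0 = pi / 2, exact = FALSE) {
  stopifnot(is(params, "ShapeParams"))
  n <- as.integer(n)
  if (n < 2L) stop("degree n must be >= 2")
  x0 <- cos(phi0)
  term <- function(l) {
    P <- pracma::legendre(l, x0)[n + 1L]
    km <- sqrt(2 * (2 * l + 1) / (4 * pi)) *
      exp(0.5 * (lgamma(l - n + 1) - lgamma(l + n + 1)))
    (km * P)^2 * lambdaVariance(l, params)
  }
  ls <- if (exact) n:params@nMax else n
  sin(phi0)^2 * sum(vapply(ls, term, 0))
}

#' Roundness index of a contour spectrum
#'
#' `R = -log(sum_n bn)` (natural log). Large R means the normalized radius
#' function is spectrally flat, i.e. the contour is close to a circle. A
#' numerically perfect circle (sum below 1e-12) is capped at
#' `R = -log(1e-12) ~ 27.63` to keep the index finite and orderable.
#'
#' @param spectrum a [FourierSpectrum]
#' @return a [RoundnessIndex]
#' @export
roundnessIndex <- function(spectrum) {
  stopifnot(is(spectrum, "FourierSpectrum"))
  s <- sum(spectrum@bn)
  capped <- s < 1e-12
  new("RoundnessIndex", R = -log(max(s, 1e-12)),
      nHarm = length(spectrum@n), capped = capped)
}

setMethod("show", "FourierSpectrum", function(object) {
  cat(sprintf("FourierSpectrum: degrees 1..%d, sum(bn) = %.4g\n",
              max(object@n), sum(object@bn)))
})

setMethod("show", "RoundnessIndex", function(object) {
  cat(sprintf("RoundnessIndex: R = %.3f over %d degrees%s\n", object@R,
              object@nHarm, if (object@capped) " (capped: perfect circle)" else ""))
})
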