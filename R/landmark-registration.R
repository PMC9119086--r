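# Translation-only landmark registration of two contours and its Monte-Carlo
# error harness.

#' Landmark coordinates of a contour
#'
#' Landmark i is `(x, y) = origin + rho_i * (cos theta_i, sin theta_i)`.
#' Landmarks of two contours pair by shared angle index (same longitude),
#' never by nearest neighbor.
#'
#' @param contour a [Contour]
#' @return N x 2 matrix of (x, y) positions
#' @export
contourLandmarks <- function(contour) {
  stopifnot(is(contour, "Contour"))
  cbind(x = contour@origin[1] + contour@radii * cos(contour@angles),
        y = contour@origin[2] + contour@radii * sin(contour@angles))
}

asLandmarks <- function(l) {
  if (is(l, "Contour")) l <- contourLandmarks(l)
  l <- as.matrix(l)
  if (ncol(l) != 2 || !all(is.finite(l)))
    stop("landmarks must be a finite n x 2 matrix")
  l
}

#' Squared-difference registration cost
#'
#' `sum_i (x_iT - (x_iS + u))^2 + (y_iT - (y_iS + v))^2` for a probed
#' translation (u, v).
#'
#' @param ls,lt matched landmark sets (n x 2 matrices or [Contour]s)
#' @param u,v probed x and y translation in pixels
#' @return the cost (>= 0)
#' @export
registrationCost <- function(ls, lt, u, v) {
  ls <- asLandmarks(ls); lt <- asLandmarks(lt)
  if (nrow(ls) != nrow(lt)) stop("landmark sets must pair one-to-one")
  sum((lt[, 1] - (ls[, 1] + u))^2 + (lt[, 2] - (ls[, 2] + v))^2)
}

#' Closed-form translation estimate
#'
#' The exact minimizer of [registrationCost()]:
#' `dt = mean(x_iT - x_iS)`, `ds = mean(y_iT - y_iS)`.
#'
#' @param ls,lt matched landmark sets (n x 2 matrices or [Contour]s)
#' @return a [TranslationEstimate]
#' @export
estimateTranslation <- function(ls, lt) {
  ls <- asLandmarks(ls); lt <- asLandmarks(lt)
  if (nrow(ls) != nrow(lt)) stop("landmark sets must pair one-to-one")
  if (nrow(ls) < 1) stop("landmark sets are empty")
  dt <- mean(lt[, 1] - ls[, 1])
  ds <- mean(lt[, 2] - ls[, 2])
  new("TranslationEstimate", dt = dt, ds = ds, nLandmarks = nrow(ls),
      cost = registrationCost(ls, lt, dt, ds))
}

setMethod("show", "TranslationEstimate", function(object) {
  cat(sprintf("TranslationEstimate: (%.4f, %.4f) px from %d landmarks, cost %.4g\n",
              object@dt, object@ds, object@nLandmarks, object@cost))
})

#' Monte-Carlo error moments of the translation estimator
#'
#' Simulates `reps` adjacent-section pairs under the shape model, estimates
#' the translation of each with the closed-form estimator, and summarizes
#' the x-axis error `dt_hat - dt`: mean estimate, mean error, second moment,
#' and their standard errors. The harmonic basis at the two latitudes is
#' precomputed once, so the per-pair work is one Gaussian coefficient draw
#' plus the landmark estimator.
#'
#' @param params a [ShapeParams]
#' @param spec a [SectionPairSpec]
#' @param reps number of simulated pairs (>= 2)
#' @param seed integer seed
#' @return list with `meanDt`, `meanErr`, `secondMoment`, standard errors
#'   `seMean`, `seMoment`, and `reps`
#' @export
empiricalErrorMoment <- function(params, spec, reps = 2000L, seed = 1L) {
  stopifnot(is(params, "ShapeParams"), is(spec, "SectionPairSpec"))
  reps <- as.integer(reps)
  if (reps < 2L) stop("reps must be >= 2")
  lat <- sectionLatitudes(spec@thickness, params@meanRadius)
  N <- spec@nLandmarks
  th <- 2 * pi * (0:(N - 1)) / N
  BS <- harmonicBasis(params, th, rep(lat[["phiS"]], N))
  BT <- harmonicBasis(params, th, rep(lat[["phiT"]], N))
  vars <- coefVariances(params)
  A <- withr::with_seed(as.integer(seed),
                        matrix(rnorm(reps * length(vars)), reps))
  A <- sweep(A, 2, sqrt(vars), "*")
  rbar <- params@meanRadius
  sphi <- sin(lat[["phiS"]])
  rhoS <- rbar * sphi * (1 + A %*% t(BS))
  rhoT <- rbar * sin(lat[["phiT"]]) * (1 + A %*% t(BT))
  dt <- vapply(seq_len(reps), function(i) {
    ls <- cbind(rhoS[i, ] * cos(th), rhoS[i, ] * sin(th))
    lt <- cbind(spec@translation[1] + rhoT[i, ] * cos(th),
                spec@translation[2] + rhoT[i, ] * sin(th))
    estimateTranslation(ls, lt)@dt
  }, 0)
  err <- dt - spec@translation[1]
  list(meanDt = mean(dt), meanErr = mean(err),
       secondMoment = mean(err^2),
       seMean = sd(dt) / sqrt(reps),
       seMoment = sd(err^2) / sqrt(reps),
       reps = reps)
}
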