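# Synthetic EM-like stack generator: tubular structures rendered as
# sequences of sphere-like cross-sections, with ground-truth labels,
# membranes, deformations, and dense flow; plus evaluation metrics.

#' Construct a phantom specification
#'
#' Each tube is one harmonic surface whose cross-section drifts smoothly
#' through the stack; its roundness is governed by its own (alpha, beta)
#' (large alpha => near-circular) and its section-to-section center drift
#' by `driftSd` - round tubes are straighter by construction, mirroring
#' the stability of round structures in real tissue.
#'
#' @param nSections,height,width stack geometry
#' @param nTubes number of tubes; the first `round(roundFraction*nTubes)`
#'   are round/straight, the rest irregular/wandering
#' @param roundFraction fraction of round tubes
#' @param radiusRange tube radius range in pixels
#' @param noiseSd background Gaussian noise sd (gray units)
#' @param seed integer seed
#' @return a validated [PhantomSpec]
#' @export
phantomSpec <- function(nSections = 8L, height = 256L, width = 256L,
                        nTubes = 6L, roundFraction = 0.5,
                        radiusRange = c(16, 24), noiseSd = 0.02,
                        seed = 1L) {
  nRound <- round(roundFraction * nTubes)
  tubes <- withr::with_seed(as.integer(seed), {
    rad <- runif(nTubes, radiusRange[1], radiusRange[2])
    data.frame(
      alpha = ifelse(seq_len(nTubes) <= nRound, 2e4, 25),
      beta = ifelse(seq_len(nTubes) <= nRound, 1, 0.05),
      p = 4,
      radius = rad,
      driftSd = ifelse(seq_len(nTubes) <= nRound, 0.6, 2.5),
      gray = runif(nTubes, 0.4, 0.62))
  })
  new("PhantomSpec", nSections = as.integer(nSections),
      height = as.integer(height), width = as.integer(width),
      tubes = tubes, noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d sections of %dx%d, %d tubes, seed %d\n",
              object@nSections, object@height, object@width,
              nrow(object@tubes), object@seed))
})

setMethod("show", "PhantomStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("PhantomStack: %d sections of %dx%d\n", d[3], d[1], d[2]))
})

# smooth 2-octave value-noise texture in [-1, 1]
noiseTexture <- function(h, w, seed) {
  withr::with_seed(as.integer(seed), {
    t1 <- gaussianBlur(matrix(rnorm(h * w), h, w), 3)
    t2 <- gaussianBlur(matrix(rnorm(h * w), h, w), 8)
  })
  tx <- t1 / max(abs(t1)) + 0.5 * t2 / max(abs(t2))
  tx / max(abs(tx))
}

#' Generate an aligned phantom stack with ground truth
#'
#' Renders every tube's cross-section (dark 2-px membrane, textured
#' interior; texture rides along with the tube so adjacent sections share
#' matchable content), over a lightly textured noisy background. Ground
#' truth: per-section label and membrane maps, per-pair zero flow (the
#' stack is aligned by construction), identity transforms, and the tube
#' center tracks.
#'
#' @param spec a [PhantomSpec]
#' @return a [PhantomStack]
#' @export
generatePhantomStack <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@height; w <- spec@width; nz <- spec@nSections
  nt <- nrow(spec@tubes)
  # tube shapes, start positions and drift tracks
  shapes <- lapply(seq_len(nt), function(t)
    sampleShape(shapeParams(p = spec@tubes$p[t], alpha = spec@tubes$alpha[t],
                            beta = spec@tubes$beta[t], nMax = 30L,
                            meanRadius = spec@tubes$radius[t]),
                subSeed(spec@seed, t)))
  centers <- withr::with_seed(subSeed(spec@seed, 101L), {
    margin <- max(spec@tubes$radius) + 6
    pos <- matrix(0, nt, 2)
    placed <- 0
    tries <- 0
    while (placed < nt && tries < 4000) {
      cand <- c(runif(1, margin, w - 1 - margin),
                runif(1, margin, h - 1 - margin))
      dmin <- if (placed) min(sqrt(rowSums(sweep(pos[seq_len(placed), ,
                                                     drop = FALSE], 2,
                                                 cand)^2))) else Inf
      tries <- tries + 1
      if (dmin > 1.9 * max(spec@tubes$radius)) {
        placed <- placed + 1
        pos[placed, ] <- cand
      }
    }
    if (placed < nt) {
      warning("tube placement saturated; allowing overlaps")
      while (placed < nt) {
        placed <- placed + 1
        pos[placed, ] <- c(runif(1, margin, w - 1 - margin),
                           runif(1, margin, h - 1 - margin))
      }
    }
    drift <- array(rnorm(nt * 2 * (nz - 1)), c(nt, 2, nz - 1))
    list(pos = pos, drift = drift)
  })
  tracks <- vector("list", nz)
  tracks[[1]] <- centers$pos
  if (nz > 1) for (z in 2:nz)
    tracks[[z]] <- tracks[[z - 1]] +
      centers$drift[, , z - 1] * spec@tubes$driftSd
  bgTex <- noiseTexture(h, w, subSeed(spec@seed, 202L))
  tubeTex <- lapply(seq_len(nt), function(t)
    noiseTexture(h, w, subSeed(spec@seed, 300L + t)))
  secNoise <- withr::with_seed(subSeed(spec@seed, 203L),
                               array(rnorm(h * w * nz, sd = spec@noiseSd),
                                     c(h, w, nz)))
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  images <- array(0, c(h, w, nz))
  labels <- array(0L, c(h, w, nz))
  membranes <- array(0, c(h, w, nz))
  for (z in seq_len(nz)) {
    img <- 0.8 + 0.06 * bgTex
    lab <- matrix(0L, h, w)
    mem <- matrix(0, h, w)
    # latitude wobbles slowly along z: adjacent sections stay similar
    for (t in seq_len(nt)) {
      phi <- pi / 2 + 0.25 * sin(2 * pi * z / nz + t)
      ct <- projectContour(shapes[[t]], phi, 96L, tracks[[z]][t, ])
      cx <- ct@origin[1]; cy <- ct@origin[2]
      rmax <- max(ct@radii) + 2
      x0 <- max(1, floor(cx - rmax)); x1 <- min(w, ceiling(cx + rmax) + 1)
      y0 <- max(1, floor(cy - rmax)); y1 <- min(h, ceiling(cy + rmax) + 1)
      if (x0 > x1 || y0 > y1) next
      sub <- cbind(as.numeric(ys[y0:y1, x0:x1]), as.numeric(xs[y0:y1, x0:x1]))
      dx <- sub[, 2] - cx; dy <- sub[, 1] - cy
      dist <- sqrt(dx^2 + dy^2)
      rho <- contourRadiusAt(ct, atan2(dy, dx))
      inside <- dist <= rho
      ring <- abs(dist - rho) <= 1
      idx <- cbind(sub[, 1] + 1, sub[, 2] + 1)
      # interior texture sampled in tube-local coordinates
      texv <- bilinearSample(tubeTex[[t]],
                            (dx %% (w - 1)), (dy %% (h - 1)), 0)
      img[idx[inside, , drop = FALSE]] <-
        spec@tubes$gray[t] + 0.08 * texv[inside]
      img[idx[ring, , drop = FALSE]] <- 0.12
      lab[idx[inside & !ring, , drop = FALSE]] <- t
      mem[idx[ring, , drop = FALSE]] <- 1
    }
    images[, , z] <- pmin(pmax(img + secNoise[, , z], 0), 1)
    labels[, , z] <- lab
    membranes[, , z] <- mem
  }
  gtFlow <- lapply(seq_len(max(nz - 1, 0)), function(i)
    array(0, c(h, w, 2)))
  new("PhantomStack", images = images, labels = labels,
      membranes = membranes, gtFlow = gtFlow,
      gtTransforms = rep(list(list(type = "identity")), nz),
      tubeCenters = tracks)
}

# Backward map closures -------------------------------------------------

# rotation by ang (radians) about image center c, then shift by s:
# deformed(p) = aligned(g(p)), g(p) = R(-ang) (p - c - s) + c
affineBackwardMap <- function(ang, shift, center) {
  force(ang); force(shift); force(center)
  function(p) {
    p <- as.matrix(p)
    dx <- p[, 1] - center[1] - shift[1]
    dy <- p[, 2] - center[2] - shift[2]
    cbind(cos(-ang) * dx - sin(-ang) * dy + center[1],
          sin(-ang) * dx + cos(-ang) * dy + center[2])
  }
}

composeMaps <- function(outer, inner) {
  # deformed2(p) = deformed1(inner(p)), deformed1(q) = aligned(outer(q))
  force(outer); force(inner)
  function(p) outer(inner(p))
}

# Invert a smooth backward map numerically (vectorized Newton with
# finite-difference Jacobian): solves g(q) = a for q.
invertMap <- function(g, a, init = a, iters = 25, tol = 1e-8) {
  q <- as.matrix(init)
  a <- as.matrix(a)
  if (!nrow(a)) return(q)
  hstep <- 0.5
  for (it in seq_len(iters)) {
    f <- g(q) - a
    if (max(abs(f)) < tol) break
    gx1 <- g(cbind(q[, 1] + hstep, q[, 2]))
    gx0 <- g(cbind(q[, 1] - hstep, q[, 2]))
    gy1 <- g(cbind(q[, 1], q[, 2] + hstep))
    gy0 <- g(cbind(q[, 1], q[, 2] - hstep))
    j11 <- (gx1[, 1] - gx0[, 1]) / (2 * hstep)
    j21 <- (gx1[, 2] - gx0[, 2]) / (2 * hstep)
    j12 <- (gy1[, 1] - gy0[, 1]) / (2 * hstep)
    j22 <- (gy1[, 2] - gy0[, 2]) / (2 * hstep)
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-12] <- 1e-12
    q <- q - cbind(( j22 * f[, 1] - j12 * f[, 2]) / det,
                   (-j21 * f[, 1] + j11 * f[, 2]) / det)
  }
  q
}

#' Apply a serial deformation protocol to an aligned stack
#'
#' Protocol `"fibsem"`: every section is rotated by a random angle
#' (uniform in +-rotRange degrees) and shifted uniformly in
#' +-shiftRange px; in addition, every `mlsEvery`-th section (0-based
#' index 0, mlsEvery, 2*mlsEvery, ...) receives a random four-control-point
#' rigid-MLS distortion. Protocol `"cremi"`: every section is deformed by
#' a thin-plate spline with `tpsN` random vectors (components
#' `N(0, tpsSigma^2)`) at uniform random positions. Ground-truth
#' transforms and the recomputed dense flow between adjacent deformed
#' sections are returned.
#'
#' @param stack a [PhantomStack] (aligned)
#' @param protocol `"fibsem"` or `"cremi"`
#' @param seed integer seed
#' @param rotRange rotation bound in degrees
#' @param shiftRange shift bound in pixels
#' @param mlsEvery MLS-distortion period in sections (0 disables)
#' @param mlsMaxDisp MLS control-point displacement bound in pixels
#' @param tpsSigma,tpsN TPS protocol vector scale (px) and count
#' @return a deformed [PhantomStack]
#' @export
applySerialDeformation <- function(stack, protocol = c("fibsem", "cremi"),
                                   seed = 1L, rotRange = 90,
                                   shiftRange = 100, mlsEvery = 5L,
                                   mlsMaxDisp = 20, tpsSigma = 10,
                                   tpsN = 8L) {
  stopifnot(is(stack, "PhantomStack"))
  protocol <- match.arg(protocol)
  d <- dim(stack@images)
  h <- d[1]; w <- d[2]; nz <- d[3]
  center <- c((w - 1) / 2, (h - 1) / 2)
  maps <- vector("list", nz)
  transforms <- vector("list", nz)
  for (z in seq_len(nz)) {
    szSeed <- subSeed(seed, 400L + z)
    if (protocol == "fibsem") {
      pars <- withr::with_seed(szSeed, runif(3))
      ang <- (pars[1] * 2 - 1) * rotRange * pi / 180
      shift <- (pars[2:3] * 2 - 1) * shiftRange
      g <- affineBackwardMap(ang, shift, center)
      tr <- list(type = "fibsem", angle = ang, shift = shift)
      if (mlsEvery > 0 && (z - 1) %% mlsEvery == 0 && mlsMaxDisp > 0 &&
          min(h, w) >= 2 * 2 * 50) {
        dst <- mlsRandomDistort(matrix(0, h, w), subSeed(seed, 900L + z),
                                maxDisp = mlsMaxDisp)
        gm <- local({
          back <- controlPointSet(dst$cps@dst, dst$cps@src)
          function(p) mlsRigidMap(back, p)
        })
        g <- composeMaps(g, gm)
        tr$mlsCps <- dst$cps
      }
    } else {
      pars <- withr::with_seed(szSeed, {
        list(pos = cbind(runif(tpsN, 20, w - 21), runif(tpsN, 20, h - 21)),
             vec = matrix(rnorm(2 * tpsN, sd = tpsSigma), tpsN, 2))
      })
      cps <- controlPointSet(pars$pos, pars$pos + pars$vec)
      tr <- list(type = "cremi", tpsCps = cps)
      if (max(abs(pars$vec)) < 1e-12) {
        g <- function(p) as.matrix(p)
      } else {
        g <- tpsMap(controlPointSet(cps@dst, cps@src))
      }
    }
    maps[[z]] <- g
    transforms[[z]] <- tr
  }
  # resample sections through the backward maps
  px <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), w))
  images <- array(0, d); labels <- array(0L, d); membranes <- array(0, d)
  tubeCenters <- stack@tubeCenters
  for (z in seq_len(nz)) {
    m <- maps[[z]](px)
    images[, , z] <- matrix(bilinearSample(stack@images[, , z],
                                           m[, 1], m[, 2]), h, w)
    # nearest-neighbor for labels/membranes
    xr <- round(m[, 1]); yr <- round(m[, 2])
    ok <- xr >= 0 & xr <= w - 1 & yr >= 0 & yr <= h - 1
    lz <- integer(h * w)
    lz[ok] <- stack@labels[, , z][cbind(yr[ok] + 1, xr[ok] + 1)]
    labels[, , z] <- matrix(lz, h, w)
    mz <- numeric(h * w)
    mz[ok] <- stack@membranes[, , z][cbind(yr[ok] + 1, xr[ok] + 1)]
    membranes[, , z] <- matrix(mz, h, w)
    # deformed tube centers: invert the backward map at the track points
    if (length(tubeCenters) >= z && !is.null(tubeCenters[[z]]))
      tubeCenters[[z]] <- invertMap(maps[[z]], tubeCenters[[z]],
                                    init = tubeCenters[[z]])
  }
  # ground-truth flow on a dense grid: p in deformed z matches
  # q = g_{z+1}^{-1}(g_z(p)) in deformed z+1
  gtFlow <- vector("list", max(nz - 1, 0))
  for (z in seq_len(nz - 1)) {
    aligned <- maps[[z]](px)
    q <- invertMap(maps[[z + 1]], aligned, init = aligned)
    fx <- matrix(q[, 1] - px[, 1], h, w)
    fy <- matrix(q[, 2] - px[, 2], h, w)
    gtFlow[[z]] <- array(c(fx, fy), c(h, w, 2))
  }
  out <- new("PhantomStack", images = images, labels = labels,
             membranes = membranes, gtFlow = gtFlow,
             gtTransforms = transforms, tubeCenters = tubeCenters)
  attr(out, "maps") <- maps
  out
}

#' Structural similarity index of two images
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03, over the given dynamic range; returns the mean SSIM map
#' value in \[-1, 1\].
#'
#' @param image,reference equally sized matrices
#' @param dynamicRange data range L (1 for \[0, 1\] images)
#' @return the SSIM score
#' @export
ssimScore <- function(image, reference, dynamicRange = 1) {
  if (!identical(dim(image), dim(reference)))
    stop("image geometries do not match")
  C1 <- (0.01 * dynamicRange)^2
  C2 <- (0.03 * dynamicRange)^2
  g <- function(m) gaussianSsimFilter(m)
  mu1 <- g(image); mu2 <- g(reference)
  s11 <- g(image^2) - mu1^2
  s22 <- g(reference^2) - mu2^2
  s12 <- g(image * reference) - mu1 * mu2
  mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
       ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
}

# separable 11x11 Gaussian (sigma 1.5) with replicated borders
gaussianSsimFilter <- function(m) {
  k <- dnorm(-5:5, sd = 1.5)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  padIdx <- function(n) pmin(pmax(1:(n + 10) - 5, 1), n)
  mp <- m[padIdx(h), padIdx(w)]
  rowf <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
  rowf <- rowf[6:(h + 5), , drop = FALSE]
  colf <- t(apply(rowf, 1, function(row) stats::filter(row, k, sides = 2)))
  colf[, 6:(w + 5), drop = FALSE]
}

#' Residuals between estimated and ground-truth displacements
#'
#' Euclidean residual statistics over evaluation points, overall and
#' stratified inside/outside an optional mask.
#'
#' @param est m x 2 estimated displacements
#' @param gt m x 2 ground-truth displacements
#' @param inside optional logical vector marking points inside a region
#'   mask
#' @return list of `overall`, and when `inside` is given, `inside` /
#'   `outside` stats (each mean, median, var, n)
#' @export
correspondenceResidual <- function(est, gt, inside = NULL) {
  est <- as.matrix(est); gt <- as.matrix(gt)
  if (!all(dim(est) == dim(gt))) stop("displacement sets differ in size")
  if (!nrow(est)) stop("empty evaluation set")
  r <- sqrt(rowSums((est - gt)^2))
  stat <- function(v) list(mean = mean(v), median = median(v),
                           var = if (length(v) > 1) var(v) else 0,
                           n = length(v))
  out <- list(overall = stat(r))
  if (!is.null(inside)) {
    if (length(inside) != length(r)) stop("mask length mismatch")
    if (any(inside)) out$inside <- stat(r[inside])
    if (any(!inside)) out$outside <- stat(r[!inside])
  }
  out
}
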