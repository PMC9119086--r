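test_that("spatial angle cosine is the direction dot product", {
  expect_equal(spatialAngleCos(0.7, 1.1, 0.7, 1.1), 1)
  expect_equal(spatialAngleCos(0.7, 1.1, 0.7 + pi, pi - 1.1), -1)
  expect_equal(spatialAngleCos(0, pi / 2, pi / 2, pi / 2), 0)
})

test_that("radial covariance matches a term-by-term series oracle", {
  sp <- shapeParams(alpha = 1, beta = 0.1)
  # cos(psi) = 1 recovers the pointwise variance
  want <- sum(lambdaVariance(2:sp@nMax, sp) * (2 * (2:sp@nMax) + 1) / (4 * pi))
  expect_equal(radialCovariance(1, sp), want)
  # independent summation with pracma's Legendre values at cos(psi) = 0
  oracle <- sum(vapply(2:sp@nMax, function(n)
    lambdaVariance(n, sp) * (2 * n + 1) / (4 * pi) *
      pracma::legendre(n, 0)[1], 0))
  expect_equal(radialCovariance(0, sp), oracle, tolerance = 1e-12)
  expect_error(radialCovariance(1.2, sp), "cosPsi")
})

test_that("radial covariance agrees with sampled shapes and is PSD", {
  sp <- shapeParams(alpha = 50, beta = 0.01, nMax = 30L)
  set.seed(7)
  ang <- cbind(runif(8, 0, 2 * pi), runif(8, 0.3, pi - 0.3))
  B <- morphoreg:::harmonicBasis(sp, ang[, 1], ang[, 2])
  cv <- morphoreg:::coefVariances(sp)
  set.seed(8)
  r <- 1 + (matrix(rnorm(5000 * length(cv)), 5000) %*% diag(sqrt(cv))) %*% t(B)
  for (k in 1:5) {
    i <- k; j <- k + 3
    cp <- spatialAngleCos(ang[i, 1], ang[i, 2], ang[j, 1], ang[j, 2])
    emp <- cov(r[, i], r[, j])
    # SE of a covariance estimate from the sample
    se <- sd((r[, i] - mean(r[, i])) * (r[, j] - mean(r[, j]))) / sqrt(5000)
    expect_lt(abs(emp - radialCovariance(cp, sp)), 3 * se)
  }
  # Gram matrix of the model covariance on <= 8 directions is PSD
  G <- radialCovariance(outer(seq_len(8), seq_len(8), function(i, j)
    spatialAngleCos(ang[i, 1], ang[i, 2], ang[j, 1], ang[j, 2])), sp)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
})

test_that("theoretical translation variance vanishes in degenerate cases", {
  spec <- sectionPairSpec()
  tight <- shapeParams(alpha = 1e12, beta = 1)
  expect_lt(theoreticalTranslationVariance(tight, spec), 1e-6)
  sp <- shapeParams(alpha = 10, beta = 0.01)
  expect_lt(theoreticalTranslationVariance(
    sp, sectionPairSpec(thickness = 0)), 1e-20)
  expect_gt(theoreticalTranslationVariance(sp, spec), 0)
})

test_that("closed-form variance matches Monte Carlo across settings", {
  spec <- sectionPairSpec()
  for (ab in list(c(1, 0.01), c(100, 0.001), c(1000, 0.01))) {
    sp <- shapeParams(alpha = ab[1], beta = ab[2])
    theo <- theoreticalTranslationVariance(sp, spec)
    em <- empiricalErrorMoment(sp, spec, reps = 1000, seed = 31L)
    expect_lt(abs(em$secondMoment - theo), 3 * em$seMoment)
  }
})

test_that("contour Fourier coefficients recover planted modes", {
  th <- 2 * pi * (0:127) / 128
  circle <- new("Contour", angles = th, radii = rep(7.5, 128),
                origin = c(0, 0), latitude = pi / 2)
  fs <- contourFourier(circle)
  expect_lt(max(fs@bn), 1e-12)
  one <- new("Contour", angles = th, radii = 1 + 0.1 * sin(3 * th),
             origin = c(0, 0), latitude = pi / 2)
  f1 <- contourFourier(one)
  expect_equal(f1@bns[3], 0.1, tolerance = 1e-10)
  expect_equal(f1@bn[3], 0.01, tolerance = 1e-10)
  expect_lt(max(f1@bn[-3]), 1e-10)
  expect_error(contourFourier(circle, nHarm = 64L), "aliasing")
})

test_that("kappa: leading term, parity gap, and Monte-Carlo variance", {
  sp <- shapeParams(alpha = 1, beta = 1)
  # lambda -> 0 drives kappa -> 0
  expect_lt(kappaApprox(3, shapeParams(alpha = 1e12, beta = 1)), 1e-10)
  # the approximation is the l = n term; l = n+1 vanishes at the equator
  # (odd parity), so the first correction enters at l = n+2
  for (n in 2:5) {
    ex <- kappaApprox(n, sp, exact = TRUE)
    ap <- kappaApprox(n, sp)
    expect_lt(ap, ex)
    expect_equal(abs(pracma::legendre(n + 1, 0)[n + 1]), 0)
  }
  expect_lt(abs(1 - kappaApprox(2, sp) / kappaApprox(2, sp, exact = TRUE)),
            0.05)
  # exact series equals the sampled Fourier-coefficient variance
  spc <- shapeParams(alpha = 50, beta = 0.05, nMax = 30L)
  th <- 2 * pi * (0:127) / 128
  B <- morphoreg:::harmonicBasis(spc, th, rep(pi / 2, 128))
  cv <- morphoreg:::coefVariances(spc)
  set.seed(21)
  r <- 1 + (matrix(rnorm(4000 * length(cv)), 4000) %*% diag(sqrt(cv))) %*% t(B)
  for (n in c(2L, 3L, 5L)) {
    bns <- as.numeric(r %*% sin(n * th)) * (2 * pi / 128) / pi
    kap <- kappaApprox(n, spc, exact = TRUE)
    se <- sd((bns - mean(bns))^2) / sqrt(4000)
    expect_lt(abs(var(bns) - kap), 3 * se)
  }
})

test_that("roundness index caps, scales, and orders correctly", {
  th <- 2 * pi * (0:63) / 64
  circle <- new("Contour", angles = th, radii = rep(20, 64),
                origin = c(0, 0), latitude = pi / 2)
  ri <- roundnessIndex(contourFourier(circle))
  expect_true(ri@capped)
  expect_equal(ri@R, -log(1e-12))
  wob <- new("Contour", angles = th, radii = 1 + 0.05 * sin(4 * th),
             origin = c(0, 0), latitude = pi / 2)
  fs <- contourFourier(wob)
  r1 <- roundnessIndex(fs)@R
  # quadrupling every bn lowers R by log 4
  fs2 <- fs
  fs2@bnc <- 2 * fs@bnc
  fs2@bns <- 2 * fs@bns
  fs2@bn <- fs2@bnc^2 + fs2@bns^2
  expect_equal(roundnessIndex(fs2)@R, r1 - log(4), tolerance = 1e-10)
  # scale invariance via the mean-radius normalization
  wob2 <- wob
  wob2@radii <- wob@radii * 37.5
  expect_equal(roundnessIndex(contourFourier(wob2))@R, r1, tolerance = 1e-10)
})

test_that("mean roundness rises as the variance law tightens", {
  # larger beta suppresses high-degree deformation, so shapes get rounder
  meanR <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(b) {
    sp <- shapeParams(alpha = 30, beta = b, nMax = 30L)
    th <- 2 * pi * (0:63) / 64
    B <- morphoreg:::harmonicBasis(sp, th, rep(pi / 2, 64))
    cv <- morphoreg:::coefVariances(sp)
    set.seed(77)
    r <- 150 * (1 + (matrix(rnorm(1000 * length(cv)), 1000) %*%
                       diag(sqrt(cv))) %*% t(B))
    mean(vapply(1:1000, function(i) {
      ct <- new("Contour", angles = th, radii = pmax(r[i, ], 1e-3),
                origin = c(0, 0), latitude = pi / 2)
      roundnessIndex(contourFourier(ct))@R
    }, 0))
  }, 0)
  expect_true(all(diff(meanR) > 0))
})
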