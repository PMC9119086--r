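test_that("variance law matches its closed form and is monotone", {
  sp <- shapeParams(p = 4, alpha = 1, beta = 1)
  expect_equal(lambdaVariance(2, sp), 1)            # n^p - 2^p vanishes
  expect_equal(lambdaVariance(3, sp), 1 / 66)       # 1/(1 + 81 - 16)
  lam <- lambdaVariance(2:40, shapeParams(alpha = 1, beta = 0.1))
  expect_true(all(diff(lam) < 0))
  expect_true(all(lam > 0))
  # raising either precision never raises any variance
  lam2 <- lambdaVariance(2:40, shapeParams(alpha = 2, beta = 0.1))
  lam3 <- lambdaVariance(2:40, shapeParams(alpha = 1, beta = 0.2))
  expect_true(all(lam2 <= lam))
  expect_true(all(lam3 <= lam))
  expect_error(lambdaVariance(1, sp), "n must be")
  expect_error(shapeParams(alpha = -1), "alpha")
  expect_error(shapeParams(p = 2), "p")
})

test_that("shape sampling is seed-reproducible with the right variances", {
  sp <- shapeParams(alpha = 30, beta = 0.02, nMax = 12L)
  s1 <- sampleShape(sp, 42L)
  s2 <- sampleShape(sp, 42L)
  expect_identical(s1@coeffs, s2@coeffs)
  expect_false(identical(sampleShape(sp, 43L)@coeffs, s1@coeffs))
  # near-deterministic sphere at huge precision
  tight <- sampleShape(shapeParams(alpha = 1e12, beta = 1), 1L)
  expect_lt(max(abs(tight@coeffs)), 1e-4)
  # sample variance of single coefficients over 5000 draws vs lambda_n
  draws <- vapply(1:5000, function(s) {
    sh <- sampleShape(sp, s)
    off <- morphoreg:::coefOffsets(sp@nMax)
    sh@coeffs[off$starts[c(1, 4, 9)] + 1L]   # one (n, m=-n) coeff each
  }, numeric(3))
  for (i in seq_along(c(2L, 5L, 10L))) {
    n <- c(2L, 5L, 10L)[i]
    lam <- lambdaVariance(n, sp)
    se <- lam * sqrt(2 / 4999)
    expect_lt(abs(var(draws[i, ]) - lam), 3 * se)
  }
})

test_that("radius function has unit surface mean and the law variance", {
  sp <- shapeParams(alpha = 50, beta = 0.01)
  sh <- sampleShape(sp, 11L)
  # zero-coefficient shape is the unit sphere
  flat <- sh
  flat@coeffs[] <- 0
  expect_equal(evaluateRadius(flat, c(0, 1, 3), c(0.5, 1.5, 2.5)),
               c(1, 1, 1))
  # surface quadrature (64 x 64, Gauss-Legendre latitude weights)
  gl <- pracma::gaussLegendre(64, -1, 1)
  th <- 2 * pi * (0:63) / 64
  G <- expand.grid(th = th, x = gl$x)
  r <- evaluateRadius(sh, G$th, acos(G$x))
  expect_lt(abs(sum(r * rep(gl$w, each = 64) / (2 * 64)) - 1), 1e-6)
  # pointwise variance at a fixed direction vs sum lambda_n (2n+1)/(4 pi)
  want <- sum(lambdaVariance(2:sp@nMax, sp) * (2 * (2:sp@nMax) + 1) / (4 * pi))
  B <- morphoreg:::harmonicBasis(sp, 1.1, 1.9)
  cv <- morphoreg:::coefVariances(sp)
  set.seed(1)
  rs <- as.numeric(1 + (matrix(rnorm(5000 * length(cv)), 5000) %*%
                          diag(sqrt(cv))) %*% t(B))
  se <- want * sqrt(2 / 4999)
  expect_lt(abs(var(rs) - want), 3 * se)
  expect_error(evaluateRadius(sh, -1, 1), "theta")
  expect_error(evaluateRadius(sh, 1, 4), "phi")
})

test_that("section latitudes are symmetric about the equator", {
  expect_equal(sectionLatitudes(0, 150), c(phiS = pi / 2, phiT = pi / 2))
  lat <- sectionLatitudes(40, 150)
  expect_equal(lat[["phiS"]], acos(2 / 15))
  expect_equal(lat[["phiT"]], acos(-2 / 15))
  for (d in c(0, 10, 100, 299)) {
    l <- sectionLatitudes(d, 150)
    expect_lt(abs(sin(l[1]) - sin(l[2])), 1e-12)
  }
  expect_error(sectionLatitudes(300, 150), "not intersect")
})

test_that("contour projection scales by meanRadius * sin(phi)", {
  sp <- shapeParams(alpha = 200, beta = 0.05, meanRadius = 150)
  flat <- sampleShape(sp, 1L)
  flat@coeffs[] <- 0
  ct <- projectContour(flat, pi / 2, 64L)
  expect_equal(ct@radii, rep(150, 64))
  ct2 <- projectContour(flat, pi / 2, 360L)
  expect_equal(diff(ct2@angles), rep(2 * pi / 360, 359))
  # mean radius over shapes approaches meanRadius * sin(phi)
  phi <- 1.2
  m <- vapply(1:400, function(s)
    mean(projectContour(sampleShape(sp, s), phi, 32L)@radii), 0)
  se <- sd(m) / sqrt(400)
  expect_lt(abs(mean(m) - 150 * sin(phi)), 3 * se)
  expect_error(projectContour(flat, pi, 64L), "degenerate")
})

test_that("section pairs share one shape and the stated translation", {
  sp <- shapeParams(alpha = 500, beta = 0.02)
  # d = 0 with zero shift: the two contours coincide
  same <- makeSectionPair(sp, sectionPairSpec(thickness = 0,
                                              translation = c(0, 0)), 5L)
  expect_equal(same$S@radii, same$T@radii)
  expect_equal(same$S@origin, same$T@origin)
  # default geometry: thickness 40, shift (4.5, 4.5)
  pair <- makeSectionPair(sp, sectionPairSpec(), 5L)
  expect_equal(pair$T@origin - pair$S@origin, c(4.5, 4.5))
  expect_equal(pair$S@angles, pair$T@angles)
  pair2 <- makeSectionPair(sp, sectionPairSpec(), 5L)
  expect_identical(pair$S@radii, pair2$S@radii)
})

test_that("contour rasterization is deterministic with the right area", {
  sp <- shapeParams(alpha = 1e9, beta = 1, meanRadius = 10)
  disc <- projectContour(sampleShape(sp, 1L), pi / 2, 64L, c(32, 32))
  img <- renderContourImage(disc, c(64L, 64L))
  inside <- sum(img <= 0.55)
  expect_lt(abs(inside - pi * 100) / (pi * 100), 0.05)
  # integer translation commutes with rasterization
  disc2 <- disc
  disc2@origin <- disc@origin + c(3, 0)
  img2 <- renderContourImage(disc2, c(64L, 64L))
  expect_equal(img2[, 4:64], img[, 1:61])
  big <- projectContour(sampleShape(shapeParams(alpha = 1e9, beta = 1,
                                                meanRadius = 100), 1L),
                        pi / 2, 64L, c(32, 32))
  expect_error(renderContourImage(big, c(64L, 64L)), "bounds")
})

test_that("the default simulation design has 121 parameter subsets", {
  g <- sphericalDatasetGrid()
  expect_identical(nrow(g), 121L)
  expect_identical(length(unique(g$alpha)), 11L)
  expect_identical(length(unique(g$beta)), 11L)
  expect_true(all(g$pairsPerSubset == 1000L))
})
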