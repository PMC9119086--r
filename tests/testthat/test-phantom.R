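test_that("phantom stacks are reproducible with consistent ground truth", {
  spec <- phantomSpec(nSections = 4L, height = 160L, width = 160L,
                      nTubes = 4L, seed = 11L)
  ph <- generatePhantomStack(spec)
  expect_identical(ph@images, generatePhantomStack(spec)@images)
  expect_identical(dim(ph@images), c(160L, 160L, 4L))
  expect_true(all(ph@images >= 0 & ph@images <= 1))
  # membranes darker than their region interiors
  for (z in 1:4) {
    img <- ph@images[, , z]
    for (t in seq_len(4)) {
      inside <- ph@labels[, , z] == t
      ring <- ph@membranes[, , z] == 1
      if (sum(inside) > 50)
        expect_lt(mean(img[ring]), mean(img[inside]) - 0.1)
    }
  }
  # aligned stack: zero ground-truth flow
  expect_equal(max(abs(simplify2array(ph@gtFlow))), 0)
})

test_that("tube roundness classes separate at the R = 6 threshold", {
  spec <- phantomSpec(nSections = 6L, height = 220L, width = 220L,
                      nTubes = 6L, seed = 3L)
  ph <- generatePhantomStack(spec)
  # spec default: first half round (high alpha), second half irregular
  rounds <- c(); irregs <- c()
  for (z in 1:6) {
    sel <- selectRegions(ph@labels[, , z])
    rep <- sel@report[!sel@report$border & !is.na(sel@report$R), ]
    rounds <- c(rounds, rep$R[rep$label <= 3])
    irregs <- c(irregs, rep$R[rep$label > 3])
  }
  expect_gte(mean(rounds >= 6), 0.9)
  expect_gte(mean(irregs < 6), 0.9)
})

test_that("serial deformation draws stay inside the protocol bounds", {
  # 250 two-section stacks provide 500 parameter draws
  tiny <- new("PhantomStack",
              images = array(0.5, c(64, 64, 2)),
              labels = array(0L, c(64, 64, 2)),
              membranes = array(0, c(64, 64, 2)),
              gtFlow = list(array(0, c(64, 64, 2))),
              gtTransforms = rep(list(list(type = "identity")), 2),
              tubeCenters = rep(list(matrix(0, 0, 2)), 2))
  angles <- c(); shifts <- c()
  for (s in 1:250) {
    df <- applySerialDeformation(tiny, "fibsem", seed = s, mlsEvery = 0)
    angles <- c(angles, vapply(df@gtTransforms, function(t) t$angle, 0))
    shifts <- c(shifts, unlist(lapply(df@gtTransforms, function(t) t$shift)))
  }
  expect_true(all(abs(angles) <= 90 * pi / 180))
  expect_true(all(abs(shifts) <= 100))
  # uniformity of the protocol draws
  expect_gt(stats::ks.test(angles / (pi / 2), "punif", -1, 1)$p.value, 0.01)
  expect_gt(stats::ks.test(shifts / 100, "punif", -1, 1)$p.value, 0.01)
})

test_that("MLS distortion hits exactly every fifth section", {
  spec <- phantomSpec(nSections = 7L, height = 220L, width = 220L,
                      nTubes = 3L, seed = 2L)
  ph <- generatePhantomStack(spec)
  df <- applySerialDeformation(ph, "fibsem", seed = 4, rotRange = 10,
                               shiftRange = 10, mlsEvery = 5L)
  hasMls <- vapply(df@gtTransforms, function(t) !is.null(t$mlsCps), TRUE)
  expect_identical(which(hasMls), c(1L, 6L))   # 0-based sections 0 and 5
  # zero-amplitude protocol leaves the stack untouched
  d0 <- applySerialDeformation(ph, "fibsem", seed = 4, rotRange = 0,
                               shiftRange = 0, mlsMaxDisp = 0)
  expect_equal(max(abs(d0@images - ph@images)), 0)
  expect_equal(max(abs(simplify2array(d0@gtFlow))), 0)
})

test_that("ground-truth flow composes the per-section transforms", {
  spec <- phantomSpec(nSections = 3L, height = 220L, width = 220L,
                      nTubes = 3L, seed = 6L)
  ph <- generatePhantomStack(spec)
  df <- applySerialDeformation(ph, "fibsem", seed = 9, rotRange = 5,
                               shiftRange = 10, mlsEvery = 2L,
                               mlsMaxDisp = 8)
  maps <- attr(df, "maps")
  set.seed(10)
  px <- cbind(runif(20, 30, 190), runif(20, 30, 190))
  for (z in 1:2) {
    gf <- df@gtFlow[[z]]
    fx <- morphoreg::bilinearSample(gf[, , 1], px[, 1], px[, 2])
    fy <- morphoreg::bilinearSample(gf[, , 2], px[, 1], px[, 2])
    q <- cbind(px[, 1] + fx, px[, 2] + fy)
    # the matched points must land on the same aligned-frame position
    err <- maps[[z]](px) - maps[[z + 1]](q)
    expect_lt(max(abs(err)), 0.1)
  }
})

test_that("cremi-protocol TPS deformation is reproducible and bounded", {
  spec <- phantomSpec(nSections = 3L, height = 160L, width = 160L,
                      nTubes = 3L, seed = 8L)
  ph <- generatePhantomStack(spec)
  a <- applySerialDeformation(ph, "cremi", seed = 5, tpsSigma = 6)
  b <- applySerialDeformation(ph, "cremi", seed = 5, tpsSigma = 6)
  expect_identical(a@images, b@images)
  expect_false(identical(a@images, ph@images))
  z <- applySerialDeformation(ph, "cremi", seed = 5, tpsSigma = 0)
  expect_equal(max(abs(z@images - ph@images)), 0)
})

test_that("SSIM behaves like the standard windowed index", {
  set.seed(12)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ssimScore(img, img), 1)
  expect_lt(ssimScore(img, 1 - img), 0)
  # constant images: closed form (2 m1 m2 + C1)/(m1^2 + m2^2 + C1)
  m1 <- 0.4; m2 <- 0.45
  want <- (2 * m1 * m2 + 1e-4) / (m1^2 + m2^2 + 1e-4)
  expect_equal(ssimScore(matrix(m1, 32, 32), matrix(m2, 32, 32)), want,
               tolerance = 1e-10)
  expect_error(ssimScore(img, img[1:32, ]), "match")
})

test_that("residual statistics stratify by mask membership", {
  est <- cbind(c(1, 2, 3, 4), c(0, 0, 0, 0))
  gt <- est
  r0 <- correspondenceResidual(est, gt)
  expect_equal(r0$overall$mean, 0)
  r1 <- correspondenceResidual(est + cbind(rep(1, 4), 0), gt)
  expect_equal(r1$overall$mean, 1)
  expect_equal(r1$overall$var, 0)
  rs <- correspondenceResidual(est + cbind(c(2, 2, 0, 0), 0), gt,
                               inside = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rs$inside$mean, 2)
  expect_equal(rs$outside$mean, 0)
  expect_error(correspondenceResidual(est[0, ], gt[0, ]), "empty")
})

test_that("true displacements vary less inside the selected regions", {
  run <- phantomStudyRun()
  ph <- run$aligned
  nz <- dim(ph@images)[3]
  # per-tube drift between adjacent sections (the true content motion)
  drift <- lapply(seq_len(nz - 1), function(z)
    ph@tubeCenters[[z + 1]] - ph@tubeCenters[[z]])
  insideVar <- c(); outsideVar <- c()
  for (z in seq_len(nz - 1)) {
    sel <- selectRegions(watershedRegions(segmentMembranes(ph@images[, , z])))
    # a tube counts as inside when its center lies in the selected mask
    cen <- ph@tubeCenters[[z]]
    ins <- sel@mask[cbind(pmin(pmax(round(cen[, 2]) + 1, 1), 220),
                          pmin(pmax(round(cen[, 1]) + 1, 1), 220))]
    mag <- sqrt(rowSums(drift[[z]]^2))
    if (any(ins)) insideVar <- c(insideVar, mag[ins])
    if (any(!ins)) outsideVar <- c(outsideVar, mag[!ins])
  }
  expect_lt(var(insideVar), var(outsideVar))
})
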