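test_that("descriptors are normalized, shift-equivariant gradient maps", {
  expect_equal(max(abs(denseDescriptors(matrix(0.7, 32, 32))@data)), 0)
  tex <- smoothTexture(1, 80, 80)
  d <- denseDescriptors(tex)
  nrm <- sqrt(rowSums(d@data^2))
  expect_true(all(abs(nrm - 1) < 1e-9 | nrm < 1e-12))
  expect_lte(max(d@data), 1)
  # integer translate: descriptor field shifts along (away from borders)
  sh <- tex[, 6:80]
  dsh <- denseDescriptors(cbind(sh, matrix(0, 80, 5)))
  idx <- function(x, y, h) y + x * h + 1
  for (p in list(c(30, 30), c(40, 25), c(50, 55))) {
    a <- d@data[idx(p[1], p[2], 80), ]
    b <- dsh@data[idx(p[1] - 5, p[2], 80), ]
    expect_lt(max(abs(a - b)), 1e-6)
  }
  expect_error(denseDescriptors(matrix(0, 8, 8)), "support")
})

test_that("flow energy matches hand arithmetic on a tiny field", {
  # two pixels stacked vertically, 128-d descriptors
  d1 <- matrix(0, 2, 128); d2 <- matrix(0, 2, 128)
  d1[1, 1] <- 1; d1[2, 2] <- 1
  d2[1, 1] <- 0.6; d2[1, 3] <- 0.8
  d2[2, 2] <- 1
  f1 <- new("DescriptorField", data = d1, dim = c(2L, 1L))
  f2 <- new("DescriptorField", data = d2, dim = c(2L, 1L))
  par <- flowParams(dataTrunc = 5, eta = 0.1, smoothWeight = 2,
                    smoothTrunc = 3, searchRadius = 2L)
  zero <- list(u = matrix(0L, 2, 1), v = matrix(0L, 2, 1))
  # data: |1-0.6| + 0.8 = 1.2 for pixel 1; 0 for pixel 2
  expect_equal(flowEnergy(f1, f2, zero, par), 1.2)
  flow <- list(u = matrix(0L, 2, 1), v = matrix(c(1L, 0L), 2, 1))
  # pixel 1 -> pixel 2 target: |1-0|+|0-1| = 2; eta*1; pair min(2*1,3)=2
  expect_equal(flowEnergy(f1, f2, flow, par), 2 + 0.1 + 2)
  # out-of-image target pays the truncation
  flow2 <- list(u = matrix(0L, 2, 1), v = matrix(c(-1L, 0L), 2, 1))
  expect_equal(flowEnergy(f1, f2, flow2, par), 5 + 0.1 + 2)
  # zero flow has a zero magnitude term for any eta
  expect_equal(flowEnergy(f1, f1, zero, flowParams(eta = 99)), 0)
})

test_that("matching identical images returns the exactly-zero flow", {
  tex <- smoothTexture(2, 48, 48)
  d <- denseDescriptors(tex)
  fl <- matchFlow(d, d, flowParams(searchRadius = 6L, levels = 2L))
  expect_true(all(fl@u == 0L) && all(fl@v == 0L))
  expect_equal(fl@energy, 0)
})

test_that("an integer translation within range is recovered densely", {
  base <- smoothTexture(5, 80, 80)
  im1 <- base[11:70, 11:70]
  im2 <- base[11:70 - 2, 11:70 - 3]   # true flow (u, v) = (3, 2)
  d1 <- denseDescriptors(im1)
  d2 <- denseDescriptors(im2)
  fl <- matchFlow(d1, d2, flowParams(searchRadius = 8L, levels = 2L))
  interior <- cbind(as.numeric(fl@u[17:44, 17:44]),
                    as.numeric(fl@v[17:44, 17:44]))
  hit <- mean(interior[, 1] == 3 & interior[, 2] == 2)
  expect_gte(hit, 0.95)
  # energy descent per sweep and never worse than the zero flow
  tr <- attr(fl, "trace")
  expect_true(all(diff(tr) <= 1e-9))
  zero <- list(u = matrix(0L, 60, 60), v = matrix(0L, 60, 60))
  expect_lte(fl@energy,
             flowEnergy(d1, d2, zero, flowParams(searchRadius = 8L)))
  # self-consistency of the stored energy
  expect_equal(fl@energy, flowEnergy(d1, d2, fl,
                                     flowParams(searchRadius = 8L)))
})

test_that("small-instance energies never beat the exact optimum", {
  fp <- tinyFlowParams()
  agree <- 0
  for (s in 1:8) {
    pd <- plantedDescriptorPair(s)
    opt <- flowGlobalEnergy(pd$d1, pd$d2, fp)
    fl <- matchFlow(pd$d1, pd$d2, fp)
    expect_gte(fl@energy, opt - 1e-9)
    if (abs(fl@energy - opt) < 1e-6) agree <- agree + 1
  }
  expect_gte(agree, 6)
})

test_that("grid correspondences follow the mask and drop escapes", {
  u <- matrix(0L, 64, 64); v <- matrix(0L, 64, 64)
  fl <- new("FlowField", u = u, v = v, searchRadius = 4L, energy = 0)
  full <- gridCorrespondences(fl, NULL, 16)
  expect_identical(nrow(full), 16L)   # vertices at 0, 16, 32, 48
  expect_true(all(full$x1 == full$x2 & full$y1 == full$y2))
  empty <- gridCorrespondences(fl, matrix(FALSE, 64, 64), 16)
  expect_identical(nrow(empty), 0L)
  # a flow pushing the last grid column out of the image drops it
  u2 <- matrix(20L, 64, 64)
  fl2 <- new("FlowField", u = u2, v = v, searchRadius = 20L, energy = 0)
  esc <- gridCorrespondences(fl2, NULL, 16)
  expect_true(all(esc$x2 <= 63))
  expect_identical(nrow(esc), 12L)
  expect_error(gridCorrespondences(fl, NULL, 0), "spacing")
})
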