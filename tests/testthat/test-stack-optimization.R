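test_that("the neighbor graph is mutual kNN with inverse-distance weights", {
  pts1 <- data.frame(section = 1L, x = 5, y = 5)
  expect_identical(nrow(buildNeighborGraph(pts1)), 0L)
  coll <- data.frame(section = 1L, x = c(0, 10, 20), y = 0)
  e <- buildNeighborGraph(coll, stackEnergyParams(lambda = 2, k = 2L,
                                                  radius = 15))
  expect_identical(nrow(e), 2L)          # the 20-px pair exceeds the radius
  expect_equal(e$w, c(2 / 10, 2 / 10))
  set.seed(8)
  cloud <- data.frame(section = rep(1:2, each = 20),
                      x = runif(40, 0, 100), y = runif(40, 0, 100))
  g <- buildNeighborGraph(cloud, stackEnergyParams())
  expect_true(all(g$w > 0))
  expect_true(all(cloud$section[g$a] == cloud$section[g$b]))
  dup <- data.frame(section = 1L, x = c(1, 1, 9), y = c(1, 1, 1))
  expect_warning(buildNeighborGraph(dup, stackEnergyParams(radius = 50)),
                 "coincident")
})

test_that("stack energy matches hand arithmetic", {
  pts <- data.frame(section = 1L, x = c(0, 10), y = c(0, 0),
                    u = c(1, 3), v = c(-2, 0))
  edges <- data.frame(a = 1L, b = 2L, w = 0.5)
  expect_equal(stackEnergy(pts, edges),
               (1 + 4 + 9 + 0) + 0.5 * ((1 - 3)^2 + (-2 - 0)^2))
  pts0 <- transform(pts, u = 0, v = 0)
  expect_equal(stackEnergy(pts0, edges), 0)
  # uniform displacement has no smoothness cost
  ptsU <- transform(pts, u = 7, v = -1)
  expect_equal(stackEnergy(ptsU, edges), 2 * (49 + 1))
})

test_that("consistent correspondences solve to zero displacement", {
  pr <- data.frame(pair = c(1L, 1L, 2L), x1 = c(10, 40, 25), y1 = c(10, 40, 5),
                   x2 = c(10, 40, 25), y2 = c(10, 40, 5))
  sol <- solveStackDisplacements(correspondenceSet(pr, 3L))
  expect_equal(max(abs(c(sol@points$u, sol@points$v))), 0)
  expect_equal(sol@energy, 0)
})

test_that("a single offset correspondence splits symmetrically", {
  pr <- data.frame(pair = 1L, x1 = 10, y1 = 10, x2 = 14, y2 = 16)
  sol <- solveStackDisplacements(correspondenceSet(pr, 2L))
  expect_equal(sol@points$u, c(2, -2))
  expect_equal(sol@points$v, c(3, -3))
  expect_lte(sol@residual, 1e-8)
})

test_that("the sparse solution matches a dense KKT oracle", {
  set.seed(6)
  for (trial in 1:5) {
    pr <- do.call(rbind, lapply(1:2, function(i)
      data.frame(pair = i, x1 = runif(6, 0, 100), y1 = runif(6, 0, 100))))
    pr$x2 <- pr$x1 + rnorm(12, sd = 3)
    pr$y2 <- pr$y1 + rnorm(12, sd = 3)
    cs <- correspondenceSet(pr[, c("pair", "x1", "y1", "x2", "y2")], 3L)
    par <- stackEnergyParams()
    sol <- solveStackDisplacements(cs, par)
    expect_lte(sol@residual, 1e-8)
    pts <- sol@points
    edges <- buildNeighborGraph(pts, par)
    n <- nrow(pts)
    Q <- diag(n)
    for (e in seq_len(nrow(edges))) {
      a <- edges$a[e]; b <- edges$b[e]; w <- edges$w[e]
      Q[a, a] <- Q[a, a] + w; Q[b, b] <- Q[b, b] + w
      Q[a, b] <- Q[a, b] - w; Q[b, a] <- Q[b, a] - w
    }
    key <- paste(pts$section, round(pts$x, 9), round(pts$y, 9))
    si <- match(paste(pr$pair, round(pr$x1, 9), round(pr$y1, 9)), key)
    di <- match(paste(pr$pair + 1, round(pr$x2, 9), round(pr$y2, 9)), key)
    C <- matrix(0, nrow(pr), n)
    for (r in seq_len(nrow(pr))) { C[r, si[r]] <- 1; C[r, di[r]] <- -1 }
    kkt <- function(rhs) {
      K <- rbind(cbind(2 * Q, t(C)), cbind(C, matrix(0, nrow(C), nrow(C))))
      solve(K, c(rep(0, n), rhs))[1:n]
    }
    wx <- kkt(pr$x2 - pr$x1); wy <- kkt(pr$y2 - pr$y1)
    oracle <- sum(wx^2 + wy^2) +
      sum(edges$w * ((wx[edges$a] - wx[edges$b])^2 +
                     (wy[edges$a] - wy[edges$b])^2))
    expect_lt(abs(oracle - sol@energy) / max(oracle, 1e-12), 1e-6)
  }
})

test_that("reversing the stack negates every displacement", {
  set.seed(9)
  pr <- do.call(rbind, lapply(1:3, function(i)
    data.frame(pair = i, x1 = runif(5, 0, 80), y1 = runif(5, 0, 80))))
  pr$x2 <- pr$x1 + rnorm(15, sd = 2)
  pr$y2 <- pr$y1 + rnorm(15, sd = 2)
  sol <- solveStackDisplacements(correspondenceSet(pr, 4L))
  rev <- data.frame(pair = 4L - pr$pair, x1 = pr$x2, y1 = pr$y2,
                    x2 = pr$x1, y2 = pr$y1)
  solR <- solveStackDisplacements(correspondenceSet(rev, 4L))
  a <- sol@points[order(sol@points$section, sol@points$x, sol@points$y), ]
  b <- solR@points
  b$section <- 5L - b$section
  b <- b[order(b$section, b$x, b$y), ]
  expect_equal(a$u, b$u, tolerance = 1e-9)
  expect_equal(a$v, b$v, tolerance = 1e-9)
  expect_equal(sol@energy, solR@energy, tolerance = 1e-9)
})

test_that("without smoothness each chain meets at its mean position", {
  # one point tracked through three sections by exact-position chaining
  pr <- data.frame(pair = 1:2, x1 = c(10, 13), y1 = c(20, 26),
                   x2 = c(13, 19), y2 = c(26, 23))
  sol <- solveStackDisplacements(correspondenceSet(pr, 3L),
                                 stackEnergyParams(lambda = 0))
  expect_identical(max(sol@points$chain), 1L)   # one transitive chain
  tx <- mean(c(10, 13, 19)); ty <- mean(c(20, 26, 23))
  expect_equal(sol@points$x + sol@points$u, rep(tx, 3))
  expect_equal(sol@points$y + sol@points$v, rep(ty, 3))
})

test_that("duplicate source points are rejected", {
  bad <- data.frame(pair = c(1L, 1L), x1 = c(5, 5), y1 = c(5, 5),
                    x2 = c(6, 7), y2 = c(5, 5))
  expect_error(correspondenceSet(bad, 2L), "duplicate")
})
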