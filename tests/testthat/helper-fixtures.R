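# Shared fixtures, all generated in code.

# label map holding a clean disc (round) and a 6-armed star (irregular)
discStarLabels <- function() {
  h <- 128; w <- 192
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  lab <- matrix(0L, h, w)
  lab[sqrt((xs - 48)^2 + (ys - 64)^2) <= 24] <- 1L
  ang <- atan2(ys - 64, xs - 140)
  lab[sqrt((xs - 140)^2 + (ys - 64)^2) <= 24 * (1 + 0.3 * sin(6 * ang))] <- 2L
  lab
}

# random L2-normalized descriptor field pair with a planted integer shift;
# weak pairwise params keep the exact small-instance solver fast
plantedDescriptorPair <- function(seed, side = 8L) {
  set.seed(seed)
  n <- side * side
  d1 <- matrix(abs(rnorm(n * 128)), n, 128)
  d1 <- d1 / sqrt(rowSums(d1^2))
  sh <- switch(seed %% 4 + 1, c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  pix <- expand.grid(y = 0:(side - 1), x = 0:(side - 1))
  idx <- function(x, y) y + x * side + 1
  src <- cbind(pmin(pmax(pix$x - sh[1], 0), side - 1),
               pmin(pmax(pix$y - sh[2], 0), side - 1))
  d2 <- d1[idx(src[, 1], src[, 2]), ] +
    0.005 * abs(matrix(rnorm(n * 128), n, 128))
  d2 <- d2 / sqrt(rowSums(d2^2))
  list(d1 = new("DescriptorField", data = d1, dim = c(side, side)),
       d2 = new("DescriptorField", data = d2, dim = c(side, side)),
       shift = sh)
}

tinyFlowParams <- function() {
  flowParams(dataTrunc = 20.48, eta = 0.01, smoothWeight = 0.1,
             smoothTrunc = 1, searchRadius = 1L, levels = 1L)
}

# smooth random texture for flow tests
smoothTexture <- function(seed, h, w) {
  set.seed(seed)
  m <- matrix(runif(h * w), h, w)
  for (i in 1:2) m <- (m + morphoreg:::gaussianBlur(m, 2)) / 2
  m
}

# memoized phantom study-condition run shared between pipeline tests and
# the end-to-end acceptance check
.fixtureCache <- new.env(parent = emptyenv())

phantomStudyRun <- function() {
  if (!is.null(.fixtureCache$study)) return(.fixtureCache$study)
  spec <- phantomSpec(nSections = 6L, height = 220L, width = 220L,
                      nTubes = 6L, seed = 3L)
  aligned <- generatePhantomStack(spec)
  deformed <- applySerialDeformation(aligned, "fibsem", seed = 2,
                                     rotRange = 0, shiftRange = 8,
                                     mlsEvery = 0)
  res <- registerStack(deformed, pipelineConfig())
  .fixtureCache$study <- list(spec = spec, aligned = aligned,
                              deformed = deformed, res = res)
  .fixtureCache$study
}

# ground-truth correspondence residual before/after registration,
# evaluated at the pipeline's emitted correspondences
studyResiduals <- function(run) {
  maps <- registrationMaps(run$res$solution, dim(run$aligned@images)[3])
  pr <- run$res$correspondences@pairs
  h <- dim(run$aligned@images)[1]; w <- dim(run$aligned@images)[2]
  before <- c(); after <- c()
  for (z in sort(unique(pr$pair))) {
    sub <- pr[pr$pair == z, ]
    gf <- run$deformed@gtFlow[[z]]
    fx <- gf[cbind(sub$y1 + 1, sub$x1 + 1, 1)]
    fy <- gf[cbind(sub$y1 + 1, sub$x1 + 1, 2)]
    ok <- is.finite(fx) & is.finite(fy) &
      sub$x1 + fx >= 0 & sub$x1 + fx <= w - 1 &
      sub$y1 + fy >= 0 & sub$y1 + fy <= h - 1
    p <- cbind(sub$x1, sub$y1)[ok, , drop = FALSE]
    q <- cbind(sub$x1 + fx, sub$y1 + fy)[ok, , drop = FALSE]
    before <- c(before, sqrt(rowSums((q - p)^2)))
    after <- c(after, sqrt(rowSums((maps[[z + 1]](q) - maps[[z]](p))^2)))
  }
  list(before = before, after = after)
}
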