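# Simultaneous adjustment of correspondence positions across all sections:
# minimize the quadratic displacement + within-section smoothness energy
# subject to matched points landing on the same position.

#' Construct stack-adjustment parameters
#'
#' @param lambda smoothness weight (>= 0)
#' @param k mutual k-nearest-neighbor degree of the within-section graph
#' @param radius neighbor search radius in pixels
#' @param invDist TRUE: edge weight lambda/dist (closer points coupled more
#'   strongly); FALSE: lambda*dist
#' @return a validated [StackEnergyParams]
#' @export
stackEnergyParams <- function(lambda = 1, k = 4L, radius = 48,
                              invDist = TRUE) {
  new("StackEnergyParams", lambda = lambda, k = as.integer(k),
      radius = radius, invDist = invDist)
}

#' Assemble a correspondence set
#'
#' @param pairs data.frame with columns pair, x1, y1, x2, y2 - each row is
#'   a matched point pair between sections `pair` and `pair + 1`
#' @param nSections total number of sections
#' @return a validated [CorrespondenceSet]
#' @export
correspondenceSet <- function(pairs, nSections) {
  new("CorrespondenceSet", pairs = as.data.frame(pairs),
      nSections = as.integer(nSections))
}

setMethod("show", "CorrespondenceSet", function(object) {
  cat(sprintf("CorrespondenceSet: %d pairs over %d sections\n",
              nrow(object@pairs), object@nSections))
})

#' Within-section neighbor graph of control points
#'
#' Mutual k-nearest-neighbor edges within a radius; each edge carries
#' weight lambda/dist (or lambda*dist). Coincident points are skipped with
#' a warning.
#'
#' @param points data.frame with columns section, x, y (one row per control
#'   point; row order defines the point ids)
#' @param params a [StackEnergyParams]
#' @return data.frame with columns a, b (row indices into `points`), w
#' @export
buildNeighborGraph <- function(points, params = stackEnergyParams()) {
  stopifnot(all(c("section", "x", "y") %in% names(points)))
  out <- list()
  for (s in unique(points$section)) {
    idx <- which(points$section == s)
    n <- length(idx)
    if (n < 2 || params@k < 1) next
    P <- as.matrix(points[idx, c("x", "y")])
    D <- as.matrix(dist(P))
    diag(D) <- Inf
    k <- min(params@k, n - 1)
    nnRank <- apply(D, 1, function(r) rank(r, ties.method = "first"))
    nn <- t(nnRank) <= k   # nn[i, j]: j among i's k nearest
    mutual <- nn & t(nn) & D <= params@radius
    ee <- which(mutual & upper.tri(mutual), arr.ind = TRUE)
    if (!nrow(ee)) next
    d <- D[ee]
    zero <- d < 1e-9
    if (any(zero)) {
      warning("skipping edges between coincident control points")
      ee <- ee[!zero, , drop = FALSE]
      d <- d[!zero]
    }
    if (!nrow(ee)) next
    w <- if (params@invDist) params@lambda / d else params@lambda * d
    out[[length(out) + 1]] <- data.frame(a = idx[ee[, 1]], b = idx[ee[, 2]],
                                         w = w)
  }
  if (!length(out)) return(data.frame(a = integer(), b = integer(),
                                      w = numeric()))
  do.call(rbind, out)
}

#' Quadratic stack-adjustment energy
#'
#' `sum_points (u^2 + v^2) + sum_edges w_e ((u_a - u_b)^2 + (v_a - v_b)^2)`.
#'
#' @param points data.frame with columns section, x, y, u, v
#' @param edges edge data.frame from [buildNeighborGraph()]
#' @return the energy value (>= 0)
#' @export
stackEnergy <- function(points, edges) {
  stopifnot(all(c("u", "v") %in% names(points)))
  e <- sum(points$u^2 + points$v^2)
  if (nrow(edges)) {
    if (max(edges$a, edges$b) > nrow(points))
      stop("edge indices exceed the point table")
    e <- e + sum(edges$w * ((points$u[edges$a] - points$u[edges$b])^2 +
                            (points$v[edges$a] - points$v[edges$b])^2))
  }
  e
}

#' Solve the constrained whole-stack displacement adjustment
#'
#' Every matched pair must land on a shared target position; matches
#' compose transitively, so chains spanning several sections collapse to
#' one target unknown each (a chain holding two points of the same section
#' is a contradiction - it is merged toward the chain mean and counted).
#' The reduced problem is an unconstrained sparse symmetric
#' positive-definite quadratic in the chain targets, solved exactly by a
#' sparse Cholesky factorization; x and y decouple. Reversing the section
#' order only relabels chains, so displacements are reproduced exactly up
#' to sign conventions of the input.
#'
#' @param corrs a [CorrespondenceSet]
#' @param params a [StackEnergyParams]
#' @return a [DisplacementSolution]
#' @export
solveStackDisplacements <- function(corrs, params = stackEnergyParams()) {
  stopifnot(is(corrs, "CorrespondenceSet"))
  validObject(corrs)
  pr <- corrs@pairs
  if (!nrow(pr))
    return(new("DisplacementSolution",
               points = data.frame(section = integer(), x = numeric(),
                                   y = numeric(), u = numeric(),
                                   v = numeric(), chain = integer()),
               energy = 0, residual = 0, nContradictions = 0L))
  # control points: unique (section, x, y) across all endpoints
  ends <- rbind(data.frame(section = pr$pair, x = pr$x1, y = pr$y1),
                data.frame(section = pr$pair + 1L, x = pr$x2, y = pr$y2))
  key <- paste(ends$section, round(ends$x, 9), round(ends$y, 9))
  uniq <- !duplicated(key)
  points <- ends[uniq, ]
  rownames(points) <- NULL
  pid <- match(key, key[uniq])
  n <- nrow(points)
  src <- pid[seq_len(nrow(pr))]
  dst <- pid[nrow(pr) + seq_len(nrow(pr))]
  # union-find over matched points -> chains
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_along(src)) {
    a <- find(src[r]); b <- find(dst[r])
    if (a != b) parent[b] <- a
  }
  chain <- vapply(seq_len(n), find, 1L)
  chain <- match(chain, unique(chain))
  nc <- max(chain)
  contra <- sum(vapply(split(points$section, chain),
                       function(s) as.integer(anyDuplicated(s) > 0), 1L))
  edges <- buildNeighborGraph(points, params)
  # unknowns: chain target positions T_c; w_p = T_chain(p) - p
  A <- Matrix::sparseMatrix(i = chain, j = chain, x = rep(1, n),
                            dims = c(nc, nc))
  bx <- numeric(nc); by <- numeric(nc)
  addTo <- function(acc, idx, val) {
    s <- rowsum(val, idx)
    acc[as.numeric(rownames(s))] <- acc[as.numeric(rownames(s))] + s[, 1]
    acc
  }
  bx <- addTo(bx, chain, points$x)
  by <- addTo(by, chain, points$y)
  if (nrow(edges)) {
    ca <- chain[edges$a]; cb <- chain[edges$b]
    off <- ca != cb
    if (any(off)) {
      w <- edges$w[off]; ca2 <- ca[off]; cb2 <- cb[off]
      A <- A + Matrix::sparseMatrix(
        i = c(ca2, cb2, ca2, cb2), j = c(ca2, cb2, cb2, ca2),
        x = c(w, w, -w, -w), dims = c(nc, nc))
      dxe <- points$x[edges$a][off] - points$x[edges$b][off]
      dye <- points$y[edges$a][off] - points$y[edges$b][off]
      bx <- addTo(bx, c(ca2, cb2), c(w * dxe, -w * dxe))
      by <- addTo(by, c(ca2, cb2), c(w * dye, -w * dye))
    }
  }
  Tx <- as.numeric(Matrix::solve(A, bx))
  Ty <- as.numeric(Matrix::solve(A, by))
  points$u <- Tx[chain] - points$x
  points$v <- Ty[chain] - points$y
  points$chain <- chain
  resid <- max(abs((points$x[src] + points$u[src]) -
                   (points$x[dst] + points$u[dst])),
               abs((points$y[src] + points$v[src]) -
                   (points$y[dst] + points$v[dst])))
  new("DisplacementSolution", points = points,
      energy = stackEnergy(points, edges), residual = resid,
      nContradictions = as.integer(contra))
}

setMethod("show", "DisplacementSolution", function(object) {
  cat(sprintf(
    "DisplacementSolution: %d control points, energy %.4g, residual %.2e, %d contradictions\n",
    nrow(object@points), object@energy, object@residual,
    object@nContradictions))
})
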