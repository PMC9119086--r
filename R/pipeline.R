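# Full registration pipeline: region selection -> dense flow -> grid
# correspondences -> whole-stack constrained adjustment -> per-section
# rigid MLS warping.

#' Default pipeline configuration
#'
#' @param segmentation `"classical"` or `"external"`
#' @param membraneMaps for `"external"`: list of probability matrices (or
#'   file paths), one per section
#' @param rThres,minArea roundness threshold and minimum region area
#' @param flow a [FlowParams]
#' @param gridSpacing correspondence grid stride in pixels
#' @param stack a [StackEnergyParams]
#' @param warpGridStep MLS deformation-grid step in pixels
#' @param preAlign run coarse phase-correlation translation pre-alignment
#'   before the flow (plumbing for grossly shifted stacks; off by default)
#' @param verbose print per-stage progress
#' @return a named list of settings
#' @export
pipelineConfig <- function(segmentation = "classical", membraneMaps = NULL,
                           rThres = 6, minArea = 64,
                           flow = flowParams(), gridSpacing = 16,
                           stack = stackEnergyParams(),
                           warpGridStep = 8, preAlign = FALSE,
                           verbose = FALSE) {
  list(segmentation = segmentation, membraneMaps = membraneMaps,
       rThres = rThres, minArea = minArea, flow = flow,
       gridSpacing = gridSpacing, stack = stack,
       warpGridStep = warpGridStep, preAlign = preAlign, verbose = verbose)
}

asStackArray <- function(stack) {
  if (is(stack, "PhantomStack")) stack <- stack@images
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) != 3) stop("a stack must be a h x w x n array")
  if (dim(stack)[3] < 2) stop("a stack needs at least 2 sections")
  stack
}

#' Register a serial-section stack
#'
#' Runs the full morphology-driven pipeline: per section, membrane
#' segmentation, watershed, and roundness-based region selection; per
#' adjacent pair, dense descriptor flow and grid-vertex correspondences
#' restricted to the selected regions (falling back to the full grid with
#' a warning when a section selects nothing); one whole-stack constrained
#' displacement adjustment; and a rigid MLS warp of every section into the
#' common frame. Deterministic for fixed inputs and configuration.
#'
#' @param stack h x w x n array (or list of matrices, or [PhantomStack])
#' @param config list from [pipelineConfig()]
#' @return list with `aligned` (h x w x n array), `masks`, `flows`,
#'   `correspondences` (a [CorrespondenceSet]), `solution`
#'   (a [DisplacementSolution]), `preShifts`, and `report` (per-stage
#'   timings and energies)
#' @export
registerStack <- function(stack, config = pipelineConfig()) {
  imgs <- asStackArray(stack)
  h <- dim(imgs)[1]; w <- dim(imgs)[2]; nz <- dim(imgs)[3]
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  t0 <- proc.time()[3]
  report <- list(stages = list())
  stamp <- function(name) {
    report$stages[[name]] <<- proc.time()[3] - t0
    t0 <<- proc.time()[3]
  }
  # optional coarse translation pre-alignment (plumbing, off by default)
  preShifts <- matrix(0, nz, 2)
  if (isTRUE(config$preAlign)) {
    for (z in 2:nz) {
      sh <- phaseCorrelation(imgs[, , z - 1], imgs[, , z])
      preShifts[z, ] <- preShifts[z - 1, ] + sh
    }
    px <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), w))
    for (z in seq_len(nz)) {
      if (all(preShifts[z, ] == 0)) next
      say("pre-align section %d by (%g, %g)", z, preShifts[z, 1],
          preShifts[z, 2])
      imgs[, , z] <- matrix(
        bilinearSample(imgs[, , z], px[, 1] - preShifts[z, 1],
                       px[, 2] - preShifts[z, 2]), h, w)
    }
  }
  stamp("preAlign")
  # stage 1: region selection per section
  masks <- vector("list", nz)
  for (z in seq_len(nz)) {
    mem <- if (identical(config$segmentation, "external")) {
      segmentMembranes(imgs[, , z], "external",
                       map = config$membraneMaps[[z]])
    } else {
      segmentMembranes(imgs[, , z], "classical")
    }
    lab <- watershedRegions(mem)
    masks[[z]] <- selectRegions(lab, rThres = config$rThres,
                                minArea = config$minArea)
    say("section %d: %d/%d regions selected", z,
        sum(masks[[z]]@report$kept), nrow(masks[[z]]@report))
  }
  stamp("regionSelection")
  # stage 2: dense flow + grid correspondences per adjacent pair
  flows <- vector("list", nz - 1)
  pairTabs <- vector("list", nz - 1)
  descPrev <- denseDescriptors(imgs[, , 1])
  for (z in seq_len(nz - 1)) {
    descNext <- denseDescriptors(imgs[, , z + 1])
    fl <- matchFlow(descPrev, descNext, config$flow)
    flows[[z]] <- fl
    tab <- gridCorrespondences(fl, masks[[z]], config$gridSpacing)
    if (!nrow(tab)) {
      warning(sprintf(
        "no selected regions on the grid for pair %d; falling back to the full grid", z))
      tab <- gridCorrespondences(fl, NULL, config$gridSpacing)
    }
    if (nrow(tab)) tab$pair <- z
    pairTabs[[z]] <- tab
    say("pair %d: %d correspondences, flow energy %.4g", z, nrow(tab),
        fl@energy)
    descPrev <- descNext
  }
  stamp("correspondences")
  # stage 3: whole-stack constrained adjustment
  allPairs <- do.call(rbind, pairTabs[vapply(pairTabs, nrow, 1L) > 0])
  corrs <- correspondenceSet(allPairs[, c("pair", "x1", "y1", "x2", "y2")],
                             nz)
  sol <- solveStackDisplacements(corrs, config$stack)
  say("stack adjustment: energy %.4g, residual %.2e", sol@energy,
      sol@residual)
  stamp("stackOptimization")
  # stage 4: warp every section by its control-point displacements
  aligned <- imgs
  for (z in seq_len(nz)) {
    pts <- sol@points[sol@points$section == z, , drop = FALSE]
    if (!nrow(pts)) next
    cps <- controlPointSet(cbind(pts$x, pts$y),
                           cbind(pts$x + pts$u, pts$y + pts$v))
    aligned[, , z] <- mlsRigidWarp(imgs[, , z], cps,
                                   gridStep = config$warpGridStep)
  }
  stamp("warping")
  report$flowEnergies <- vapply(flows, function(f) f@energy, 0)
  report$stackEnergy <- sol@energy
  report$constraintResidual <- sol@residual
  list(aligned = aligned, masks = masks, flows = flows,
       correspondences = corrs, solution = sol, preShifts = preShifts,
       report = report)
}

#' Alignment quality metrics
#'
#' Per-section SSIM against a ground-truth stack and against the adjacent
#' (next) section.
#'
#' @param aligned h x w x n array (or list / [PhantomStack])
#' @param truth optional ground-truth stack of the same geometry
#' @return data.frame with one row per section: section, ssimGT (NA
#'   without truth), ssimAdjacent (NA for the last section)
#' @export
evaluateAlignment <- function(aligned, truth = NULL) {
  a <- asStackArray(aligned)
  nz <- dim(a)[3]
  gt <- if (!is.null(truth)) asStackArray(truth)
  if (!is.null(gt) && !identical(dim(gt), dim(a)))
    stop("ground-truth geometry does not match")
  data.frame(
    section = seq_len(nz),
    ssimGT = vapply(seq_len(nz), function(z)
      if (is.null(gt)) NA_real_ else ssimScore(a[, , z], gt[, , z]), 0),
    ssimAdjacent = vapply(seq_len(nz), function(z)
      if (z < nz) ssimScore(a[, , z], a[, , z + 1]) else NA_real_, 0))
}

#' Forward registration maps of a solved stack
#'
#' For evaluation: returns, per section, a function mapping positions in
#' the unregistered section to their positions in the aligned frame (the
#' rigid MLS interpolation of the section's control-point displacements).
#'
#' @param solution a [DisplacementSolution]
#' @param nSections number of sections
#' @return list of mapping functions (identity where no control points)
#' @export
registrationMaps <- function(solution, nSections) {
  lapply(seq_len(nSections), function(z) {
    pts <- solution@points[solution@points$section == z, , drop = FALSE]
    if (!nrow(pts)) return(function(p) as.matrix(p))
    cps <- controlPointSet(cbind(pts$x, pts$y),
                           cbind(pts$x + pts$u, pts$y + pts$v))
    function(p) mlsRigidMap(cps, p)
  })
}
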