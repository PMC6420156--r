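#' Build per-frame point clouds from a trajectory
#'
#' Converts a trajectory into the sequence of Euclidean point clouds whose
#' Rips homology the crocker summarizes. `mode = "pos"` takes raw 2-D
#' positions in metres. `mode = "posvel"` concatenates position and
#' one-frame-displacement velocity into 4-D points, normalizing position by
#' the arena radius (0.2 m) and velocity by the maximum step length
#' (0.0013 m) so the two blocks live on comparable scales; it starts at the
#' first frame with defined velocities. Time is downsampled by `timeStride`
#' (default 4). Agents masked by a tracking dropout (and, in `posvel` mode,
#' agents without a defined velocity) are omitted from that frame's cloud.
#'
#' @param traj A [TrajectorySet-class].
#' @param mode `"pos"` or `"posvel"`.
#' @param timeStride Keep every `timeStride`-th frame (>= 1).
#' @param posScale,velScale Normalization scales (m) for `posvel` mode.
#' @return List with `clouds` (list of matrices), `times` (0-based frame
#'   indices) and `mode`.
#' @export
buildPointClouds <- function(traj, mode = c("pos", "posvel"),
                             timeStride = 4L, posScale = 0.2,
                             velScale = 0.0013) {
  mode <- match.arg(mode)
  if (timeStride < 1L) stop("timeStride must be >= 1")
  if (posScale <= 0 || velScale <= 0) stop("scales must be positive")
  Tn <- nFrames(traj)
  if (mode == "pos") {
    frames <- seq(1L, Tn, by = timeStride)
    clouds <- lapply(frames, function(t) framePositions(traj, t))
  } else {
    if (Tn < 2L) stop("posvel mode needs at least 2 frames")
    v <- velocitiesFromPositions(traj)
    frames <- seq(2L, Tn, by = timeStride)
    clouds <- lapply(frames, function(t) {
      vt <- matrix(v[t - 1L, , ], ncol = 2)
      keep <- traj@present[t, ] & stats::complete.cases(vt)
      cbind(traj@positions[t, keep, 1] / posScale,
            traj@positions[t, keep, 2] / posScale,
            vt[keep, 1] / velScale,
            vt[keep, 2] / velScale)
    })
  }
  list(clouds = clouds, times = as.integer(frames - 1L), mode = mode)
}

#' Construct a Crocker object
#'
#' Low-level constructor used by [computeCrocker()] and the file reader.
#'
#' @param betti Betti matrix, `length(epsGrid)` x `length(times)`.
#' @param epsGrid,times,k,mode,averaged Slot values; see [Crocker-class].
#' @return A validated [Crocker-class].
#' @export
newCrocker <- function(betti, epsGrid, times, k, mode, averaged = FALSE) {
  new("Crocker", betti = betti, epsGrid = as.numeric(epsGrid),
      times = as.integer(times), k = as.integer(k), mode = mode,
      averaged = averaged)
}

#' Compute a crocker matrix from a trajectory
#'
#' Evaluates the Betti number \eqn{b_k(t, \epsilon)} of the Vietoris-Rips
#' complex on each (downsampled) frame's point cloud over a uniform grid of
#' `nEps` proximity values from 0 to `maxEps`. Defaults follow the reference
#' analysis: 50 proximity values, time downsampled by 4, maximum filtration
#' 0.2 (raw position clouds, metres) or 1.5 (normalized position-velocity
#' clouds). Each time column is computed independently on whatever agents
#' are present at that frame, so tracking dropouts shrink single columns
#' rather than invalidating the matrix.
#'
#' @inheritParams buildPointClouds
#' @param k Homology dimension, 0 or 1.
#' @param maxEps Maximum filtration value; default 0.2 for `"pos"`, 1.5 for
#'   `"posvel"`.
#' @param nEps Number of proximity samples (default 50).
#' @return A [Crocker-class].
#' @examples
#' ic <- generateInitialConditions(8, "clustered", seed = 1)
#' traj <- simulateTrajectories(ic, aphidModelParams(), 40, seed = 1)
#' computeCrocker(traj, "pos", k = 0)
#' @export
computeCrocker <- function(traj, mode = c("pos", "posvel"), k = 0L,
                           maxEps = NULL, nEps = 50L, timeStride = 4L,
                           posScale = 0.2, velScale = 0.0013) {
  mode <- match.arg(mode)
  if (!k %in% c(0L, 1L)) stop("homology dimension k must be 0 or 1")
  if (is.null(maxEps)) maxEps <- if (mode == "pos") 0.2 else 1.5
  pc <- buildPointClouds(traj, mode, timeStride, posScale, velScale)
  grid <- seq(0, maxEps, length.out = nEps)
  betti <- vapply(pc$clouds, function(cl)
    ripsBettiCurve(cl, grid, maxDim = as.integer(k))[k + 1L, ],
    numeric(nEps))
  betti <- matrix(betti, nrow = nEps)
  newCrocker(betti, grid, pc$times, k, mode)
}

#' @rdname accessors
#' @export
setMethod("bettiMatrix", "Crocker", function(object) object@betti)

#' @rdname accessors
#' @export
setMethod("epsGrid", "Crocker", function(object) object@epsGrid)

#' @rdname accessors
#' @export
setMethod("crockerTimes", "Crocker", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("homologyDim", "Crocker", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("crockerMode", "Crocker", function(object) object@mode)

setMethod("show", "Crocker", function(object) {
  cat(sprintf("Crocker: b_%s(%s), %d eps values in [0, %g] x %d frames%s\n",
              ifelse(is.na(object@k), "0+1", object@k), object@mode,
              length(object@epsGrid), max(object@epsGrid),
              length(object@times),
              if (object@averaged) " (ensemble average)" else ""))
})

.sameGrid <- function(a, b) {
  isTRUE(all.equal(a@epsGrid, b@epsGrid)) && identical(a@times, b@times)
}

#' Element-wise average of crockers
#'
#' The ensemble-average crocker: the element-wise arithmetic mean of the
#' Betti matrices of independent runs on identical grids. Averaging over
#' runs suppresses realization noise and exposes systematic contour trends.
#'
#' @param crockers Non-empty list of [Crocker-class] objects with identical
#'   grids, dimension and mode.
#' @return A [Crocker-class] with `averaged = TRUE` and real-valued entries.
#' @export
averageCrocker <- function(crockers) {
  if (!length(crockers)) stop("empty crocker list")
  ref <- crockers[[1]]
  for (cr in crockers[-1]) {
    if (!.sameGrid(ref, cr) || !identical(ref@k, cr@k))
      stop("crockers must share eps grid, time grid and dimension")
  }
  betti <- Reduce(`+`, lapply(crockers, bettiMatrix)) / length(crockers)
  newCrocker(betti, ref@epsGrid, ref@times, ref@k, ref@mode, averaged = TRUE)
}

#' Concatenate two crockers into one matrix
#'
#' Stacks the Betti matrices of two crockers on the same time grid (e.g.
#' \eqn{b_0} over \eqn{b_1}) so connected components and loops enter a
#' single Frobenius comparison. The result's eps grid is the concatenation
#' (offset so it stays ascending, for bookkeeping only) and its `k` is `NA`.
#'
#' @param a,b [Crocker-class] objects sharing a time grid.
#' @return A [Crocker-class] whose row count is the sum of the inputs'.
#' @export
concatenateCrockers <- function(a, b) {
  if (!identical(a@times, b@times)) stop("time grids must match")
  betti <- rbind(a@betti, b@betti)
  grid <- c(a@epsGrid,
            max(a@epsGrid) + diff(range(b@epsGrid))[1] / length(b@epsGrid) +
              b@epsGrid - min(b@epsGrid))
  newCrocker(betti, grid, a@times, NA_integer_,
             paste(a@mode, b@mode, sep = "+"),
             averaged = a@averaged || b@averaged)
}

#' Connectivity merge scale of a crocker
#'
#' For each time column, the smallest grid proximity value at which the
#' (possibly averaged) \eqn{b_0} drops to `level` or below — the scale at
#' which the group becomes a single connected component. Columns never
#' reaching the level return the maximum grid value. The time trend of this
#' statistic quantifies dispersal: rising merge scales mean agents are
#' drifting apart.
#'
#' @param crocker A [Crocker-class] (meaningful for `k = 0`).
#' @param level Threshold (default 1).
#' @return Numeric vector, one merge scale per time column.
#' @export
mergeScale <- function(crocker, level = 1) {
  apply(crocker@betti, 2L, function(col) {
    i <- which(col <= level)[1]
    if (is.na(i)) max(crocker@epsGrid) else crocker@epsGrid[i]
  })
}

#' Contour plot of a crocker
#'
#' Renders the classic crocker contour diagram: time on the horizontal
#' axis, proximity scale on the vertical axis, contour lines separating the
#' regions where the Betti number is below/at-or-above each integer level.
#' The contour labelled `n` separates the region with fewer than `n`
#' features from the region with at least `n`; levels above `maxContour`
#' (default 11) are suppressed as topological noise.
#'
#' @param crocker A [Crocker-class].
#' @param maxContour Highest contour level drawn.
#' @param file Optional output path (`.png`, `.svg` or `.pdf` by
#'   extension); `NULL` draws on the current device.
#' @param main Plot title.
#' @return `file` (or `NULL`), invisibly.
#' @export
crockerContourPlot <- function(crocker, maxContour = 11L, file = NULL,
                               main = NULL) {
  if (is.null(main))
    main <- sprintf("b_%s(%s) crocker",
                    ifelse(is.na(crocker@k), "0+1", crocker@k), crocker@mode)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 900, height = 600,
                                type = "cairo"),
           svg = grDevices::svg(file, width = 9, height = 6),
           pdf = grDevices::pdf(file, width = 9, height = 6),
           stop("unsupported plot format: ", ext))
    on.exit(grDevices::dev.off())
  }
  levels <- seq_len(min(maxContour, max(2, ceiling(max(crocker@betti)))))
  levels <- levels[levels >= 2]      # the 1-contour is the whole plot
  graphics::contour(x = crocker@times, y = crocker@epsGrid,
                    z = t(crocker@betti),
                    levels = levels - 0.5, labels = levels,
                    xlab = "frame", ylab = "proximity eps", main = main)
  invisible(file)
}
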