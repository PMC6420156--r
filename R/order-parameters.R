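## Collective-motion order parameters. Per frame t (velocities defined by
## one-frame backward differences, so series start at the second frame):
##   P      = |sum v_i| / sum |v_i|          polarization
##   M_ang  = |sum r_i x v_i| / sum |r_i||v_i|   angular momentum
##   M_abs  = sum |r_i x v_i| / sum |r_i||v_i|   absolute angular momentum
##   d_a    = mean over agents of nearest-neighbour distance
##   Mov%   = 100 * fraction of present agents in the moving state
## with r_i relative to the instantaneous centre of mass of present agents
## and the 2-D cross product r x v = r_x v_y - r_y v_x. Stationary agents
## have |v_i| = 0 and so drop out of the sums of P, M_ang, M_abs; if every
## agent is stationary those three are 0 by convention. Agents masked by a
## tracking dropout are excluded from all sums frame-wise.

#' Velocities by one-frame backward differences
#'
#' `v(t) = x(t) - x(t-1)` in metres per frame, for each agent present at
#' both frames; `NA` otherwise. The result covers frames 2..T.
#'
#' @param traj A [TrajectorySet-class] with at least two frames.
#' @return (T-1) x N x 2 array of velocities.
#' @export
velocitiesFromPositions <- function(traj) {
  Tn <- nFrames(traj)
  if (Tn < 2L) stop("need at least 2 frames to form velocities")
  p <- traj@positions
  v <- p[-1, , , drop = FALSE] - p[-Tn, , , drop = FALSE]
  defined <- traj@present[-1, , drop = FALSE] &
    traj@present[-Tn, , drop = FALSE]
  v[, , 1][!defined] <- NA_real_
  v[, , 2][!defined] <- NA_real_
  v
}

#' Classify motion states from displacements
#'
#' Experimental-style trajectories carry no ground-truth motion state; an
#' agent is classified stationary at frame t when it moved at most
#' `threshold` metres since the previous frame (the conventional tracking
#' threshold is 1e-4 m; the boundary case is stationary). Frames where the
#' displacement is undefined (first frame, dropouts) are `NA`.
#'
#' @param traj A [TrajectorySet-class].
#' @param threshold Positive displacement threshold in metres.
#' @return T x N logical matrix (`TRUE` = moving), `NA` in the first row.
#' @export
classifyMotionStates <- function(traj, threshold = 1e-4) {
  if (threshold <= 0) stop("threshold must be positive")
  v <- velocitiesFromPositions(traj)
  speed <- sqrt(v[, , 1]^2 + v[, , 2]^2)
  mov <- matrix(NA, nFrames(traj), nAgents(traj))
  mov[-1, ] <- speed > threshold
  mov
}

#' Order parameters of a single frame
#'
#' Frame-level kernels behind [computeOrderParameters()]; exported for
#' direct use and testing. `positions` and `velocities` are M x 2 matrices
#' over the agents entering the sums (rows with `NA` are dropped).
#'
#' @param velocities M x 2 matrix of per-agent velocities.
#' @param positions M x 2 matrix of per-agent positions.
#' @param moving Logical vector of motion states (`NA` dropped).
#' @return A scalar; `NA` when undefined (no agents, or fewer than two for
#'   [meanNNDistance()]).
#' @name frameOrderParameters
NULL

.dropNA <- function(m) m[stats::complete.cases(m), , drop = FALSE]

#' @rdname frameOrderParameters
#' @export
polarization <- function(velocities) {
  v <- .dropNA(velocities)
  if (nrow(v) == 0L) return(NA_real_)
  den <- sum(sqrt(rowSums(v^2)))
  if (den == 0) return(0)
  sqrt(sum(colSums(v)^2)) / den
}

.momentumParts <- function(positions, velocities) {
  keep <- stats::complete.cases(positions) & stats::complete.cases(velocities)
  p <- positions[keep, , drop = FALSE]
  v <- velocities[keep, , drop = FALSE]
  if (nrow(p) == 0L) return(NULL)
  r <- sweep(p, 2L, colMeans(p))  # relative to the group's centre of mass
  cross <- r[, 1] * v[, 2] - r[, 2] * v[, 1]
  list(cross = cross,
       den = sum(sqrt(rowSums(r^2)) * sqrt(rowSums(v^2))))
}

#' @rdname frameOrderParameters
#' @export
angularMomentum <- function(positions, velocities) {
  m <- .momentumParts(positions, velocities)
  if (is.null(m)) return(NA_real_)
  if (m$den == 0) return(0)
  abs(sum(m$cross)) / m$den
}

#' @rdname frameOrderParameters
#' @export
absoluteAngularMomentum <- function(positions, velocities) {
  m <- .momentumParts(positions, velocities)
  if (is.null(m)) return(NA_real_)
  if (m$den == 0) return(0)
  sum(abs(m$cross)) / m$den
}

#' @rdname frameOrderParameters
#' @export
meanNNDistance <- function(positions) {
  p <- .dropNA(positions)
  if (nrow(p) < 2L) return(NA_real_)
  mean(nearestNeighborDistances(p))
}

#' @rdname frameOrderParameters
#' @export
percentMoving <- function(moving) {
  moving <- moving[!is.na(moving)]
  if (length(moving) == 0L) return(NA_real_)
  100 * mean(moving)
}

#' Compute the five order-parameter time series
#'
#' Evaluates polarization `P`, angular momentum `M_ang`, absolute angular
#' momentum `M_abs`, mean nearest-neighbour distance `d_a` (m) and percent
#' moving `Mov_pct` in every frame from the second onward (velocities need
#' one backward difference), aligned on a common frame grid. Missing values
#' (dropout frames) propagate as `NA` rather than being dropped.
#'
#' @param traj A [TrajectorySet-class] with at least 2 frames.
#' @param useRecordedStates If `TRUE` (default) and the trajectory carries
#'   simulator motion states, use them for `Mov_pct`; otherwise classify
#'   states from displacements via [classifyMotionStates()].
#' @param threshold Displacement threshold (m) for state classification.
#' @return Data frame with columns `frame` (0-based index, `1..T-1`), `P`,
#'   `M_ang`, `M_abs`, `d_a`, `Mov_pct`; `T-1` rows.
#' @examples
#' ic <- generateInitialConditions(8, "dispersed", seed = 1)
#' traj <- simulateTrajectories(ic, aphidModelParams(), 40, seed = 1)
#' head(computeOrderParameters(traj))
#' @export
computeOrderParameters <- function(traj, useRecordedStates = TRUE,
                                   threshold = 1e-4) {
  Tn <- nFrames(traj)
  if (Tn < 2L) stop("need at least 2 frames")
  v <- velocitiesFromPositions(traj)
  recorded <- useRecordedStates && !anyNA(traj@moving)
  mov <- if (recorded) traj@moving else classifyMotionStates(traj, threshold)
  mov[!traj@present] <- NA

  out <- data.frame(frame = seq_len(Tn - 1L), P = NA_real_,
                    M_ang = NA_real_, M_abs = NA_real_, d_a = NA_real_,
                    Mov_pct = NA_real_)
  for (s in seq_len(Tn - 1L)) {
    t <- s + 1L                      # frame index in the trajectory arrays
    keep <- traj@present[t, ]
    pt <- matrix(traj@positions[t, keep, ], ncol = 2)
    vt <- matrix(v[s, keep, ], ncol = 2)
    out$P[s] <- polarization(vt)
    out$M_ang[s] <- angularMomentum(pt, vt)
    out$M_abs[s] <- absoluteAngularMomentum(pt, vt)
    out$d_a[s] <- meanNNDistance(pt)
    out$Mov_pct[s] <- percentMoving(mov[t, keep])
  }
  out
}

#' Long-format order parameters
#'
#' Tidy `(frame, name, value)` rendering of [computeOrderParameters()],
#' matching the on-disk CSV the command-line interface writes.
#'
#' @inheritParams computeOrderParameters
#' @return Data frame with columns `frame`, `name`, `value`.
#' @export
orderParametersLong <- function(traj, ...) {
  wide <- computeOrderParameters(traj, ...)
  nm <- setdiff(names(wide), "frame")
  data.frame(frame = rep(wide$frame, length(nm)),
             name = rep(nm, each = nrow(wide)),
             value = unlist(wide[nm], use.names = FALSE))
}
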