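#' Construct a TrajectorySet
#'
#' Low-level constructor; most trajectories come from
#' [simulateTrajectories()], [generatePseudoExperiment()] or
#' [readTrajectory()].
#'
#' @param positions T x N x 2 numeric array (m).
#' @param moving T x N logical matrix (`TRUE` = moving state). Defaults to
#'   all-stationary.
#' @param headings T x N numeric matrix of headings (rad); defaults to `NA`.
#' @param present T x N logical presence mask; defaults to all-present.
#' @param arena An [ArenaConfig-class].
#' @param seed Integer seed recorded as provenance, or `NA`.
#' @return A validated [TrajectorySet-class].
#' @export
trajectorySet <- function(positions, moving = NULL, headings = NULL,
                          present = NULL, arena = arenaConfig(),
                          seed = NA_integer_) {
  d <- dim(positions)
  if (is.null(moving)) moving <- matrix(FALSE, d[1], d[2])
  if (is.null(headings)) headings <- matrix(NA_real_, d[1], d[2])
  if (is.null(present)) present <- matrix(TRUE, d[1], d[2])
  new("TrajectorySet", positions = positions, moving = moving,
      headings = headings, present = present, arena = arena,
      seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("agentPositions", "TrajectorySet", function(object)
  object@positions)

#' @rdname accessors
#' @export
setMethod("motionStates", "TrajectorySet", function(object) object@moving)

#' @rdname accessors
#' @export
setMethod("headings", "TrajectorySet", function(object) object@headings)

#' @rdname accessors
#' @export
setMethod("presentMask", "TrajectorySet", function(object) object@present)

#' @rdname accessors
#' @export
setMethod("arena", "TrajectorySet", function(object) object@arena)

#' @rdname accessors
#' @export
setMethod("nFrames", "TrajectorySet", function(object)
  dim(object@positions)[1])

#' @rdname accessors
#' @export
setMethod("nAgents", "TrajectorySet", function(object)
  dim(object@positions)[2])

setMethod("show", "TrajectorySet", function(object) {
  d <- dim(object@positions)
  nAbsent <- sum(!object@present)
  cat("TrajectorySet:", d[2], "agents x", d[1], "frames",
      sprintf("(%.1f min at %g s/frame)\n",
              d[1] * object@arena@frameDuration / 60,
              object@arena@frameDuration))
  cat("  arena radius", object@arena@radius, "m;",
      if (nAbsent) sprintf("%d masked (agent, frame) entries", nAbsent)
      else "no tracking dropouts", "\n")
  if (!is.na(object@seed)) cat("  seed:", object@seed, "\n")
})

#' Positions of present agents at one frame
#'
#' @param traj A [TrajectorySet-class].
#' @param frame 1-based frame index.
#' @return M x 2 matrix of the positions of the M agents present at that
#'   frame.
#' @export
framePositions <- function(traj, frame) {
  keep <- traj@present[frame, ]
  matrix(traj@positions[frame, keep, , drop = FALSE], ncol = 2)
}

#' Extract the initial configuration of a trajectory
#'
#' The first-frame positions of agents present at frame one, wrapped as an
#' [InitialConfiguration-class] so a trajectory can seed new simulations —
#' the way experimental trials seed model runs.
#'
#' @param traj A [TrajectorySet-class].
#' @return An [InitialConfiguration-class] with pattern `"from_file"`.
#' @export
initialConfiguration <- function(traj) {
  new("InitialConfiguration", positions = framePositions(traj, 1L),
      pattern = "from_file", arena = traj@arena)
}

setMethod("show", "InitialConfiguration", function(object) {
  cat("InitialConfiguration:", nrow(object@positions), "agents, pattern",
      sQuote(object@pattern), "in arena of radius",
      object@arena@radius, "m\n")
})

#' @rdname accessors
#' @export
setMethod("agentPositions", "InitialConfiguration", function(object)
  object@positions)

#' @rdname accessors
#' @export
setMethod("nAgents", "InitialConfiguration", function(object)
  nrow(object@positions))

#' @rdname accessors
#' @export
setMethod("arena", "InitialConfiguration", function(object) object@arena)
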