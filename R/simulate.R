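## Core stochastic simulator: a stop-start correlated random walk in a
## circular arena. Each frame: (i) every agent's distance d to its nearest
## (present) neighbour is computed from the positions at the start of the
## frame; (ii) motion states flip with the distance-dependent transition
## probabilities; (iii) agents in the moving state step by the
## distance-dependent step length along their heading (boundary-reflected)
## and then turn by a wrapped-Cauchy angle whose spread depends on d.
## Updates are synchronous. The random stream is consumed in a fixed order
## (one uniform per agent for transitions, then one per agent for turns),
## so control-model state sequences are identical across spatial
## configurations under the same seed.

.nnDistancesMasked <- function(pos, present) {
  n <- nrow(pos)
  d <- rep(Inf, n)           # an agent with no present neighbour sees d = Inf
  idx <- which(present)
  if (length(idx) >= 2L)
    d[idx] <- nearestNeighborDistances(pos[idx, , drop = FALSE])
  d
}

.reflectAll <- function(pos, R, rule) {
  r <- sqrt(rowSums(pos^2))
  out <- which(r > R)
  for (i in out)
    pos[i, ] <- reflectIntoArena(c(0, 0), pos[i, ], arenaConfig(radius = R),
                                 rule = rule)
  pos
}

#' Advance one frame of the stop-start walk
#'
#' Synchronous single-frame update used by [simulateTrajectories()]; exposed
#' for step-by-step inspection. Consumes the supplied uniform variates
#' (`uTrans` for state transitions, `uTurn` for turning angles, one per
#' agent) instead of drawing, which makes frame updates replayable.
#'
#' @param pos N x 2 position matrix (m).
#' @param moving Logical vector: current motion state.
#' @param headings Numeric vector of headings (rad).
#' @param present Logical vector: agents visible to the distance computation.
#' @param params A [ModelParams-class].
#' @param arena An [ArenaConfig-class].
#' @param uTrans,uTurn Uniform(0,1) variates, one per agent.
#' @param transitionTiming `"before_move"` (default: states flip, then the
#'   agents moving afterwards step) or `"after_move"` (agents move per their
#'   incoming state, then states flip).
#' @param turnTiming `"after_step"` (default: step along the old heading,
#'   then turn) or `"before_step"`.
#' @param reflection Boundary rule passed to [reflectIntoArena()].
#' @return List with updated `pos`, `moving`, `headings`.
#' @export
advanceFrame <- function(pos, moving, headings, present, params, arena,
                         uTrans, uTurn,
                         transitionTiming = c("before_move", "after_move"),
                         turnTiming = c("after_step", "before_step"),
                         reflection = c("radial", "specular")) {
  transitionTiming <- match.arg(transitionTiming)
  turnTiming <- match.arg(turnTiming)
  reflection <- match.arg(reflection)
  n <- nrow(pos)
  if (length(moving) != n || length(headings) != n || length(present) != n ||
      length(uTrans) != n || length(uTurn) != n)
    stop("mismatched per-agent vector lengths")

  d <- .nnDistancesMasked(pos, present)

  transition <- function(moving) {
    pStop <- pMoveToStop(d, params)
    pGo <- pStopToMove(d, params)
    flip <- ifelse(moving, uTrans < pStop, uTrans < pGo)
    xor(moving, flip)
  }
  move <- function(moving, headings) {
    act <- which(moving)
    if (length(act)) {
      ell <- stepLength(d[act], params)
      rho <- spreadParam(d[act], params)
      turn <- .wrappedCauchyTransform(uTurn[act], rho)
      if (turnTiming == "before_step")
        headings[act] <- headings[act] + turn
      step <- cbind(ell * cos(headings[act]), ell * sin(headings[act]))
      pos[act, ] <- .reflectAll(pos[act, , drop = FALSE] + step,
                                arena@radius, reflection)
      if (turnTiming == "after_step")
        headings[act] <- headings[act] + turn
    }
    list(pos = pos, headings = headings)
  }

  if (transitionTiming == "before_move") {
    moving <- transition(moving)
    m <- move(moving, headings)
  } else {
    m <- move(moving, headings)
    moving <- transition(moving)
  }
  list(pos = m$pos, moving = moving, headings = m$headings)
}

#' Simulate a trial of the aphid motion model
#'
#' Runs the interactive or control stop-start walk from an initial
#' configuration for a fixed number of frames. Frame one of the result is
#' the initial configuration itself. Initial headings are uniform on
#' `(-pi, pi]`; initial states are all-stationary by default, or drawn from
#' the two-state Markov stationary distribution at each agent's initial
#' nearest-neighbour distance (`initialStates = "steady"`).
#'
#' @param ic An [InitialConfiguration-class].
#' @param params A [ModelParams-class].
#' @param nFrames Total number of frames (>= 1), including the initial one.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @param initialStates `"stationary"` or `"steady"`.
#' @inheritParams advanceFrame
#' @return A [TrajectorySet-class] with exact motion states recorded.
#' @examples
#' ic <- generateInitialConditions(7, "dispersed", seed = 1)
#' simulateTrajectories(ic, aphidModelParams(), nFrames = 50, seed = 1)
#' @export
simulateTrajectories <- function(ic, params, nFrames, seed = NULL,
                                 initialStates = c("stationary", "steady"),
                                 transitionTiming = c("before_move",
                                                      "after_move"),
                                 turnTiming = c("after_step", "before_step"),
                                 reflection = c("radial", "specular")) {
  stopifnot(is(ic, "InitialConfiguration"), is(params, "ModelParams"))
  validObject(params)
  initialStates <- match.arg(initialStates)
  transitionTiming <- match.arg(transitionTiming)
  turnTiming <- match.arg(turnTiming)
  reflection <- match.arg(reflection)
  if (nFrames < 1L) stop("nFrames must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  n <- nAgents(ic)
  pos <- array(NA_real_, c(nFrames, n, 2))
  mov <- matrix(NA, nFrames, n)
  hdg <- matrix(NA_real_, nFrames, n)

  p <- ic@positions
  h <- stats::runif(n, -pi, pi)
  if (initialStates == "stationary") {
    m <- rep(FALSE, n)
  } else {
    d0 <- .nnDistancesMasked(p, rep(TRUE, n))
    pGo <- pStopToMove(d0, params)
    pStop <- pMoveToStop(d0, params)
    m <- stats::runif(n) < pGo / (pGo + pStop)
  }
  pos[1, , ] <- p; mov[1, ] <- m; hdg[1, ] <- h

  t <- 2L
  while (t <= nFrames) {
    st <- advanceFrame(p, m, h, rep(TRUE, n), params, ic@arena,
                       uTrans = stats::runif(n), uTurn = stats::runif(n),
                       transitionTiming = transitionTiming,
                       turnTiming = turnTiming, reflection = reflection)
    p <- st$pos; m <- st$moving; h <- st$headings
    pos[t, , ] <- p; mov[t, ] <- m; hdg[t, ] <- h
    t <- t + 1L
  }

  trajectorySet(pos, moving = mov, headings = hdg, arena = ic@arena,
                seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Run an ensemble of simulations
#'
#' Convenience batch driver: `nRuns` independent realizations of one
#' model/initial-condition pair, drawn from a single seeded random stream.
#'
#' @inheritParams simulateTrajectories
#' @param nRuns Number of realizations.
#' @return List of [TrajectorySet-class] objects.
#' @export
simulateEnsemble <- function(ic, params, nFrames, nRuns, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nRuns), function(i)
    simulateTrajectories(ic, params, nFrames, seed = NULL, ...))
}
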