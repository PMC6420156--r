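#' @import methods
NULL

#' Circular arena configuration
#'
#' Geometry and frame timing of the experimental arena: a featureless circular
#' dish in which the insects walk, filmed at a fixed frame rate. All
#' coordinates in the package are arena-centred and in metres; time is indexed
#' by frame.
#'
#' @slot radius Arena radius in metres (default 0.2, i.e. a 40 cm dish).
#' @slot frameDuration Duration of one video frame in seconds (default 0.5).
#'
#' @seealso [arenaConfig()]
#' @exportClass ArenaConfig
setClass("ArenaConfig",
  representation(radius = "numeric", frameDuration = "numeric"))

setValidity("ArenaConfig", function(object) {
  msg <- character()
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    msg <- c(msg, "radius must be a single positive number")
  if (length(object@frameDuration) != 1L || !is.finite(object@frameDuration) ||
      object@frameDuration <= 0)
    msg <- c(msg, "frameDuration must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Fitted parameters of the aphid motion models
#'
#' Holds the twelve fitted constants of the stop-start correlated random walk,
#' plus the model kind. Moving insects stop with probability
#' \eqn{P_{MS}(d) = P_{MS}^\infty + (P_{MS}^0 - P_{MS}^\infty) e^{-d/d_{MS}}},
#' stationary insects start moving with probability
#' \eqn{P_{SM}(d) = P_{SM}^0 e^{-d/d_{SM}} + P_{SM}^\infty d/(d+\Delta_{SM})},
#' moving insects step by
#' \eqn{\ell(d) = \ell^\infty + (\ell^0 - \ell^\infty) e^{-d/d_\ell}} and turn
#' by a wrapped-Cauchy angle with spread
#' \eqn{\rho(d) = \rho^\infty + (\rho^0 - \rho^\infty) e^{-d/d_\rho}}, where
#' \eqn{d} is the distance to the nearest neighbour. The \emph{interactive}
#' kind uses these distance-dependent forms; the \emph{control} kind freezes
#' all four quantities at their \eqn{d \to \infty} limits, removing social
#' interaction.
#'
#' @slot pmsInf,pms0 Limiting and zero-distance moving-to-stopped
#'   probabilities.
#' @slot dMs Length scale (m) of the moving-to-stopped decay.
#' @slot psm0,psmInf Zero-distance and limiting stopped-to-moving
#'   probabilities.
#' @slot dSm,deltaSm Length scales (m) of the stopped-to-moving form.
#' @slot ellInf,ell0 Limiting and zero-distance step lengths (m).
#' @slot dEll Length scale (m) of the step-length transition.
#' @slot rhoInf,rho0 Limiting and zero-distance wrapped-Cauchy spread values.
#' @slot dRho Length scale (m) of the spread transition.
#' @slot kind `"interactive"` or `"control"`.
#'
#' @seealso [aphidModelParams()]
#' @exportClass ModelParams
setClass("ModelParams",
  representation(
    pmsInf = "numeric", pms0 = "numeric", dMs = "numeric",
    psm0 = "numeric", psmInf = "numeric", dSm = "numeric", deltaSm = "numeric",
    ellInf = "numeric", ell0 = "numeric", dEll = "numeric",
    rhoInf = "numeric", rho0 = "numeric", dRho = "numeric",
    kind = "character"))

setValidity("ModelParams", function(object) {
  msg <- character()
  prob <- c(pmsInf = object@pmsInf, pms0 = object@pms0,
            psm0 = object@psm0, psmInf = object@psmInf)
  if (any(prob < 0 | prob > 1))
    msg <- c(msg, "transition probabilities must lie in [0, 1]")
  lens <- c(dMs = object@dMs, dSm = object@dSm, deltaSm = object@deltaSm,
            dEll = object@dEll, dRho = object@dRho,
            ellInf = object@ellInf, ell0 = object@ell0)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "length scales and step lengths must be positive")
  if (object@rho0 <= 0 || object@rho0 >= 1 ||
      object@rhoInf <= 0 || object@rhoInf >= 1)
    msg <- c(msg, "spread parameters rho0, rhoInf must lie in (0, 1)")
  if (length(object@kind) != 1L ||
      !object@kind %in% c("interactive", "control"))
    msg <- c(msg, "kind must be 'interactive' or 'control'")
  if (length(msg)) msg else TRUE
})

#' Initial spatial configuration of a trial
#'
#' Positions of the N agents at frame zero, together with the pattern label
#' used to generate them and the arena they live in.
#'
#' @slot positions N x 2 matrix of arena-centred coordinates (m).
#' @slot pattern One of `"clustered"`, `"dispersed"`, `"ring"`, `"from_file"`.
#' @slot arena An [ArenaConfig-class] object.
#'
#' @seealso [generateInitialConditions()]
#' @exportClass InitialConfiguration
setClass("InitialConfiguration",
  representation(positions = "matrix", pattern = "character",
                 arena = "ArenaConfig"))

setValidity("InitialConfiguration", function(object) {
  msg <- character()
  p <- object@positions
  if (!is.numeric(p) || ncol(p) != 2L)
    msg <- c(msg, "positions must be a numeric N x 2 matrix")
  else {
    if (nrow(p) < 2L)
      msg <- c(msg, "at least 2 agents are required")
    r <- sqrt(rowSums(p^2))
    if (any(r > object@arena@radius + 1e-12))
      msg <- c(msg, "all initial positions must lie inside the arena")
  }
  if (length(object@pattern) != 1L ||
      !object@pattern %in% c("clustered", "dispersed", "ring", "from_file"))
    msg <- c(msg, "unknown pattern label")
  if (length(msg)) msg else TRUE
})

#' A set of agent trajectories over frames
#'
#' Dense per-frame record of a simulated or tracked trial: positions, motion
#' states, headings and a presence mask for N agents over T frames. Absent
#' (masked) entries model motion-tracking dropouts; downstream computations
#' treat them as missing. Positions of masked frames may still be retained
#' internally (the simulator knows where every agent is) but are never used
#' by consumers.
#'
#' @slot positions T x N x 2 numeric array of coordinates (m).
#' @slot moving T x N logical matrix; `TRUE` where the agent is in the moving
#'   state.
#' @slot headings T x N numeric matrix of headings in radians (NA where
#'   unknown, e.g. trajectories read from file).
#' @slot present T x N logical matrix; `FALSE` marks tracking dropouts.
#' @slot arena An [ArenaConfig-class].
#' @slot seed Integer seed the trajectory was generated with, or `NA`.
#'
#' @seealso [simulateTrajectories()], [generatePseudoExperiment()],
#'   [readTrajectory()]
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(positions = "array", moving = "matrix", headings = "matrix",
                 present = "matrix", arena = "ArenaConfig", seed = "integer"))

setValidity("TrajectorySet", function(object) {
  msg <- character()
  d <- dim(object@positions)
  if (length(d) != 3L || d[3] != 2L)
    return("positions must be a T x N x 2 array")
  if (d[1] < 1L || d[2] < 1L)
    msg <- c(msg, "need T >= 1 frames and N >= 1 agents")
  for (nm in c("moving", "headings", "present")) {
    m <- slot(object, nm)
    if (!identical(dim(m), d[1:2]))
      msg <- c(msg, sprintf("%s must be a T x N matrix matching positions", nm))
  }
  if (!length(msg)) {
    r2 <- object@positions[, , 1]^2 + object@positions[, , 2]^2
    ok <- !object@present | is.na(r2) | r2 <= (object@arena@radius + 1e-12)^2
    if (!all(ok))
      msg <- c(msg, "present positions must lie inside the closed arena disk")
  }
  if (length(msg)) msg else TRUE
})

#' Crocker matrix of Betti numbers
#'
#' A crocker ("Contour Realization Of Computed k-dimensional hole Evolution in
#' the Rips complex") stores the Betti number \eqn{b_k(t, \epsilon)} of the
#' Vietoris-Rips complex built on the point cloud at each sampled frame, over
#' a grid of proximity values. Rows index the \eqn{\epsilon} grid, columns the
#' sampled frames. Entries are non-negative integers for a single trajectory,
#' or non-negative reals for an ensemble average.
#'
#' @slot betti Numeric matrix, `length(epsGrid)` rows by `length(times)`
#'   columns.
#' @slot epsGrid Ascending proximity values; by convention 50 uniform samples
#'   from 0 to the maximum filtration value.
#' @slot times Sampled frame indices (0-based).
#' @slot k Homology dimension, 0 (components) or 1 (loops); a concatenated
#'   crocker stores `NA`.
#' @slot mode `"pos"` (2-D positions) or `"posvel"` (normalized 4-D
#'   position-velocity points), or a derived label.
#' @slot averaged `TRUE` for element-wise ensemble means (real entries).
#'
#' @seealso [computeCrocker()], [averageCrocker()], [concatenateCrockers()]
#' @exportClass Crocker
setClass("Crocker",
  representation(betti = "matrix", epsGrid = "numeric", times = "integer",
                 k = "integer", mode = "character", averaged = "logical"))

setValidity("Crocker", function(object) {
  msg <- character()
  if (!identical(dim(object@betti),
                 c(length(object@epsGrid), length(object@times))))
    msg <- c(msg, "betti must be length(epsGrid) x length(times)")
  if (is.unsorted(object@epsGrid, strictly = TRUE))
    msg <- c(msg, "epsGrid must be strictly ascending")
  if (any(object@betti < 0, na.rm = TRUE))
    msg <- c(msg, "Betti entries must be non-negative")
  if (!object@averaged && any(object@betti != round(object@betti)))
    msg <- c(msg, "non-averaged crocker entries must be integers")
  if (!is.na(object@k) && !object@k %in% c(0L, 1L))
    msg <- c(msg, "homology dimension k must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Result of one model-vs-model comparison
#'
#' For one summary measure, the mean distance from a reference trajectory to
#' an ensemble of interactive-model runs (`dInt`) and to an ensemble of
#' control-model runs (`dCon`), the difference of means `D = dCon - dInt`, a
#' Bonferroni-corrected confidence radius `r95`, and the verdict:
#' `"interactive"` if `D - r95 > 0` (interactive runs are significantly
#' closer to the reference), `"control"` if `D + r95 < 0`, otherwise
#' `"inconclusive"`.
#'
#' @slot measure Label of the summary measure compared.
#' @slot dInt,dCon Mean per-run distances for the two ensembles.
#' @slot D Difference of means `dCon - dInt`.
#' @slot r95 Confidence radius at the corrected level.
#' @slot alphaCorrected Per-comparison significance level actually used.
#' @slot verdict `"interactive"`, `"control"` or `"inconclusive"`.
#' @slot intDistances,conDistances Per-run distance samples.
#'
#' @seealso [compareModels()], [resultsTable()]
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(measure = "character", dInt = "numeric", dCon = "numeric",
                 D = "numeric", r95 = "numeric", alphaCorrected = "numeric",
                 verdict = "character",
                 intDistances = "numeric", conDistances = "numeric"))

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (any(object@intDistances < 0) || any(object@conDistances < 0))
    msg <- c(msg, "distances must be non-negative")
  if (!object@verdict %in% c("interactive", "control", "inconclusive"))
    msg <- c(msg, "unknown verdict label")
  expected <- if (object@D - object@r95 > 0) "interactive"
              else if (object@D + object@r95 < 0) "control"
              else "inconclusive"
  if (object@verdict != expected)
    msg <- c(msg, "verdict inconsistent with the interval-excludes-zero rule")
  if (length(msg)) msg else TRUE
})
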