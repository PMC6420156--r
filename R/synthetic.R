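#' Aphid counts of the nine reference trials
#'
#' The nine experimental trials the analysis was designed around used groups
#' of 19, 28, 27, 33, 27, 30, 26, 7 and 9 aphids; offered as presets for
#' synthetic studies that mirror the trial sizes.
#'
#' @return Integer vector of length nine.
#' @export
aphidTrialSizes <- function() c(19L, 28L, 27L, 33L, 27L, 30L, 26L, 7L, 9L)

#' Generate a synthetic initial configuration
#'
#' Draws N agent positions inside the circular arena in one of three spatial
#' patterns emulating the reference trials: `"clustered"` (uniform in a
#' sub-disk of radius `clusterFraction * R` around a random interior centre —
#' the tight huddles seen at the start of most trials), `"dispersed"`
#' (uniform over the whole disk) or `"ring"` (jittered positions near a
#' circle of radius `0.7 R`, a regression-friendly extreme of spread-out
#' groups).
#'
#' @param nAgents Number of agents (>= 2).
#' @param pattern `"clustered"`, `"dispersed"` or `"ring"`.
#' @param arena An [ArenaConfig-class].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param clusterFraction Sub-disk radius for the clustered pattern, as a
#'   fraction of the arena radius (default 0.25).
#' @return An [InitialConfiguration-class].
#' @examples
#' generateInitialConditions(30, "clustered", seed = 1)
#' @export
generateInitialConditions <- function(nAgents,
                                      pattern = c("clustered", "dispersed",
                                                  "ring"),
                                      arena = arenaConfig(), seed = NULL,
                                      clusterFraction = 0.25) {
  pattern <- match.arg(pattern)
  if (nAgents < 2L) stop("nAgents must be >= 2")
  if (clusterFraction <= 0 || clusterFraction > 1)
    stop("clusterFraction must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  R <- arena@radius

  unifDisk <- function(n, radius) {
    r <- radius * sqrt(stats::runif(n))
    a <- stats::runif(n, -pi, pi)
    cbind(r * cos(a), r * sin(a))
  }

  pos <- switch(pattern,
    dispersed = unifDisk(nAgents, 0.999 * R),
    clustered = {
      rc <- clusterFraction * R
      ctr <- unifDisk(1L, R - rc)   # cluster fully inside the arena
      sweep(unifDisk(nAgents, 0.999 * rc), 2L, ctr, "+")
    },
    ring = {
      a <- stats::runif(nAgents, -pi, pi)
      r <- pmin(0.999 * R, pmax(0, 0.7 * R + stats::rnorm(nAgents, 0,
                                                          0.03 * R)))
      cbind(r * cos(a), r * sin(a))
    })
  new("InitialConfiguration", positions = pos, pattern = pattern,
      arena = arena)
}

#' Generate a pseudo-experimental trajectory
#'
#' Produces a synthetic stand-in for an experimental tracking record: one
#' realization of a motion model, optionally overlaid with motion-tracking
#' dropouts in which agents vanish from the record for short runs of frames
#' and are later picked back up. Each agent independently begins an absence
#' run at per-frame rate `dropoutRate`; run lengths are geometric with the
#' given mean. Positions during masked frames are retained internally but
#' all downstream computations treat them as missing. The initial frame is
#' never masked. When the generating model is the interactive model, the
#' ground truth for model-selection checks is known: the interactive model
#' should be preferred.
#'
#' @inheritParams simulateTrajectories
#' @param dropoutRate Per-frame probability, in `[0, 1)`, that a visible
#'   agent starts an absence run.
#' @param meanDropoutLen Mean absence-run length in frames (>= 1).
#' @param ... Passed to [simulateTrajectories()].
#' @return A [TrajectorySet-class] with a presence mask.
#' @examples
#' ic <- generateInitialConditions(9, "clustered", seed = 3)
#' generatePseudoExperiment(ic, aphidModelParams(), nFrames = 100,
#'                          dropoutRate = 0.01, seed = 3)
#' @export
generatePseudoExperiment <- function(ic, params, nFrames, dropoutRate = 0,
                                     meanDropoutLen = 3, seed = NULL, ...) {
  if (is.na(dropoutRate) || dropoutRate < 0 || dropoutRate >= 1)
    stop("dropoutRate must lie in [0, 1)")
  if (meanDropoutLen < 1) stop("meanDropoutLen must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  traj <- simulateTrajectories(ic, params, nFrames, seed = NULL, ...)
  if (dropoutRate > 0) {
    n <- nAgents(traj)
    present <- traj@present
    ## geometric run length with the given mean: success prob 1/mean
    pEnd <- 1 / meanDropoutLen
    for (a in seq_len(n)) {
      t <- 2L
      while (t <= nFrames) {
        if (stats::runif(1) < dropoutRate) {
          len <- 1L + stats::rgeom(1L, pEnd)
          present[t:min(nFrames, t + len - 1L), a] <- FALSE
          t <- t + len
        }
        t <- t + 1L
      }
    }
    traj@present <- present
  }
  traj
}
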