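## The four distance-response functions of the walk model, the wrapped-Cauchy
## turning-angle machinery, nearest-neighbour distances and the arena
## boundary rule. All four response functions are vectorized over d, accept
## d = Inf exactly, and — for a control-kind ModelParams — ignore d and
## return the d -> infinity limit (the control model has no social term).

.checkDistance <- function(d) {
  if (any(is.na(d)) || any(d < 0))
    stop("nearest-neighbour distance d must be >= 0 (Inf allowed)")
}

.effectiveDistance <- function(d, params) {
  if (params@kind == "control") rep(Inf, length(d)) else d
}

## exp(-Inf) = 0 in R, so the d = Inf limit falls out of the exponential
## forms; only the saturating ratio d/(d + Delta) needs an explicit branch.

#' Distance-dependent model response functions
#'
#' The stop-start walk is driven by four functions of an agent's distance
#' \eqn{d} to its nearest neighbour: the probability per frame that a moving
#' agent stops, the probability that a stationary agent starts moving, the
#' step length taken while moving, and the spread parameter of the
#' wrapped-Cauchy turning-angle distribution. Each interpolates exponentially
#' (or, for the stopped-to-moving probability, with an additional saturating
#' term) between a zero-distance value and an infinite-distance limit. For a
#' control-kind [ModelParams-class] every function returns its
#' \eqn{d \to \infty} limit regardless of `d`.
#'
#' @param d Non-negative distance(s) in metres; `Inf` is allowed and gives
#'   the limiting value.
#' @param params A [ModelParams-class] object.
#' @return Numeric vector the length of `d`.
#' @examples
#' p <- aphidModelParams()
#' pMoveToStop(0, p)    # 0.5508
#' pMoveToStop(Inf, p)  # 0.1280
#' stepLength(c(0, Inf), p)
#' @export
pMoveToStop <- function(d, params) {
  .checkDistance(d)
  d <- .effectiveDistance(d, params)
  params@pmsInf + (params@pms0 - params@pmsInf) * exp(-d / params@dMs)
}

#' @rdname pMoveToStop
#' @export
pStopToMove <- function(d, params) {
  .checkDistance(d)
  d <- .effectiveDistance(d, params)
  sat <- ifelse(is.infinite(d), 1, d / (d + params@deltaSm))
  params@psm0 * exp(-d / params@dSm) + params@psmInf * sat
}

#' @rdname pMoveToStop
#' @export
stepLength <- function(d, params) {
  .checkDistance(d)
  d <- .effectiveDistance(d, params)
  params@ellInf + (params@ell0 - params@ellInf) * exp(-d / params@dEll)
}

#' @rdname pMoveToStop
#' @export
spreadParam <- function(d, params) {
  .checkDistance(d)
  d <- .effectiveDistance(d, params)
  params@rhoInf + (params@rho0 - params@rhoInf) * exp(-d / params@dRho)
}

#' Wrapped Cauchy turning-angle distribution
#'
#' Density and sampler for the wrapped Cauchy distribution centred at zero,
#' \deqn{f(\theta) = \frac{1}{2\pi}\frac{1-\rho^2}{1+\rho^2-2\rho\cos\theta},}
#' the turning-angle law of the walk. `rho = 0` is the circular uniform
#' distribution; `rho` close to 1 concentrates the mass at zero. The circular
#' mean resultant length of the distribution equals `rho`.
#'
#' Sampling uses the inverse-CDF tangent transform of a uniform variate,
#' \eqn{\theta = 2\arctan\left(\frac{1-\rho}{1+\rho}\tan(\pi(u-1/2))\right)}.
#'
#' @param theta Angle(s) in radians.
#' @param n Number of draws.
#' @param rho Spread parameter in `[0, 1)`.
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return `dWrappedCauchy`: densities; `sampleTurningAngle`: `n` angles in
#'   `(-pi, pi]`.
#' @examples
#' dWrappedCauchy(0, 0.5)            # 3 / (2 * pi)
#' sampleTurningAngle(5, 0.9, seed = 1)
#' @export
dWrappedCauchy <- function(theta, rho) {
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho >= 1)
    stop("rho must be a single value in [0, 1)")
  (1 - rho^2) / (2 * pi * (1 + rho^2 - 2 * rho * cos(theta)))
}

#' @rdname dWrappedCauchy
#' @export
sampleTurningAngle <- function(n, rho, seed = NULL) {
  if (any(is.na(rho)) || any(rho < 0) || any(rho >= 1))
    stop("rho must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  .wrappedCauchyTransform(u, rho)
}

## maps u ~ U(0,1) to a wrapped-Cauchy(0, rho) angle; vectorized over both
## arguments (rho may be per-draw, as in the simulator).
.wrappedCauchyTransform <- function(u, rho) {
  theta <- 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
  ## atan maps into (-pi, pi); fold the measure-zero endpoint convention
  ifelse(theta <= -pi, pi, theta)
}

#' Per-agent nearest-neighbour distances
#'
#' For each point, the minimum Euclidean distance to any other point. This is
#' the distance `d` that drives all four model response functions.
#'
#' @param points Numeric N x 2 matrix of coordinates (N >= 2).
#' @return Numeric vector of length N.
#' @examples
#' nearestNeighborDistances(rbind(c(0, 0), c(0.03, 0)))
#' @export
nearestNeighborDistances <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L)
    stop("nearest-neighbour distance needs at least 2 points")
  dm <- as.matrix(stats::dist(points))
  diag(dm) <- Inf
  unname(apply(dm, 1L, min))
}

#' Reflect an overshooting step back into the arena
#'
#' Agents stepping through the circular boundary are reflected back inside.
#' The default `"radial"` rule mirrors the radius: a proposed point at radius
#' `r > R` on a ray from the centre returns at radius `2R - r` on the same
#' ray. The `"specular"` rule mirrors the overshoot across the tangent line
#' at the boundary-crossing point of the radial direction. With steps three
#' orders of magnitude smaller than the arena radius the two rules are
#' numerically indistinguishable; both are provided. Any residual overshoot
#' (possible only for steps longer than 2R) is clamped to the boundary.
#'
#' @param previous Position before the step (must be inside the arena).
#' @param proposed Proposed position after the step.
#' @param arena An [ArenaConfig-class].
#' @param rule `"radial"` or `"specular"`.
#' @return A 2-vector inside the closed arena disk. Proposed points already
#'   inside are returned unchanged.
#' @export
reflectIntoArena <- function(previous, proposed, arena,
                             rule = c("radial", "specular")) {
  rule <- match.arg(rule)
  R <- arena@radius
  if (sum(previous^2) > R^2 * (1 + 1e-9))
    stop("previous position lies outside the arena: upstream invariant breach")
  r <- sqrt(sum(proposed^2))
  if (r <= R) return(proposed)
  if (rule == "radial") {
    out <- proposed * (2 * R - r) / r
    if (2 * R - r < 0) out <- -proposed * R / r  # clamp huge overshoots
  } else {
    ## specular: reflect the part of the step beyond the boundary across the
    ## tangent plane at the radial exit point
    uhat <- proposed / r
    excess <- r - R
    out <- proposed - 2 * excess * uhat
    rr <- sqrt(sum(out^2))
    if (rr > R) out <- out * R / rr
  }
  out
}
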