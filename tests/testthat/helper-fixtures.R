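# Shared fixtures: tiny deterministic trajectories and point configurations
# built in code.

fixtureParams <- function(kind = "interactive") aphidModelParams(kind)

# N agents on a circle of radius r, rotating rigidly by dtheta per frame
rotationTrajectory <- function(n = 6, r = 0.1, dtheta = 0.02, nFrames = 20,
                               arena = arenaConfig()) {
  pos <- array(NA_real_, c(nFrames, n, 2))
  base <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  for (t in seq_len(nFrames)) {
    a <- base + (t - 1) * dtheta
    pos[t, , 1] <- r * cos(a)
    pos[t, , 2] <- r * sin(a)
  }
  trajectorySet(pos, moving = matrix(TRUE, nFrames, n), arena = arena)
}

# uniform drift by delta per frame along x
driftTrajectory <- function(n = 5, delta = 1e-3, nFrames = 10,
                            arena = arenaConfig()) {
  pos <- array(NA_real_, c(nFrames, n, 2))
  y0 <- seq(-0.05, 0.05, length.out = n)
  for (t in seq_len(nFrames)) {
    pos[t, , 1] <- -0.05 + (t - 1) * delta
    pos[t, , 2] <- y0
  }
  trajectorySet(pos, moving = matrix(TRUE, nFrames, n), arena = arena)
}

constantTrajectory <- function(n = 6, nFrames = 8, seed = 1,
                               arena = arenaConfig()) {
  set.seed(seed)
  p0 <- cbind(runif(n, -0.1, 0.1), runif(n, -0.1, 0.1))
  pos <- array(NA_real_, c(nFrames, n, 2))
  for (t in seq_len(nFrames)) pos[t, , ] <- p0
  trajectorySet(pos, arena = arena)
}

# five pairs 2 cm within pairs, pair centres far apart (>= 5 cm separation)
fivePairsCloud <- function() {
  centres <- cbind(c(-0.15, -0.075, 0, 0.075, 0.15), rep(0, 5))
  rbind(centres + cbind(rep(0, 5), rep(0.01, 5)),
        centres + cbind(rep(0, 5), rep(-0.01, 5)))
}

randomCloud <- function(n, d = 2, scale = 1) {
  matrix(runif(n * d, -scale, scale), n, d)
}
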