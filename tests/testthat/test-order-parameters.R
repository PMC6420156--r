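# Collective-motion order parameters.

test_that("velocities are backward differences with missing propagation", {
  tr <- constantTrajectory(n = 4, nFrames = 6)
  v <- velocitiesFromPositions(tr)
  expect_equal(dim(v), c(5, 4, 2))
  expect_true(all(v == 0))

  dr <- driftTrajectory(n = 3, delta = 2e-3, nFrames = 5)
  v <- velocitiesFromPositions(dr)
  expect_true(all(abs(v[, , 1] - 2e-3) < 1e-15))
  expect_true(all(v[, , 2] == 0))

  # absence at t-1 undefines the velocity at t
  tr@present[3, 2] <- FALSE
  v <- velocitiesFromPositions(tr)
  expect_true(all(is.na(v[2, 2, ])))  # frame 3 uses frames 2 and 3
  expect_true(all(is.na(v[3, 2, ])))  # frame 4 uses the absent frame 3
  expect_false(anyNA(v[4, 2, ]))
  expect_error(velocitiesFromPositions(constantTrajectory(nFrames = 1)),
               "at least 2")
})

test_that("motion-state classification applies the 1e-4 m threshold", {
  pos <- array(0, c(2, 3, 2))
  pos[2, , 1] <- c(5e-5, 2e-4, 1e-4)   # below, above, exactly at threshold
  tr <- trajectorySet(pos)
  mv <- classifyMotionStates(tr)
  expect_identical(mv[2, ], c(FALSE, TRUE, FALSE))
  expect_error(classifyMotionStates(tr, threshold = 0), "positive")
})

test_that("polarization: alignment, cancellation and degenerate conventions", {
  v <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(polarization(v), 1)
  expect_equal(polarization(rbind(c(1, 0), c(-1, 0))), 0)
  expect_equal(polarization(matrix(0, 4, 2)), 0)  # all stationary
  expect_true(is.na(polarization(matrix(NA_real_, 2, 2))))
})

test_that("angular momenta: rotation, counterrotation, radial motion", {
  n <- 8
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pos <- cbind(cos(a), sin(a))
  tangential <- cbind(-sin(a), cos(a))
  expect_equal(angularMomentum(pos, 0.01 * tangential), 1)
  expect_equal(absoluteAngularMomentum(pos, 0.01 * tangential), 1)

  # symmetric counterrotating pair of pairs: M_ang = 0, M_abs = 1
  pos2 <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  v2 <- rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 0))
  expect_equal(angularMomentum(pos2, v2), 0)
  expect_equal(absoluteAngularMomentum(pos2, v2), 1)

  radial <- pos  # velocities parallel to centre-of-mass-relative positions
  expect_equal(absoluteAngularMomentum(pos, radial), 0)
  expect_equal(angularMomentum(matrix(0.1, 3, 2), matrix(0, 3, 2)), 0)
})

test_that("frame kernels match a naive double-loop oracle", {
  set.seed(14)
  for (i in 1:20) {
    m <- sample(2:10, 1)
    pos <- randomCloud(m, scale = 0.1)
    v <- randomCloud(m, scale = 0.002)
    # oracle: literal sums
    P0 <- sqrt(sum(colSums(v)^2)) / sum(sqrt(rowSums(v^2)))
    r <- sweep(pos, 2, colMeans(pos))
    cr <- numeric(m); den <- 0
    for (j in seq_len(m)) {
      cr[j] <- r[j, 1] * v[j, 2] - r[j, 2] * v[j, 1]
      den <- den + sqrt(sum(r[j, ]^2)) * sqrt(sum(v[j, ]^2))
    }
    expect_equal(polarization(v), P0)
    expect_equal(angularMomentum(pos, v), abs(sum(cr)) / den)
    expect_equal(absoluteAngularMomentum(pos, v), sum(abs(cr)) / den)
    dists <- as.matrix(dist(pos)); diag(dists) <- Inf
    expect_equal(meanNNDistance(pos), mean(apply(dists, 1, min)))
  }
})

test_that("mean nearest-neighbour distance condenses both pair scenarios", {
  expect_equal(meanNNDistance(fivePairsCloud()), 0.02)
  # a single cluster with per-agent NN distance 2 cm gives the same average
  chain <- cbind(seq(0, by = 0.02, length.out = 10), 0)
  expect_equal(meanNNDistance(chain), 0.02)
  expect_equal(meanNNDistance(rbind(c(0, 0), c(0.07, 0))), 0.07)
  expect_true(is.na(meanNNDistance(rbind(c(0, 0)))))
})

test_that("percent moving counts present agents only", {
  expect_equal(percentMoving(c(TRUE, TRUE)), 100)
  expect_equal(percentMoving(c(FALSE, FALSE, FALSE)), 0)
  expect_equal(percentMoving(c(TRUE, FALSE, NA, TRUE)), 200 / 3)
  expect_true(is.na(percentMoving(c(NA, NA))))
})

test_that("the five series align on T-1 frames with sensible fixtures", {
  tr <- constantTrajectory(n = 6, nFrames = 8)
  op <- computeOrderParameters(tr)
  expect_equal(nrow(op), 7)
  expect_equal(op$frame, 1:7)
  expect_true(all(op$Mov_pct == 0))
  expect_equal(var(op$d_a), 0)

  rot <- rotationTrajectory(dtheta = 0.005, nFrames = 12)
  op <- computeOrderParameters(rot)
  expect_true(all(op$M_ang > 0.99))   # finite differences of rigid rotation
  expect_true(all(op$Mov_pct == 100))
})

test_that("series ranges, M_abs >= M_ang, and invariances hold", {
  ic <- generateInitialConditions(10, "clustered", seed = 15)
  tr <- simulateTrajectories(ic, fixtureParams(), 80, seed = 15)
  op <- computeOrderParameters(tr)
  expect_true(all(op$P >= 0 & op$P <= 1 + 1e-12))
  expect_true(all(op$M_ang >= 0 & op$M_ang <= 1 + 1e-12))
  expect_true(all(op$M_abs >= op$M_ang - 1e-12))
  expect_true(all(op$M_abs <= 1 + 1e-12))
  expect_true(all(op$d_a >= 0))
  expect_true(all(op$Mov_pct >= 0 & op$Mov_pct <= 100))

  # permutation invariance of agent labels
  perm <- sample(nAgents(tr))
  trP <- trajectorySet(agentPositions(tr)[, perm, , drop = FALSE],
                       moving = motionStates(tr)[, perm],
                       present = presentMask(tr)[, perm], arena = arena(tr))
  expect_equal(computeOrderParameters(trP), op)

  # translation invariance (use a wide arena so the shift stays inside)
  big <- arenaConfig(radius = 10)
  shift <- agentPositions(tr)
  shift[, , 1] <- shift[, , 1] + 0.5
  trT <- trajectorySet(shift, moving = motionStates(tr),
                       present = presentMask(tr), arena = big)
  trB <- trajectorySet(agentPositions(tr), moving = motionStates(tr),
                       present = presentMask(tr), arena = big)
  expect_equal(computeOrderParameters(trT), computeOrderParameters(trB))
})

test_that("dropout frames propagate as missing, not dropped rows", {
  ic <- generateInitialConditions(3, "clustered", seed = 16)
  tr <- generatePseudoExperiment(ic, fixtureParams(), 30, dropoutRate = 0.3,
                                 meanDropoutLen = 5, seed = 16)
  op <- computeOrderParameters(tr)
  expect_equal(nrow(op), 29)
  # frames where < 2 agents are present give NA d_a but remain in the grid
  nPresent <- rowSums(presentMask(tr))[-1]
  expect_true(all(is.na(op$d_a[nPresent < 2])))
})

test_that("long format matches the wide table", {
  tr <- constantTrajectory(n = 4, nFrames = 5)
  long <- orderParametersLong(tr)
  expect_equal(nrow(long), 4 * 5)
  expect_setequal(unique(long$name), c("P", "M_ang", "M_abs", "d_a",
                                       "Mov_pct"))
  wide <- computeOrderParameters(tr)
  expect_equal(long$value[long$name == "d_a"], wide$d_a)
})
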