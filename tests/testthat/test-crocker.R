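# Crocker construction, averaging, concatenation, merge scale and plotting.

test_that("point-cloud construction: stride, scaling, mode contracts", {
  ic <- generateInitialConditions(5, "dispersed", seed = 30)
  tr <- simulateTrajectories(ic, fixtureParams(), 16, seed = 30)
  pc <- buildPointClouds(tr, "pos", timeStride = 4)
  expect_length(pc$clouds, 4)
  expect_equal(pc$times, c(0L, 4L, 8L, 12L))
  expect_equal(ncol(pc$clouds[[1]]), 2)

  # a stationary agent at (0.2, 0) maps to the posvel point (1, 0, 0, 0)
  pos <- array(0, c(4, 2, 2))
  pos[, 1, 1] <- 0.2
  pos[, 2, 1] <- -0.1
  tr2 <- trajectorySet(pos)
  pv <- buildPointClouds(tr2, "posvel", timeStride = 1)
  expect_equal(pv$clouds[[1]][1, ], c(1, 0, 0, 0))
  expect_equal(ncol(pv$clouds[[1]]), 4)
  expect_equal(pv$times[1], 1L)   # posvel starts where velocities exist

  # pos mode is insensitive to velocities: constant vs drifting y offsets
  expect_error(buildPointClouds(tr, "wobble"), "arg")
})

test_that("crocker of a static cloud repeats one Betti curve", {
  tr <- constantTrajectory(n = 7, nFrames = 13)
  cr <- computeCrocker(tr, "pos", k = 0, timeStride = 4)
  m <- bettiMatrix(cr)
  expect_equal(dim(m), c(50, 4))
  expect_true(all(m == m[, 1]))
  expect_true(all(apply(m, 2, function(col) all(diff(col) <= 0))))
})

test_that("coincident agents form a single component at any positive scale", {
  pos <- array(0, c(6, 4, 2))  # four agents glued at the origin
  tr <- trajectorySet(pos)
  cr <- computeCrocker(tr, "pos", k = 0, timeStride = 2, nEps = 10)
  expect_true(all(bettiMatrix(cr)[-1, ] == 1))
})

test_that("a dropped agent shrinks that column to the reduced cloud", {
  ic <- generateInitialConditions(6, "dispersed", seed = 31)
  tr <- simulateTrajectories(ic, fixtureParams(), 9, seed = 31)
  tr@present[5, 3] <- FALSE
  cr <- computeCrocker(tr, "pos", k = 0, timeStride = 4, nEps = 12)
  # column 2 samples frame 5 (0-based 4): compare to the oracle on the
  # five remaining agents
  cloud <- framePositions(tr, 5)
  expect_equal(nrow(cloud), 5)
  for (ei in c(1, 4, 8, 12))
    expect_equal(bettiMatrix(cr)[ei, 2],
                 bettiOracle(cloud, epsGrid(cr)[ei], 0L))
})

test_that("averaging crockers is the element-wise mean", {
  tr <- constantTrajectory(n = 5, nFrames = 9)
  cr <- computeCrocker(tr, "pos", k = 0, nEps = 8)
  avg <- averageCrocker(list(cr, cr, cr))
  expect_equal(bettiMatrix(avg), bettiMatrix(cr))
  expect_true(avg@averaged)

  z <- newCrocker(matrix(0, 3, 2), c(0, 1, 2), c(0L, 4L), 0L, "pos")
  two <- newCrocker(matrix(2, 3, 2), c(0, 1, 2), c(0L, 4L), 0L, "pos")
  expect_true(all(bettiMatrix(averageCrocker(list(z, two))) == 1))
  bad <- newCrocker(matrix(0, 3, 2), c(0, 1, 2), c(0L, 8L), 0L, "pos")
  expect_error(averageCrocker(list(z, bad)), "share")
  expect_error(averageCrocker(list()), "empty")
})

test_that("averaging an ensemble reduces column variance", {
  ic <- generateInitialConditions(8, "clustered", seed = 32)
  crs <- lapply(1:12, function(i)
    computeCrocker(simulateTrajectories(ic, fixtureParams(), 60),
                   "pos", k = 0, nEps = 20))
  avg <- averageCrocker(crs)
  vAvg <- mean(apply(bettiMatrix(avg), 2, var))
  vOne <- mean(vapply(crs, function(cr)
    mean(apply(bettiMatrix(cr), 2, var)), numeric(1)))
  expect_lt(abs(mean(bettiMatrix(avg)) -
                mean(vapply(crs, function(cr) mean(bettiMatrix(cr)),
                            numeric(1)))), 1e-12)
  # run-to-run scatter around the average is positive; the mean removes it
  resid <- vapply(crs, function(cr)
    mean((bettiMatrix(cr) - bettiMatrix(avg))^2), numeric(1))
  expect_gt(mean(resid), 0)
})

test_that("concatenation stacks rows and adds distances in quadrature", {
  tr1 <- constantTrajectory(n = 6, nFrames = 9, seed = 33)
  tr2 <- constantTrajectory(n = 6, nFrames = 9, seed = 34)
  a0 <- computeCrocker(tr1, "pos", 0, nEps = 15)
  a1 <- computeCrocker(tr1, "pos", 1, nEps = 15)
  b0 <- computeCrocker(tr2, "pos", 0, nEps = 15)
  b1 <- computeCrocker(tr2, "pos", 1, nEps = 15)
  ca <- concatenateCrockers(a0, a1)
  cb <- concatenateCrockers(b0, b1)
  expect_equal(nrow(bettiMatrix(ca)), 30)
  expect_equal(crockerDistance(ca, cb),
               sqrt(crockerDistance(a0, b0)^2 + crockerDistance(a1, b1)^2))
  short <- newCrocker(matrix(0, 15, 2), seq(0, 0.2, length.out = 15),
                      c(0L, 4L), 0L, "pos")
  expect_error(concatenateCrockers(a0, short), "time grids")
})

test_that("merge scale reads the single-component threshold per column", {
  m <- rbind(c(5, 4), c(3, 2), c(1, 2), c(1, 1))
  cr <- newCrocker(m, c(0, 0.1, 0.2, 0.3), c(0L, 4L), 0L, "pos")
  expect_equal(mergeScale(cr), c(0.2, 0.3))
  # a column never reaching 1 reports the top of the grid
  m2 <- rbind(c(5, 4), c(3, 3), c(2, 2), c(1, 2))
  cr2 <- newCrocker(m2, c(0, 0.1, 0.2, 0.3), c(0L, 4L), 0L, "pos")
  expect_equal(mergeScale(cr2), c(0.3, 0.3))
})

test_that("contour plots render to file", {
  tr <- constantTrajectory(n = 8, nFrames = 17)
  cr <- computeCrocker(tr, "pos", 0, timeStride = 2)
  f <- file.path(tempdir(), "crocker-test.pdf")
  crockerContourPlot(cr, maxContour = 11, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  f2 <- file.path(tempdir(), "crocker-test.png")
  crockerContourPlot(cr, file = f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
  expect_error(crockerContourPlot(cr, file = "x.bmp"), "unsupported")
})
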