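# Distance-response functions, wrapped-Cauchy machinery, neighbour
# distances and the boundary rule.

test_that("response functions reproduce their printed endpoint constants", {
  p <- fixtureParams()
  expect_equal(pMoveToStop(0, p), 0.5508)
  expect_equal(pMoveToStop(Inf, p), 0.1280)
  expect_equal(pStopToMove(0, p), 0.1587)
  expect_equal(pStopToMove(Inf, p), 0.3552)
  expect_equal(stepLength(0, p), 0.0003)
  expect_equal(stepLength(Inf, p), 0.0013)
  expect_equal(spreadParam(0, p), 0.1387)
  expect_equal(spreadParam(Inf, p), 0.9013)
})

test_that("control kind forces the infinite-distance limit at any d", {
  pc <- fixtureParams("control")
  for (d in c(0, 0.001, 0.05, 0.4)) {
    expect_equal(pMoveToStop(d, pc), 0.1280)
    expect_equal(pStopToMove(d, pc), 0.3552)
    expect_equal(stepLength(d, pc), 0.0013)
    expect_equal(spreadParam(d, pc), 0.9013)
  }
})

test_that("mid-scale values match independent arithmetic", {
  p <- fixtureParams()
  # each function at its own length scale, evaluated from the closed form
  expect_equal(pMoveToStop(0.0134, p), 0.1280 + (0.5508 - 0.1280) / exp(1))
  expect_equal(pStopToMove(0.0739, p),
               0.1587 * exp(-0.0739 / 0.0079) + 0.3552 / 2)
  expect_equal(stepLength(0.0074, p), 0.0013 + (0.0003 - 0.0013) / exp(1))
  expect_equal(spreadParam(0.0044, p), 0.9013 + (0.1387 - 0.9013) / exp(1))
})

test_that("response functions are monotone and bounded on [0, 0.4]", {
  p <- fixtureParams()
  d <- seq(0, 0.4, length.out = 400)
  pms <- pMoveToStop(d, p)
  expect_true(all(diff(pms) <= 0))
  expect_true(all(pms >= 0.1280 - 1e-12 & pms <= 0.5508 + 1e-12))
  ell <- stepLength(d, p)
  expect_true(all(diff(ell) >= 0))
  expect_true(all(ell >= 0.0003 - 1e-15 & ell <= 0.0013 + 1e-15))
  psm <- pStopToMove(d, p)
  expect_true(all(psm >= 0 & psm <= 1))
  rho <- spreadParam(d, p)
  expect_true(all(rho >= 0.1387 - 1e-12 & rho <= 0.9013 + 1e-12))
})

test_that("negative finite distances are rejected", {
  p <- fixtureParams()
  expect_error(pMoveToStop(-0.01, p), "must be >= 0")
  expect_error(pStopToMove(-1, p), "must be >= 0")
  expect_error(stepLength(-1e-9, p), "must be >= 0")
  expect_error(spreadParam(-0.5, p), "must be >= 0")
})

test_that("wrapped Cauchy density is correct, symmetric and normalized", {
  expect_equal(dWrappedCauchy(0.7, 0), 1 / (2 * pi))
  expect_equal(dWrappedCauchy(0, 0.5), 3 / (2 * pi))
  th <- seq(-3, 3, by = 0.37)
  expect_equal(dWrappedCauchy(th, 0.6), dWrappedCauchy(-th, 0.6))
  for (rho in c(0.2, 0.7, 0.95)) {
    expect_equal(integrate(dWrappedCauchy, -pi, pi, rho = rho,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    expect_true(all(dWrappedCauchy(th, rho) <= dWrappedCauchy(0, rho)))
  }
  expect_error(dWrappedCauchy(0, 1), "rho")
  expect_error(sampleTurningAngle(5, -0.1), "rho")
})

test_that("turning-angle sampler matches the density", {
  # oracle: mean resultant length of the density by quadrature equals rho
  for (rho in c(0.1, 0.5, 0.9)) {
    quadResultant <- integrate(function(t) cos(t) * dWrappedCauchy(t, rho),
                               -pi, pi, rel.tol = 1e-10)$value
    expect_equal(quadResultant, rho, tolerance = 1e-7)
    n <- 2e5
    th <- sampleTurningAngle(n, rho, seed = 7)
    emp <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    se <- sqrt(((1 + rho^2) / 2 - rho^2) / n)
    expect_lt(abs(emp - rho), 3 * se + 1e-4)
    expect_true(all(th > -pi & th <= pi))
  }
})

test_that("sampler limits: uniform at rho = 0, concentrated near rho = 1", {
  u <- sampleTurningAngle(5e4, 0, seed = 11)
  ks <- suppressWarnings(ks.test(u, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.001)
  tight <- sampleTurningAngle(5e4, 0.999, seed = 12)
  expect_lt(1 - sqrt(mean(cos(tight))^2 + mean(sin(tight))^2), 0.01)
  # determinism for fixed seed
  expect_identical(sampleTurningAngle(100, 0.5, seed = 3),
                   sampleTurningAngle(100, 0.5, seed = 3))
})

test_that("nearest-neighbour distances are correct and permutation-symmetric", {
  expect_equal(nearestNeighborDistances(rbind(c(0, 0), c(0.03, 0))),
               c(0.03, 0.03))
  coll <- cbind(c(0, 1, 3), 0)
  expect_equal(nearestNeighborDistances(coll), c(1, 1, 2))
  pairs <- fivePairsCloud()
  expect_equal(nearestNeighborDistances(pairs), rep(0.02, 10))
  set.seed(4)
  pts <- randomCloud(9)
  perm <- sample(9)
  expect_equal(nearestNeighborDistances(pts[perm, ]),
               nearestNeighborDistances(pts)[perm])
  expect_error(nearestNeighborDistances(rbind(c(0, 0))), "at least 2")
})

test_that("boundary reflection obeys the radial-mirror rule and containment", {
  ar <- arenaConfig(radius = 0.2)
  inside <- c(0.05, -0.1)
  expect_identical(reflectIntoArena(c(0, 0), inside, ar), inside)
  # overshoot at radius r on a ray returns at 2R - r on the same ray
  prop <- 0.22 * c(cos(1.1), sin(1.1))
  got <- reflectIntoArena(c(0.19 * cos(1.1), 0.19 * sin(1.1)), prop, ar)
  expect_equal(got, (2 * 0.2 - 0.22) * c(cos(1.1), sin(1.1)))
  expect_error(reflectIntoArena(c(0.3, 0), c(0.1, 0), ar), "outside")
  set.seed(5)
  for (i in 1:2000) {
    a <- runif(1, -pi, pi)
    prev <- runif(1, 0.18, 0.2) * c(cos(a), sin(a))
    prop <- prev + runif(1, 0, 0.05) * c(cos(runif(1, -pi, pi)),
                                         sin(runif(1, -pi, pi)))
    for (rule in c("radial", "specular")) {
      out <- reflectIntoArena(prev, prop, ar, rule = rule)
      expect_lte(sqrt(sum(out^2)), 0.2 + 1e-12)
    }
  }
})
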