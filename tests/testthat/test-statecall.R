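test_that("clustering resolves four states at the published geometry", {
  set.seed(21)
  nPer <- 400
  th <- ph <- numeric(0)
  for (s in 1:4) {
    th <- c(th, pmin(90, rnorm(nPer, polarizationAngles[s, 1], 4)))
    ph <- c(ph, rnorm(nPer, polarizationAngles[s, 2], 4))
  }
  ord <- sample(length(th))          # clustering must not depend on order
  ev <- eventsFromAngles(th[ord], ph[ord])
  cl <- clusterOrientations(ev, seed = 1)
  expect_equal(nStates(cl$model), 4)
  mu <- stateMeans(cl$model)
  for (s in 1:4) {
    expect_lt(abs(mu[s, 2] - polarizationAngles[s, 2]), 1)
    expect_lt(omegaAngle(mu[s, 1], mu[s, 2], polarizationAngles[s, 1],
                         polarizationAngles[s, 2]), 2)
  }
  ## order invariance of the model itself
  cl2 <- clusterOrientations(eventsFromAngles(th, ph), seed = 1)
  expect_equal(nStates(cl2$model), 4)
  expect_equal(stateMeans(cl2$model), stateMeans(cl$model), tolerance = 0.2)
})

test_that("unresolvable clusters merge and a single orientation gives k = 1", {
  set.seed(22)
  ## two clusters one sigma apart cannot be resolved at 2.5 sigma
  th <- c(rnorm(400, 80, 4), rnorm(400, 80, 4))
  ph <- c(rnorm(400, 10, 4), rnorm(400, 14, 4))
  cl <- clusterOrientations(eventsFromAngles(th, ph), seed = 1)
  expect_equal(nStates(cl$model), 1)
  ## a single tight orientation
  one <- clusterOrientations(
    eventsFromAngles(rnorm(200, 70, 1), rnorm(200, 30, 1)), seed = 1)
  expect_equal(nStates(one$model), 1)
})

test_that("consecutive same-state events merge as changepoint false positives", {
  ev <- eventsFromAngles(c(80, 80, 60), c(0, 0, 30))
  ev$start <- c(0L, 10L, 30L); ev$end <- c(10L, 30L, 45L)
  ev$nframes <- c(10L, 20L, 15L)
  m <- mergeSameState(ev, c(1L, 1L, 2L))
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(0L, 30L))
  expect_equal(m$end, c(30L, 45L))
  expect_equal(m$nframes, c(30L, 15L))
  ## re-averaged intensity is the frame-weighted mean
  expect_equal(m$I0[1], (10 * ev$I0[1] + 20 * ev$I0[2]) / 30)
  ## alternating labels stay untouched
  m2 <- mergeSameState(ev, c(1L, 2L, 1L), transientFrames = 0)
  expect_equal(nrow(m2), 3)
  ## 23 events with exactly one consecutive same-state pair give 22
  set.seed(3)
  lab <- c(1L, 2L, 3L, 4L)[1 + (0:22) %% 4]
  lab[12] <- lab[11]
  ev23 <- eventsFromAngles(polarizationAngles[lab, 1],
                           polarizationAngles[lab, 2])
  ev23$start <- 50L * (0:22); ev23$end <- 50L * (1:23)
  ev23$nframes <- 50L
  expect_equal(nrow(mergeSameState(ev23, lab)), 22)
})

test_that("occupancies are time-weighted and transitions exit-conditional", {
  ## alternating A/B dwells of equal duration
  lab <- rep(c(1L, 2L), 10)
  ev <- eventsFromAngles(c(80, 60)[lab], c(0, 40)[lab])
  ev$nframes <- 30L
  ev$state <- lab
  st <- stateStatistics(ev, k = 2)
  expect_equal(st$occupancy, c(0.5, 0.5))
  expect_equal(st$p[1, 2], 1)
  expect_equal(st$p[2, 1], 1)
  expect_equal(sum(st$n), 19)
  ## row normalization on a longer random label sequence
  set.seed(9)
  P <- matrix(c(0, 0.7, 0.3,
                0.2, 0, 0.8,
                0.5, 0.5, 0), 3, byrow = TRUE)
  lab <- integer(4000); lab[1] <- 1L
  for (i in 2:4000) lab[i] <- sample.int(3, 1, prob = P[lab[i - 1], ])
  ev <- eventsFromAngles(c(80, 60, 40)[lab], c(0, 30, 60)[lab])
  ev$state <- lab
  st <- stateStatistics(ev, k = 3)
  expect_equal(rowSums(st$p), rep(1, 3))
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    se <- sqrt(P[i, j] * (1 - P[i, j]) / sum(st$n[i, ]))
    expect_lt(abs(st$p[i, j] - P[i, j]), 3.5 * se + 1e-9)
  }
})

test_that("structural matching enumerates 24 pairings and finds the best", {
  self <- matchStructuralStates(polarizationAngles, polarizationAngles)
  expect_equal(length(self$lse), 24)
  expect_equal(nrow(self$permutations), 24)
  expect_equal(self$best, 1:4)
  expect_equal(min(self$lse), 0)
  ## published crystallographic vs polarization orientations pair up
  ## in register: C1-Ex, C2-Eo, C3-Io, C4-Ix
  m <- matchStructuralStates(polarizationAngles, crystalAngles,
                             structNames = c("Ex", "Eo", "Io", "Ix"))
  expect_equal(m$best, 1:4)
  expect_equal(unname(m$assignment), c("Ex", "Eo", "Io", "Ix"))
})
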