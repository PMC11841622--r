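test_that("segment LLR is zero for homogeneous counts and additive over channels", {
  counts <- matrix(rep(c(10L, 20L, 5L, 8L), each = 40), 40, 4)
  expect_equal(segmentLLR(counts, 20), 0)
  expect_error(segmentLLR(counts, 40), "out of range")
  ## only one informative channel: total equals that channel's LLR
  set.seed(1)
  one <- cbind(c(rpois(30, 5), rpois(30, 25)), 0L, 0L, 0L)
  m <- sum(one[1:30, 1]); N <- sum(one[, 1])
  manual <- m * log(m / 30) + (N - m) * log((N - m) / 30) - N * log(N / 60)
  expect_equal(segmentLLR(one, 30), manual)
})

test_that("the LLR profile peaks at a true rate change", {
  set.seed(7)
  counts <- rbind(matrix(rpois(300 * 4, 20), 300, 4),
                  matrix(rpois(300 * 4, 40), 300, 4))
  ## independent grid oracle: direct evaluation of the LLR formula
  cs <- apply(counts, 2, cumsum)
  grid <- vapply(1:599, function(s) {
    tot <- 0
    for (ch in 1:4) {
      m <- cs[s, ch]; N <- cs[600, ch]
      tot <- tot + m * log(m / s) + (N - m) * log((N - m) / (600 - s)) -
        N * log(N / 600)
    }
    tot
  }, numeric(1))
  expect_gt(max(grid), 0)
  pkg <- vapply(c(150, 300, 450), function(s) segmentLLR(counts, s),
                numeric(1))
  expect_equal(pkg, grid[c(150, 300, 450)])
  expect_lt(abs(which.max(grid) - 300), 6)
})

test_that("Monte-Carlo thresholds behave like multiple-testing quantiles", {
  t95 <- calibrateThreshold(200, 100, 0.95, nNull = 300, seed = 2)
  t99 <- calibrateThreshold(200, 100, 0.99, nNull = 300, seed = 2)
  expect_gt(t99, t95)
  tLong <- calibrateThreshold(3200, 100, 0.95, nNull = 300, seed = 2)
  expect_gt(tLong, t95)
  expect_error(calibrateThreshold(200, 100, 0.95, nNull = 50), "100")
  expect_error(calibrateThreshold(200, 100, 0.4), "confidence")
  ## deterministic given the seed
  expect_equal(t95, calibrateThreshold(200, 100, 0.95, nNull = 300, seed = 2))
})

test_that("detection finds clean steps and respects its false-positive budget", {
  r1 <- channelRates(90, 0, 400, 5)
  r2 <- channelRates(90, 40, 400, 5)
  tr <- stepTrace(list(r1, r2, r1), c(300, 250, 250), seed = 3)
  cp <- detectChangepoints(tr, nNull = 300, seed = 1)
  expect_equal(length(cp$changepoints), 2)
  expect_lt(abs(cp$changepoints[1] - 300), 3)
  expect_lt(abs(cp$changepoints[2] - 550), 3)
  expect_true(all(cp$llrRatio >= 1))
  ## null traces: detection rate near the nominal 5%
  hits <- 0
  for (i in 1:60) {
    trn <- stepTrace(list(rep(100, 4)), 500, seed = 100 + i)
    if (length(detectChangepoints(trn, nNull = 300,
                                  seed = 1)$changepoints) > 0)
      hits <- hits + 1
  }
  expect_lt(hits / 60, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 60))
})

test_that("event construction averages and corrects segment intensities", {
  cal <- Calibration(delta = 0, gains = c(1.2, 1, 0.9, 1.1),
                     backgrounds = c(4, 4, 4, 4))
  tr <- stepTrace(list(c(100, 60, 20, 60), c(30, 60, 110, 60)),
                  c(120, 80), seed = 5, calibration = cal)
  ## no changepoints: a single spanning event
  ev0 <- buildEvents(tr, NULL)
  expect_equal(nrow(ev0), 1)
  expect_equal(c(ev0$start, ev0$end), c(0, 200))
  cps <- structure(list(changepoints = 120L, llrRatio = 2,
                        confidence = 0.95), class = "ChangePointResult")
  ev <- buildEvents(tr, cps)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start, c(0, 120))
  expect_equal(ev$end, c(120, 200))
  counts <- traceCounts(tr)
  expect_equal(ev$I0[1], (mean(counts[1:120, 1]) - 4) / 1.2)
  expect_equal(ev$I90[2], (mean(counts[121:200, 3]) - 4) / 0.9)
})

test_that("particle QC enforces event count, SNR and single-step bleaching", {
  sig <- channelRates(90, 0, 400, 5)
  alt <- channelRates(90, 40, 400, 5)
  bg <- rep(5, 4)
  cal <- Calibration(delta = 0, backgrounds = bg)
  ## compliant particle: 16 pre-bleach events then a single bleach step
  lens <- rep(60, 16)
  rates <- rep(list(sig, alt), 8)
  good <- stepTrace(c(rates, list(bg)), c(lens, 40), seed = 11,
                    calibration = cal)
  ## too few events: 8 dwells before the bleach
  few <- stepTrace(c(rep(list(sig, alt), 4), list(bg)),
                   c(rep(60, 8), 40), seed = 12, calibration = cal)
  ## two bleach steps: full signal, sustained half level, background
  half <- (sig + bg) / 2
  twostep <- stepTrace(c(rates, list(half), list(bg)),
                       c(lens, 60, 40), seed = 13, calibration = cal)
  ## hopeless SNR: signal buried in noise
  dim <- stepTrace(list(channelRates(90, 0, 4, 5), bg), c(400, 40),
                   seed = 14, calibration = cal)
  res <- filterParticles(list(good, few, twostep, dim), nNull = 300, seed = 1)
  expect_equal(res$keptIdx, 1L)
  ## 16 true dwells; the occasional changepoint false positive (merged later
  ## by the state-assignment step) may add one
  expect_gte(nrow(res$kept[[1]]$events), 16)
  expect_lte(nrow(res$kept[[1]]$events), 18)
  reasons <- setNames(res$rejected$reason, res$rejected$index)
  expect_equal(reasons[["2"]], "too few events")
  expect_equal(reasons[["3"]], "multiple bleach steps")
  expect_equal(reasons[["4"]], "low SNR")
})
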