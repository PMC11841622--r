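test_that("the camera-quantized pmf is a proper distribution with the right limits", {
  for (x in c(0.05, 0.5, 3)) {
    lam <- x / 0.01
    expect_equal(sum(dwellPmf(lam, 0.01, 1:5000)), 1, tolerance = 1e-12)
  }
  ## continuum limit: slow rates give a near-geometric law
  lam <- 0.2; dt <- 0.01          # lambda dt = 0.002
  k <- 1:100
  geom <- dgeom(k - 1, lam * dt) / (1 - 0)  # geometric with mean 1/(lam dt)
  expect_equal(dwellPmf(lam, dt, k), geom, tolerance = 2e-3)
  ## kmin truncation renormalizes
  expect_equal(sum(dwellPmf(50, 0.01, 2:4000, kmin = 2)), 1,
               tolerance = 1e-12)
  expect_error(dwellPmf(50, 0.01, 1, kmin = 2), "kmin")
})

test_that("the pmf matches a Monte-Carlo camera-discretization oracle", {
  n <- 3e5
  lam <- 35; dt <- 0.01
  k <- quantizedDwells(n, lam, dt, seed = 31)
  kmax <- 25
  emp <- tabulate(k, kmax) / n
  theo <- dwellPmf(lam, dt, 1:kmax)
  se <- sqrt(theo * (1 - theo) / n)
  expect_true(all(abs(emp - theo) < 3.6 * se))
})

test_that("maximum-likelihood dwell fits recover known parameters", {
  dt <- 0.01
  k1 <- quantizedDwells(1e4, 10, dt, seed = 32)
  f1 <- fitDwell(k1, dt, ncomp = 1)
  expect_lt(abs(f1$lambda1 - 10) / 10, 0.05)
  km <- quantizedMixDwells(1e4, 50, 2, 0.6, dt, seed = 33)
  f2 <- fitDwell(km, dt, ncomp = 2)
  expect_lt(abs(f2$lambda1 - 50) / 50, 0.10)
  expect_lt(abs(f2$lambda2 - 2) / 2, 0.10)
  expect_lt(abs(f2$f - 0.6), 0.06)
  expect_error(fitDwell(km[1:30], dt, ncomp = 2), "50")
})

test_that("the F test separates one from two dwell components", {
  dt <- 0.01
  km <- quantizedMixDwells(3000, 40, 1.5, 0.55, dt, seed = 34)
  p <- ftestComponents(fitDwell(km, dt, 1), fitDwell(km, dt, 2))
  expect_lt(as.numeric(p), 1e-15)
  ## identical fits: no improvement, p = 1
  k1 <- quantizedDwells(2000, 12, dt, seed = 35)
  fit1 <- fitDwell(k1, dt, 1)
  expect_equal(as.numeric(ftestComponents(fit1, fit1)), 1)
})

test_that("serial-scheme inversion agrees with an eigenvalue oracle", {
  ## forward solve via eigen-decomposition of the 2x2 dwell generator
  forward <- function(kOut, kAb, kBa) {
    Q <- matrix(c(-(kOut + kAb), kAb, kBa, -kBa), 2, byrow = TRUE)
    lam <- sort(-eigen(Q)$values, decreasing = TRUE)
    f <- (kOut - lam[2]) / (lam[1] - lam[2])
    c(lam, f)
  }
  fw <- forward(10, 2, 1)
  expect_equal(fw[1], 12.1789, tolerance = 1e-4)
  expect_equal(fw[2], 0.8211, tolerance = 1e-4)
  expect_equal(fw[3], 0.8082, tolerance = 1e-4)
  inv <- invertSerialScheme(fw[1], fw[2], fw[3], c(0.5, 0.25, 0.25))
  expect_equal(inv$kOut, 10, tolerance = 1e-9)
  expect_equal(inv$kAb, 2, tolerance = 1e-9)
  expect_equal(inv$kBa, 1, tolerance = 1e-9)
  expect_equal(unname(inv$kInter), c(5, 2.5, 2.5), tolerance = 1e-9)
  ## property: round trip over random positive triples
  set.seed(36)
  for (i in 1:500) {
    k3 <- exp(runif(3, log(0.01), log(100)))
    fw <- forward(k3[1], k3[2], k3[3])
    inv <- invertSerialScheme(fw[1], fw[2], fw[3], 1)
    ## the numeric eigen-decomposition itself limits precision here; the
    ## tight 1e-8 identity is asserted against the closed-form oracle in
    ## the acceptance suite
    expect_lt(max(abs(c(inv$kOut, inv$kAb, inv$kBa) - k3) / k3), 1e-6)
    ## eigen identities asserted post-inversion
    expect_equal(fw[1] + fw[2], inv$kOut + inv$kAb + inv$kBa,
                 tolerance = 1e-9)
    expect_equal(fw[1] * fw[2], inv$kOut * inv$kBa, tolerance = 1e-9)
  }
  ## f = 1 boundary collapses to a single substate
  expect_equal(invertSerialScheme(10, 1, 1, 1)$flag, "single-state")
  expect_error(invertSerialScheme(10, 1, 1.4, 1), "f must")
  expect_error(invertSerialScheme(1, 10, 0.5, 1), "lambda1")
})

test_that("apparent rates interpolate the binding isotherm", {
  tt <- makeGroundTruth("adic-like", 5)
  r <- truthRates(tt)
  expect_equal(apparentRates(r, "arg", 0), r@apo)
  ## at K1/2 the apparent rate is the midpoint of apo and bound
  kh <- r@khalf$arg
  mid <- apparentRates(r, "arg", kh[["k_1_2"]])
  expect_equal(mid[["k_1_2"]],
               (r@apo[["k_1_2"]] + r@arg[["k_1_2"]]) / 2)
  ## saturating concentration approaches the bound branch
  sat <- apparentRates(r, "agm", 1)
  expect_equal(unname(sat), unname(r@agm), tolerance = 1e-3)
})

test_that("isotherm fits recover the 60 rate constants from clean curves", {
  tt <- makeGroundTruth("adic-like", 2)
  r <- truthRates(tt)
  concs <- c(0, 2e-5, 5e-5, 1.5e-4, 5e-4, 1.5e-3)
  tab <- NULL
  for (lig in c("arg", "agm")) for (cc in concs) {
    appk <- apparentRates(r, lig, cc)
    tab <- rbind(tab, data.frame(transition = names(appk),
                                 ligand = if (cc == 0) "apo" else lig,
                                 conc = cc, value = as.numeric(appk)))
  }
  fit <- fitRateConstants(tab, seed = 1)
  for (b in c("apo", "arg", "agm")) {
    err <- abs(rateConstants(fit$rates, b) - rateConstants(r, b)) /
      rateConstants(r, b)
    expect_lt(max(err), 0.02)
  }
})

test_that("stationary substate probabilities solve the eight-state scheme", {
  ## two-state detailed balance: k12 = 1, k21 = 3 gives P = (0.75, 0.25)
  appk <- setNames(rep(1e-9, 20), transitionNames())
  appk["k_1_2"] <- 1; appk["k_2_1"] <- 3
  ## connect remaining states weakly so the chain is irreducible
  P <- substateProbabilities(appk)
  expect_equal(P[1] / (P[1] + P[2]), 0.75, tolerance = 1e-4)
  expect_equal(P[2] / (P[1] + P[2]), 0.25, tolerance = 1e-4)
  ## any generator: a probability vector
  tt <- makeGroundTruth("random", 7)
  P2 <- substateProbabilities(rateConstants(tt, "apo"))
  expect_equal(sum(P2), 1)
  expect_true(all(P2 >= 0))
  ## long simulated occupancy matches the stationary solution
  path <- simulateStatePath(tt, "apo", 0, nEvents = 4000, seed = 8)
  occ <- tapply(path$duration, factor(path$state, levels = 1:8), sum)
  occ[is.na(occ)] <- 0
  occ <- occ / sum(occ)
  expect_lt(max(abs(occ - P2)), 0.03)
})

test_that("equilibrium fits recover dissociation constants from clean curves", {
  tt <- makeGroundTruth("adic-like", 3)
  concs <- c(0, 2e-5, 5e-5, 1.5e-4, 5e-4, 1.5e-3)
  pd <- NULL
  for (lig in c("arg", "agm")) for (cc in concs) {
    P <- substateProbabilities(apparentRates(truthRates(tt), lig, cc))
    pd <- rbind(pd, data.frame(state = 1:8, ligand = lig, conc = cc, P = P))
  }
  eq <- fitEquilibriumConstants(pd, seed = 1)
  expect_equal(eq$K[1], 1)
  expect_equal(unname(eq$LK[1, ]), c(1, 1))
  kdT <- truthKd(tt)
  expect_lt(abs(eq$KD[6, "arg"] - kdT[["arg_ext"]]) / kdT[["arg_ext"]], 0.15)
  expect_lt(abs(eq$KD[7, "arg"] - kdT[["arg_int"]]) / kdT[["arg_int"]], 0.15)
  expect_lt(abs(eq$KD[6, "agm"] - kdT[["agm_ext"]]) / kdT[["agm_ext"]], 0.15)
  ## at zero concentration the probabilities are the apo Boltzmann ratios
  expect_equal(unname(eq$predict("arg", 0)), eq$K / sum(eq$K))
})

test_that("ligand-coupled global dwell fits recover the half-saturation", {
  dt <- 0.01
  K <- 8e-5
  pars <- function(conc) {
    w <- conc / (conc + K)
    list(l1 = 1 / (0.8 + (2.0 - 0.8) * w),
         l2 = 1 / (6 + (9 - 6) * w),
         f = 0.93 + (0.85 - 0.93) * w)
  }
  sets <- lapply(c(0, 3e-5, 1e-4, 4e-4, 1.5e-3), function(cc) {
    p <- pars(cc)
    list(conc = cc,
         dwells = quantizedMixDwells(4000, p$l1, p$l2, p$f, dt,
                                     seed = round(1e5 * cc) + 7))
  })
  gf <- suppressWarnings(globalFitDwell(sets, dt, nStarts = 10, seed = 2))
  ## the fast component's isotherm has the largest amplitude and pins its
  ## half-saturation best (each parameter carries its own K1/2)
  expect_lt(abs(log(gf$khalf[["tau1"]] / K)), log(1.5))
  expect_lt(abs(gf$tau1_0 - 0.8) / 0.8, 0.05)
  expect_lt(abs(gf$tau1_inf - 2.0) / 2.0, 0.1)
  ## the fitted isotherms track the true parameter curves everywhere
  for (cc in c(0, 5e-5, 2e-4, 1e-3)) {
    p <- pars(cc); pr <- gf$predict(cc)
    expect_lt(abs(pr$tau1 - 1 / p$l1) * p$l1, 0.10)
    expect_lt(abs(pr$tau2 - 1 / p$l2) * p$l2, 0.15)
    expect_lt(abs(pr$f - p$f), 0.03)
  }
  at0 <- gf$predict(0)
  expect_equal(at0$tau1, gf$tau1_0)
})

test_that("rate-level serial global fits recover the underlying rates", {
  dt <- 0.01
  K <- 7e-5
  iso <- function(k0, kinf, cc) (k0 + kinf * cc / K) / (1 + cc / K)
  draw <- function(cc, n, seed) {
    kOut <- iso(1.1, 1.9, cc); kAb <- iso(0.05, 0.09, cc)
    kBa <- iso(0.13, 0.10, cc)
    eg <- serialEigenrates(kOut, kAb, kBa)
    quantizedMixDwells(n, eg$lambda1, eg$lambda2, eg$f, dt, seed)
  }
  concs <- c(0, 2e-5, 5e-5, 1.5e-4, 5e-4, 1.5e-3)
  sets <- lapply(seq_along(concs), function(i)
    list(conc = concs[i], dwells = draw(concs[i], 3000, 900 + i)))
  gf <- suppressWarnings(globalFitSerial(sets, dt, seed = 3))
  expect_lt(abs(gf$kOut0 - 1.1) / 1.1, 0.05)
  expect_lt(abs(gf$kAb0 - 0.05) / 0.05, 0.25)
  expect_lt(abs(gf$kBa0 - 0.13) / 0.13, 0.20)
  expect_lt(abs(gf$kOutInf - 1.9) / 1.9, 0.05)
  pr <- gf$predict(7e-5)
  expect_lt(abs(pr$kOut - iso(1.1, 1.9, 7e-5)) / iso(1.1, 1.9, 7e-5), 0.05)
  expect_true(pr$lambda1 > pr$lambda2)
})
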