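truthA <- makeGroundTruth("adic-like", 1)

test_that("the 24-state generator has the required structure", {
  m <- model24FromTruth(truthA)
  ext <- c(arg = 1e-4, agm = 0); int <- c(arg = 0, agm = 1e-3)
  Q <- buildGenerator(m, ext, int)
  expect_equal(dim(Q), c(24, 24))
  expect_equal(rowSums(Q), rep(0, 24), tolerance = 1e-12)
  expect_true(all(Q - diag(diag(Q)) >= 0))
  ## binding edges only at the open substates facing each compartment
  expect_equal(Q[6, 8 + 6], 1e7 * 1e-4)    # external arg binds at S6
  expect_equal(Q[7, 16 + 7], 1e7 * 1e-3)   # internal agm binds at S7
  expect_equal(Q[6, 16 + 6], 0)            # no external agm present
  expect_equal(Q[8 + 6, 6], 1e7 * truthKd(truthA)[["arg_ext"]])
  ## zero ligand everywhere: bound branches unreachable
  Q0 <- buildGenerator(m, c(arg = 0, agm = 0), c(arg = 0, agm = 0))
  expect_equal(sum(Q0[1:8, 9:24]), 0)
  p0 <- stationaryState(m, c(arg = 0, agm = 0), c(arg = 0, agm = 0))
  expect_equal(sum(p0[9:24]), 0, tolerance = 1e-9)
  ## saturating symmetric ligand: the apo states empty out
  sat <- c(arg = 0.2, agm = 0)
  psat <- stationaryState(m, sat, sat)
  expect_lt(sum(psat[1:8]), 0.02)
  expect_error(buildGenerator(m, c(arg = -1, agm = 0), int), "negative")
})

test_that("exchange thermodynamics reproduce the closed forms", {
  expect_equal(fmaxExchanger(1, 1), 0.5)
  expect_equal(round(fmaxExchanger(50, 100), 2), 0.67)
  expect_equal(fmaxExchanger(50, 1e9), 1, tolerance = 1e-6)
  expect_equal(rvFromFmax(0.5), 1)
  expect_equal(rvFromFmax(1 / 111), 110)
  ## mixing equilibrium: equal ratio everywhere, consistent with Fmax
  mx <- mixingEquilibrium(1000, 1000)
  expect_equal(mx$nRi, 500)
  expect_equal(mx$nNRi / mx$nRi, 1)
  mx2 <- mixingEquilibrium(500, 2000)
  expect_equal(mx2$nNRi / mx2$nRi, mx2$nNRe / mx2$nRe)
  expect_equal(mx2$nNRi / mx2$nRi, 2000 / 500)
  expect_equal(mx2$nRi + mx2$nRe, 500)
})

test_that("the exchanger variant removes only the apo inter-conformational path", {
  m <- model24FromTruth(truthA)
  ex <- makeExchanger(m)
  apo <- ex@apo
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(apo[[paste0("k_", i, "_", j)]], 0)
    expect_equal(apo[[paste0("k_", j, "_", i)]], 0)
  }
  for (i in 1:4) {
    expect_gt(apo[[paste0("k_", i, "_", i + 4)]], 0)
    expect_gt(apo[[paste0("k_", i + 4, "_", i)]], 0)
  }
  ## bound branches untouched
  expect_equal(ex@species[[1]]$rates, m@species[[1]]$rates)
})

test_that("deterministic transport conserves mass and reaches the right equilibria", {
  m1 <- model24FromTruth(truthA, species = "arg", names = "R")
  ## uniporter, tracer outside only, inert lumen: volume partition 1/(1+rv)
  comp <- CompartmentSystem(rv = 20, vi = 5e-17, nTransporters = 400,
                            ext = c(R = 5e-5), int = c(R = 0))
  out <- integrateTransport(m1, comp, seq(0, 30000, by = 500))
  expect_lt(attr(out, "conservation"), 1e-8)
  expect_equal(max(abs(out$probSum - 1)), 0, tolerance = 1e-8)
  fEnd <- out$frac_R[nrow(out)]
  ## the ~0.5% shortfall is tracer occupying the transporters themselves
  expect_equal(fEnd, 1 / 21, tolerance = 0.01)
  ## the symmetric-equilibrium fraction returns the configured volume ratio
  expect_equal(rvFromFmax(fEnd), 20, tolerance = 0.5)

  ## exchanger with nonradioactive lumen load reaches the mixing equilibrium
  m2 <- model24FromTruth(truthA, species = c("arg", "arg"),
                         names = c("R", "NR"))
  ex <- makeExchanger(m2)
  rv <- 10
  compX <- CompartmentSystem(rv = rv, vi = 5e-17, nTransporters = 600,
                             ext = c(R = 5e-5, NR = 0),
                             int = c(R = 0, NR = 2e-3))
  outX <- integrateTransport(ex, compX, seq(0, 60000, by = 1000))
  rc <- 2e-3 / 5e-5
  fTheory <- fmaxExchanger(rv, rc)
  expect_equal(outX$frac_R[nrow(outX)], fTheory, tolerance = 0.03 * fTheory)
  ## and matches the entropy-maximization count bookkeeping
  nRe0 <- 5e-5 * 6.02214076e23 * rv * 5e-17
  nNRi0 <- 2e-3 * 6.02214076e23 * 5e-17
  expect_equal(outX$frac_R[nrow(outX)], mixingEquilibrium(nRe0, nNRi0)$fmax,
               tolerance = 0.03 * fTheory)
})

test_that("transporter copy number sets the time scale but not the equilibrium", {
  m1 <- model24FromTruth(truthA, species = "arg", names = "R")
  tg <- seq(0, 40000, by = 200)
  f1 <- integrateTransport(m1, CompartmentSystem(rv = 20, vi = 5e-17,
                                                 nTransporters = 200,
                                                 ext = c(R = 5e-5),
                                                 int = c(R = 0)), tg)$frac_R
  f2 <- integrateTransport(m1, CompartmentSystem(rv = 20, vi = 5e-17,
                                                 nTransporters = 400,
                                                 ext = c(R = 5e-5),
                                                 int = c(R = 0)), tg)$frac_R
  ## equilibria agree up to the transporter-bound tracer fraction
  expect_equal(f1[length(f1)], f2[length(f2)], tolerance = 7.5e-3)
  half <- f1[length(f1)] / 2
  t1 <- tg[which(f1 >= half)[1]]
  t2 <- tg[which(f2 >= half)[1]]
  expect_equal(t1 / t2, 2, tolerance = 0.25)
})

test_that("net serial-path flux vanishes at equilibrium", {
  m <- model24FromTruth(truthA, species = "arg", names = "R")
  conc <- c(R = 1e-4)
  p <- stationaryState(m, conc, conc)
  fl <- fluxRate(m, p, conc, conc, "all")
  expect_equal(length(fl), 5)
  expect_lt(max(abs(fl)), 1e-10)
  expect_error(fluxRate(m, p, conc, conc, "sideways"), "unknown")
})

test_that("Michaelis-Menten fits recover exact curves", {
  s <- c(1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 3e-3)
  v <- 4.2 * s / (8e-5 + s)
  fit <- fitMichaelisMenten(s, v)
  expect_equal(fit$kmax, 4.2, tolerance = 1e-6)
  expect_equal(fit$km, 8e-5, tolerance = 1e-6)
  expect_equal(fit$offset, 0)
  ## half-saturation point
  expect_equal(4.2 * 8e-5 / (8e-5 + 8e-5), 4.2 / 2)
  voff <- 0.5 + 4.2 * s / (8e-5 + s)
  fit2 <- fitMichaelisMenten(s, voff, allowOffset = TRUE)
  expect_equal(fit2$offset, 0.5, tolerance = 1e-5)
  expect_equal(fit2$kmax, 4.2, tolerance = 1e-4)
})

test_that("stochastic and deterministic transport agree on short uptake", {
  m <- model24FromTruth(truthA, species = "arg", names = "R")
  comp <- CompartmentSystem(rv = 20, vi = 2e-18, nTransporters = 4,
                            ext = c(R = 1e-4), int = c(R = 0))
  tg <- seq(0, 400, by = 50)
  ode <- integrateTransport(m, comp, tg)
  reps <- 12
  fr <- matrix(NA_real_, reps, length(tg))
  for (r in seq_len(reps)) {
    g <- gillespieTransport(m, comp, max(tg), seed = 400 + r,
                            recordPath = FALSE)
    up <- g$uptake$R
    fr[r, ] <- approx(up$time, up$frac, xout = tg, method = "constant",
                      rule = 2)$y
  }
  mu <- colMeans(fr); sdev <- apply(fr, 2, sd)
  ## ODE curve inside the Monte-Carlo one-sigma envelope of the mean
  inside <- abs(mu[-1] - ode$frac_R[-1]) <= pmax(sdev[-1], 1e-4)
  expect_true(mean(inside) >= 0.8)
})
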