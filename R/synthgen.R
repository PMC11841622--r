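## Synthetic-data generator: ground-truth conformational-kinetic models,
## stochastic state paths under a ligand condition, rendering of four-channel
## polarized photon-count traces (Poisson shot noise, wobble depolarization,
## single-step photobleaching), and synthetic tracer flux datasets.

## Build a thermodynamically consistent rate branch from per-state
## equilibrium ratios (relative to S1) and symmetric edge scales:
## k_ij = g_e sqrt(K_j / K_i) satisfies detailed balance k_ij/k_ji = K_j/K_i.
## Serial forward rates are set directly (they are the slow, rate-limiting
## transitions); their reverses follow from the equilibrium ratios.
.buildBranch <- function(K, gInter, serialFwd) {
  out <- stats::setNames(numeric(20), transitionNames())
  for (r in seq_len(nrow(.confPairs))) {
    i <- .confPairs[r, 1]; j <- .confPairs[r, 2]
    out[paste0("k_", i, "_", j)] <- gInter[r] * sqrt(K[j] / K[i])
    out[paste0("k_", j, "_", i)] <- gInter[r] * sqrt(K[i] / K[j])
  }
  for (i in 1:4) {
    out[paste0("k_", i, "_", i + 4)] <- serialFwd[i]
    out[paste0("k_", i + 4, "_", i)] <- serialFwd[i] * K[i] / K[i + 4]
  }
  out
}

#' Generate a ground-truth conformational-kinetic model
#'
#' Presets:
#' \describe{
#'   \item{\code{"adic-like"}}{A 24-state model with the qualitative
#'   structure of an arginine/agmatine transporter: four conformations with
#'   orientations close to the published polarization means, two energetic
#'   substates per conformation with the four serial forward rates markedly
#'   (at least 5x) slower than the other rate constants, detailed-balance
#'   consistent apo and bound branches, per-state dissociation constants in
#'   the 50-200 uM range, and a wobble half-cone angle of 27 degrees.}
#'   \item{\code{"random"}}{Randomized rates, equilibrium ratios, KDs and
#'   orientations satisfying the same structural invariants.}
#' }
#' Each branch satisfies detailed balance with respect to per-state
#' equilibrium ratios, and the bound-branch ratios follow the thermodynamic
#' cycle \eqn{{}^{L}K_{i,1} = K_{i,1} K_{D1} / K_{Di}}; consequently the
#' apparent rates follow the binding isotherm exactly with
#' \eqn{K_{1/2}} equal to the source-state \eqn{K_D}, and the substate
#' probabilities follow the equilibrium isotherm exactly.  This makes
#' end-to-end parameter recovery well-posed.
#'
#' @param preset \code{"adic-like"} or \code{"random"}.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a \linkS4class{GroundTruth}.
#' @export
makeGroundTruth <- function(preset = "adic-like", seed = 1L) {
  if (!preset %in% c("adic-like", "random"))
    stop(sprintf("unknown preset '%s'", preset))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  if (preset == "adic-like") {
    Kconf <- c(1, 0.85, 0.65, 0.9)
    K <- c(Kconf, 0.42 * Kconf)            # cul-de-sacs less occupied
    gInter <- c(0.42, 0.31, 0.36, 0.49, 0.33, 0.45)  # edges (12)(13)(14)(23)(24)(34)
    serialFwd <- c(0.055, 0.049, 0.045, 0.060)       # the four slow transitions
    kdArg <- c(1.2e-4, 6e-5, 9e-5, 1.1e-4, 1.4e-4, 5e-5, 1.4e-4, 1.0e-4)
    kdAgm <- c(1.5e-4, 9e-5, 1.2e-4, 1.3e-4, 1.6e-4, 8e-5, 2.0e-4, 1.2e-4)
    gArg <- gInter * c(1.3, 0.7, 1.1, 1.5, 0.8, 1.2)
    gAgm <- gInter * c(0.8, 1.4, 0.9, 1.1, 1.3, 0.7)
    serialArg <- serialFwd * c(1.2, 0.7, 1.1, 0.8)
    serialAgm <- serialFwd * c(0.7, 1.2, 0.9, 1.3)
    orientations <- cbind(theta = c(90, 88.7, 77.4, 90),
                          phi = c(0, 17.9, 27.2, 40.5))
    delta <- 27.03
  } else {
    Kconf <- exp(stats::rnorm(4, 0, 0.4)); Kconf <- Kconf / Kconf[1]
    K <- c(Kconf, stats::runif(4, 0.25, 0.55) * Kconf)
    gInter <- exp(stats::rnorm(6, log(0.37), 0.3))
    serialFwd <- exp(stats::rnorm(4, log(0.05), 0.2))
    kdArg <- exp(stats::rnorm(8, log(1e-4), 0.35))
    kdAgm <- exp(stats::rnorm(8, log(1.3e-4), 0.35))
    gArg <- gInter * exp(stats::rnorm(6, 0, 0.25))
    gAgm <- gInter * exp(stats::rnorm(6, 0, 0.25))
    serialArg <- serialFwd * exp(stats::rnorm(4, 0, 0.2))
    serialAgm <- serialFwd * exp(stats::rnorm(4, 0, 0.2))
    phi <- sort(stats::runif(4, -60, 80))
    orientations <- cbind(theta = stats::runif(4, 55, 90), phi = phi)
    delta <- stats::runif(1, 0, 40)
  }

  apo <- .buildBranch(K, gInter, serialFwd)
  LKarg <- K * kdArg[1] / kdArg
  LKagm <- K * kdAgm[1] / kdAgm
  arg <- .buildBranch(LKarg, gArg, serialArg)
  agm <- .buildBranch(LKagm, gAgm, serialAgm)
  ## exact Eq-3 coupling: K1/2 of every transition is the source-state KD
  tp <- .transitionPairs()
  khalf <- list(arg = stats::setNames(kdArg[tp$from], tp$name),
                agm = stats::setNames(kdAgm[tp$from], tp$name))
  rates <- RateSet(apo, arg, agm, khalf)
  kd <- c(arg_ext = kdArg[6], arg_int = kdArg[7],
          agm_ext = kdAgm[6], agm_int = kdAgm[7])
  new("GroundTruth", rates = rates, kd = kd, orientations = orientations,
      delta = delta, seed = as.integer(seed),
      extra = list(K = K, kdState = list(arg = kdArg, agm = kdAgm)))
}

#' Trace rendering specification
#'
#' @param frameInterval camera frame interval (s); default 10 ms.
#' @param photonRate expected total signal photons per frame.
#' @param backgroundRate expected background photons per frame per channel.
#' @param bleachTime time (s) of the single-step photobleach, or NULL.
#' @param nFrames trace length in frames, or NULL to cover the state path.
#' @return list of class \code{"TraceSpec"}.
#' @export
traceSpec <- function(frameInterval = 0.010, photonRate = 400,
                      backgroundRate = 5, bleachTime = NULL, nFrames = NULL) {
  stopifnot(frameInterval > 0, photonRate > 0, backgroundRate >= 0)
  structure(list(frameInterval = frameInterval, photonRate = photonRate,
                 backgroundRate = backgroundRate, bleachTime = bleachTime,
                 nFrames = nFrames), class = "TraceSpec")
}

#' Photon rate required for a target signal-to-noise ratio
#'
#' SNR is defined as (mean total signal - background) / SD of the total
#' intensity; under Poisson statistics SD = sqrt(signal + 4 background), so
#' the required signal rate solves \eqn{s^2 = snr^2 (s + 4b)}.
#'
#' @param snr target SNR.
#' @param background background photons per frame per channel.
#' @return signal photons per frame.
#' @export
photonRateForSnr <- function(snr, background = 0) {
  (snr^2 + snr * sqrt(snr^2 + 16 * background)) / 2
}

#' Simulate an eight-state conformational path under a ligand condition
#'
#' Gillespie simulation of the aggregated eight-state chain whose rates are
#' the apparent (ligand-condition-dependent) rate constants of the ground
#' truth at the given concentration.  The initial state is drawn from the
#' stationary distribution.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param ligand \code{"apo"}, \code{"arg"} or \code{"agm"}.
#' @param conc ligand concentration (mol/L).
#' @param nEvents target number of conformational events (dwell episodes);
#'   the path is truncated at the end of the \code{nEvents}-th event.
#' @param seed RNG seed.
#' @return data.frame with columns \code{state} (1..8), \code{conf} (1..4),
#'   \code{duration} (s).
#' @export
simulateStatePath <- function(truth, ligand = "apo", conc = 0,
                              nEvents = 100, seed = 1) {
  appk <- apparentRates(truthRates(truth), ligand, conc)
  Q <- .generator8(appk)
  exit <- -diag(Q)
  P <- Q / exit
  diag(P) <- 0
  cumP <- t(apply(P, 1, cumsum))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  p0 <- substateProbabilities(appk)
  ## simulate the embedded chain in chunks until enough conformational events
  nTarget <- as.integer(ceiling(nEvents * 2.5 + 50))
  states <- integer(0)
  s <- sample.int(8, 1, prob = p0)
  repeat {
    chunk <- integer(nTarget)
    u <- stats::runif(nTarget)
    for (i in seq_len(nTarget)) {
      chunk[i] <- s
      s <- which(u[i] <= cumP[s, ])[1]
    }
    states <- c(states, chunk)
    confRuns <- sum(diff(.confOf(states)) != 0) + 1L
    if (confRuns > nEvents) break
  }
  dur <- stats::rexp(length(states), exit[states])
  conf <- .confOf(states)
  ## cut at the end of the nEvents-th conformational event
  runEnd <- cumsum(rle(conf)$lengths)
  cut <- runEnd[nEvents]
  data.frame(state = states[seq_len(cut)], conf = conf[seq_len(cut)],
             duration = dur[seq_len(cut)])
}

#' Render a four-channel polarized photon-count trace from a state path
#'
#' Per frame, the expected channel intensities are the time-weighted mixture
#' of the forward-model intensities of the conformations occupied during the
#' frame (frames straddling a transition mix the two states in proportion to
#' occupancy time), plus the per-channel background; observed counts are
#' independent Poisson draws.  After \code{bleachTime} the signal drops to
#' background in a single step (partial weighting within the bleach frame).
#'
#' @param path state path from \code{\link{simulateStatePath}} (or any
#'   data.frame with \code{conf} and \code{duration} columns).
#' @param truth a \linkS4class{GroundTruth} (orientations and wobble angle).
#' @param spec a \code{\link{traceSpec}}.
#' @param seed RNG seed for the Poisson draws.
#' @param condition condition metadata stored in the trace.
#' @return a \linkS4class{PolarizedTrace}.
#' @export
renderTrace <- function(path, truth, spec = traceSpec(), seed = 1,
                        condition = list(species = "apo", conc = 0, pH = 5)) {
  if (is.null(path) || nrow(path) == 0) stop("empty state path")
  dt <- spec$frameInterval
  tEnd <- sum(path$duration)
  if (!is.null(spec$bleachTime)) tEnd <- max(tEnd, spec$bleachTime)
  n <- if (is.null(spec$nFrames)) as.integer(ceiling(tEnd / dt)) else
    as.integer(spec$nFrames)
  if (n < 2) stop("trace would be shorter than 2 frames")
  ori <- truthOrientations(truth)
  chan <- forwardIntensities(ori[, 1], ori[, 2], truth@delta,
                             spec$photonRate)     # 4 conf x 4 channels
  ## occupancy time of each conformation within each frame
  occ <- matrix(0, n, 4)
  t0 <- cumsum(c(0, path$duration))[seq_len(nrow(path))]
  t1 <- t0 + path$duration
  if (!is.null(spec$bleachTime)) {
    keep <- t0 < spec$bleachTime
    t0 <- t0[keep]; t1 <- pmin(t1[keep], spec$bleachTime)
    confs <- path$conf[keep]
  } else confs <- path$conf
  t1 <- pmin(t1, n * dt)
  t0 <- pmin(t0, n * dt)
  dadd <- matrix(0, n + 1, 4)                     # full-frame diff array
  for (e in seq_along(confs)) {
    if (t1[e] <= t0[e]) next
    cfe <- confs[e]
    f0 <- floor(t0[e] / dt); f1 <- floor((t1[e] - 1e-12) / dt)
    f0 <- min(f0, n - 1); f1 <- min(f1, n - 1)
    if (f0 == f1) {
      occ[f0 + 1, cfe] <- occ[f0 + 1, cfe] + (t1[e] - t0[e])
    } else {
      occ[f0 + 1, cfe] <- occ[f0 + 1, cfe] + ((f0 + 1) * dt - t0[e])
      occ[f1 + 1, cfe] <- occ[f1 + 1, cfe] + (t1[e] - f1 * dt)
      if (f1 > f0 + 1) {
        dadd[f0 + 2, cfe] <- dadd[f0 + 2, cfe] + dt
        dadd[f1 + 1, cfe] <- dadd[f1 + 1, cfe] - dt
      }
    }
  }
  occ <- occ + apply(dadd[seq_len(n), , drop = FALSE], 2, cumsum)
  expected <- (occ %*% chan) / dt + spec$backgroundRate
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  counts <- matrix(stats::rpois(n * 4L, as.numeric(expected)), n, 4)
  PolarizedTrace(counts, frameInterval = dt,
                 calibration = Calibration(delta = truth@delta,
                                           backgrounds = rep(spec$backgroundRate, 4)),
                 condition = condition,
                 meta = list(seed = seed, truthSeed = truth@seed,
                             photonRate = spec$photonRate))
}

#' Generate a synthetic tracer flux dataset
#'
#' Computes the deterministic fractional-uptake time course of the
#' ground-truth 24-state transport model under the given protocol (averaging
#' the two sidedness configurations when \code{sidednessMix}, mimicking
#' random transporter orientation in the vesicle membrane), scales it by the
#' recovery efficiency, and multiplies each sampled point by mean-one
#' lognormal noise with the requested coefficient of variation.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param protocol list with elements \code{species} (data.frame with
#'   columns \code{name}, \code{ligand}), \code{ext}, \code{int} (named
#'   initial concentrations, mol/L), \code{tracer} (species name whose
#'   fractional uptake is reported), \code{rv}, \code{times} (s), and
#'   optionally \code{vi}, \code{nTransporters}, \code{recoveryEfficiency},
#'   \code{sidednessMix} (default TRUE).
#' @param noiseCv coefficient of variation of the multiplicative sampling
#'   noise (>= 0).
#' @param seed RNG seed.
#' @return data.frame with columns \code{time} and \code{fractional_uptake}.
#' @export
makeFluxDataset <- function(truth, protocol, noiseCv = 0.05, seed = 1) {
  if (noiseCv < 0) stop("negative noise_cv")
  vi <- if (is.null(protocol$vi)) 1e-18 else protocol$vi
  nT <- if (is.null(protocol$nTransporters)) 1 else protocol$nTransporters
  re <- if (is.null(protocol$recoveryEfficiency)) 1 else
    protocol$recoveryEfficiency
  mix <- if (is.null(protocol$sidednessMix)) TRUE else protocol$sidednessMix
  comp <- CompartmentSystem(rv = protocol$rv, vi = vi, nTransporters = nT,
                            ext = protocol$ext, int = protocol$int,
                            recoveryEfficiency = re)
  tGrid <- sort(unique(c(0, protocol$times)))
  runCfg <- function(sd) {
    m <- model24FromTruth(truth, species = protocol$species$ligand,
                          names = protocol$species$name, sidedness = sd)
    integrateTransport(m, comp, tGrid)[[paste0("frac_", protocol$tracer)]]
  }
  f <- if (mix) (runCfg(1L) + runCfg(2L)) / 2 else runCfg(1L)
  keep <- tGrid %in% protocol$times
  f <- f[keep]; tms <- tGrid[keep]
  if (noiseCv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    sdlog <- sqrt(log(1 + noiseCv^2))
    f <- f * stats::rlnorm(length(f), -sdlog^2 / 2, sdlog)
  }
  data.frame(time = tms, fractional_uptake = f)
}
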