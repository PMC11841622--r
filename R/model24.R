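## 24-state transport model: generator assembly under given substrate
## concentrations and sidedness, stochastic (Gillespie) simulation with
## two-compartment bookkeeping, deterministic 24-ODE integration, serial-path
## flux rates, Michaelis-Menten fits, the obligatory-exchanger variant, and
## the closed-form exchange thermodynamics.

.AVOGADRO <- 6.02214076e23

## open substates facing the external/internal solutions
.openStates <- function(m) {
  if (m@sidedness == 1L) list(ext = 6L, int = 7L) else list(ext = 7L, int = 6L)
}

## static (concentration-independent) off-diagonal part of the 24x24 generator
.staticRates24 <- function(m) {
  Q <- matrix(0, 24, 24)
  tp <- .transitionPairs()
  for (r in seq_len(nrow(tp)))
    Q[tp$from[r], tp$to[r]] <- m@apo[[tp$name[r]]]
  op <- .openStates(m)
  for (j in seq_along(m@species)) {
    o <- 8L * j
    sp <- m@species[[j]]
    for (r in seq_len(nrow(tp)))
      Q[o + tp$from[r], o + tp$to[r]] <- sp$rates[[tp$name[r]]]
    ## unbinding: bound open substate -> apo open substate (release)
    Q[o + op$ext, op$ext] <- m@kon * sp$kdExt
    Q[o + op$int, op$int] <- m@kon * sp$kdInt
  }
  Q
}

#' Assemble the 24-state generator under given substrate concentrations
#'
#' Off-diagonal entries are the rate constants of the apo and ligand-bound
#' branches; second-order binding edges \eqn{k_{on}[L]} connect the apo open
#' substates to the corresponding bound states (the externally facing open
#' substate binds from the external solution, the internally facing one from
#' the internal solution) and unbinding edges carry
#' \eqn{k_{off} = k_{on} K_D}.  Rows sum to zero.
#'
#' @param m a \linkS4class{Model24}.
#' @param ext,int named numeric vectors of ligand concentrations (mol/L) in
#'   the external and internal compartments; names must match the model's
#'   species names.
#' @return 24 x 24 generator matrix (states 1..8 apo, 9..16 first species
#'   bound, 17..24 second species bound).
#' @export
buildGenerator <- function(m, ext, int) {
  if (any(ext < 0) || any(int < 0)) stop("negative concentration")
  Q <- .staticRates24(m)
  op <- .openStates(m)
  for (j in seq_along(m@species)) {
    o <- 8L * j
    sp <- m@species[[j]]
    Q[op$ext, o + op$ext] <- m@kon * ext[[sp$name]]
    Q[op$int, o + op$int] <- m@kon * int[[sp$name]]
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of the 24-state model
#'
#' @inheritParams buildGenerator
#' @return numeric(24) stationary probabilities (sums to 1).  States that are
#'   unreachable (e.g. bound branches at zero ligand) carry probability 0.
#' @export
stationaryState <- function(m, ext, int) {
  Q <- buildGenerator(m, ext, int)
  ## states with no edges at all (e.g. the second ligand branch of a
  ## single-species model) carry no probability
  active <- which(rowSums(abs(Q)) > 0 | colSums(abs(Q)) > 0)
  Qa <- Q[active, active, drop = FALSE]
  na <- length(active)
  A <- t(Qa)
  A[na, ] <- 1
  b <- c(rep(0, na - 1), 1)
  sc <- apply(abs(A), 1, max)
  sc[sc == 0] <- 1
  pa <- tryCatch(solve(A / sc, b / sc), error = function(e) NULL)
  if (is.null(pa) || any(!is.finite(pa)) || any(pa < -1e-6)) {
    ## reducible chain (e.g. the exchanger's isolated apo occluded pairs):
    ## take the long-time limit of a uniform start by repeated squaring of
    ## the uniformized transition matrix
    dtu <- 0.5 / max(-diag(Qa))
    P <- diag(na) + Qa * dtu
    P <- P / rowSums(P)
    for (i in 1:60) {
      P <- P %*% P
      P <- pmax(P, 0) / rowSums(pmax(P, 0))   # keep row-stochastic
    }
    pa <- as.numeric(rep(1 / na, na) %*% P)
  }
  p <- numeric(24)
  p[active] <- pa
  p[!is.finite(p)] <- 0
  p <- pmax(p, 0)
  p / sum(p)
}

#' Exact stochastic simulation of the 24-state transport model
#'
#' Gillespie simulation of a single transporter coupled to the finite
#' substrate pools of a two-compartment system: each dwell is drawn from the
#' exponential distribution set by the occupied state's total exit rate and
#' the destination from the multinomial over its transition rates.  A bound
#' open substate releases its ligand to the facing compartment when it
#' transitions to the apo open substate; the reverse transition takes one
#' ligand up from that compartment.  Concentrations (and hence binding
#' propensities) are updated after every such event.  The compartment volumes
#' are shared evenly among \code{comp$nTransporters}, so a single simulated
#' transporter serves volumes \code{vi/nT} and \code{ve/nT}.
#'
#' @param m a \linkS4class{Model24}.
#' @param comp a \code{\link{CompartmentSystem}}.
#' @param duration simulated time (s).
#' @param seed RNG seed.
#' @param state0 initial state (default: drawn from the stationary
#'   distribution at the initial concentrations).
#' @param recordPath record the full state path (set FALSE for long runs).
#' @return list with \code{path} (data.frame time/state/duration, if
#'   recorded), \code{events} (data.frame of binding/release events with
#'   time, species, side, direction), \code{uptake} (per-species data.frame
#'   of time and internal fraction), and the final \code{ext}/\code{int}
#'   concentrations.
#' @export
gillespieTransport <- function(m, comp, duration, seed = 1, state0 = NULL,
                               recordPath = TRUE) {
  stopifnot(duration > 0)
  spNames <- vapply(m@species, function(s) s$name, character(1))
  effVi <- comp$vi / comp$nTransporters
  effVe <- comp$ve / comp$nTransporters
  nExt <- comp$ext[spNames] * .AVOGADRO * effVe
  nInt <- comp$int[spNames] * .AVOGADRO * effVi
  op <- .openStates(m)
  static <- .staticRates24(m)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (is.null(state0)) {
    p0 <- stationaryState(m, nExt / (.AVOGADRO * effVe),
                          nInt / (.AVOGADRO * effVi))
    state0 <- sample.int(24, 1, prob = p0)
  }
  s <- state0
  t <- 0
  cap <- 4096L
  pt <- numeric(cap); ps <- integer(cap); np <- 0L
  evT <- numeric(cap); evSp <- integer(cap); evSide <- integer(cap)
  evDir <- integer(cap); nev <- 0L
  kon <- m@kon
  repeat {
    rates <- static[s, ]
    if (s == op$ext)
      for (j in seq_along(spNames))
        rates[8L * j + op$ext] <- kon * nExt[j] / (.AVOGADRO * effVe)
    if (s == op$int)
      for (j in seq_along(spNames))
        rates[8L * j + op$int] <- kon * nInt[j] / (.AVOGADRO * effVi)
    R <- sum(rates)
    if (R <= 0) stop("absorbing state reached: zero exit rates")
    dt <- stats::rexp(1, R)
    if (t + dt > duration) break
    t <- t + dt
    nxt <- sample.int(24L, 1L, prob = rates)
    ## bookkeeping of binding/release
    j <- (nxt - 1L) %/% 8L; sj <- (s - 1L) %/% 8L
    if (sj == 0L && j > 0L) {          # binding
      side <- if (s == op$ext) 1L else 2L
      if (side == 1L) nExt[j] <- nExt[j] - 1 else nInt[j] <- nInt[j] - 1
      nev <- nev + 1L
      if (nev > length(evT)) {
        evT <- c(evT, numeric(length(evT))); evSp <- c(evSp, integer(length(evSp)))
        evSide <- c(evSide, integer(length(evSide)))
        evDir <- c(evDir, integer(length(evDir)))
      }
      evT[nev] <- t; evSp[nev] <- j; evSide[nev] <- side; evDir[nev] <- 1L
    } else if (sj > 0L && j == 0L) {   # release
      side <- if (nxt == op$ext) 1L else 2L
      if (side == 1L) nExt[sj] <- nExt[sj] + 1 else nInt[sj] <- nInt[sj] + 1
      nev <- nev + 1L
      if (nev > length(evT)) {
        evT <- c(evT, numeric(length(evT))); evSp <- c(evSp, integer(length(evSp)))
        evSide <- c(evSide, integer(length(evSide)))
        evDir <- c(evDir, integer(length(evDir)))
      }
      evT[nev] <- t; evSp[nev] <- sj; evSide[nev] <- side; evDir[nev] <- -1L
    }
    if (recordPath) {
      np <- np + 1L
      if (np > length(pt)) {
        pt <- c(pt, numeric(length(pt))); ps <- c(ps, integer(length(ps)))
      }
      pt[np] <- t; ps[np] <- nxt
    }
    s <- nxt
  }
  events <- data.frame(time = evT[seq_len(nev)],
                       species = spNames[evSp[seq_len(nev)]],
                       side = c("ext", "int")[evSide[seq_len(nev)]],
                       direction = evDir[seq_len(nev)],
                       stringsAsFactors = FALSE)
  uptake <- lapply(seq_along(spNames), function(j) {
    n0e <- comp$ext[[spNames[j]]] * .AVOGADRO * effVe
    n0i <- comp$int[[spNames[j]]] * .AVOGADRO * effVi
    tot <- n0e + n0i
    ev <- events[events$species == spNames[j], , drop = FALSE]
    ## internal count changes: release to int (+1), uptake from int (-1)
    dint <- ifelse(ev$side == "int", -ev$direction, 0)
    data.frame(time = c(0, ev$time),
               frac = (n0i + cumsum(c(0, dint))) / tot)
  })
  names(uptake) <- spNames
  path <- if (recordPath && np > 0)
    data.frame(time = pt[seq_len(np)], state = ps[seq_len(np)]) else NULL
  list(path = path, events = events, uptake = uptake,
       ext = nExt / (.AVOGADRO * effVe), int = nInt / (.AVOGADRO * effVi),
       state = s)
}

#' Deterministic two-compartment transport time course (24 ODEs)
#'
#' Integrates the 24 state probabilities of the transporter coupled to the
#' substrate concentrations of both compartments: the state equations are
#' \eqn{dp/dt = Q([L])^T p} with the concentration-dependent generator, and
#' each compartment concentration changes with the net binding/release flux
#' through the facing open substate, scaled by the number of transporters
#' and the compartment volume.  No parameters are adjustable once the model
#' is fixed.
#'
#' @param m a \linkS4class{Model24}.
#' @param comp a \code{\link{CompartmentSystem}}.
#' @param tGrid increasing time grid (s), starting at 0.
#' @param p0 initial state probabilities (default: stationary at the initial
#'   concentrations).
#' @param rtol,atol integrator tolerances.
#' @return data.frame with columns \code{time}, per-species internal
#'   fractional content \code{frac_<name>} (fraction of that species' total
#'   molecules that is inside vesicles, scaled by the recovery efficiency),
#'   per-species concentrations \code{ext_<name>}, \code{int_<name>}, and a
#'   \code{conservation} attribute with the worst relative mass defect.
#' @export
integrateTransport <- function(m, comp, tGrid, p0 = NULL,
                               rtol = 1e-8, atol = 1e-12) {
  stopifnot(all(diff(tGrid) > 0))
  spNames <- vapply(m@species, function(s) s$name, character(1))
  nsp <- length(spNames)
  op <- .openStates(m)
  static <- .staticRates24(m)
  kon <- m@kon
  nT <- comp$nTransporters
  vi <- comp$vi; ve <- comp$ve
  if (is.null(p0))
    p0 <- stationaryState(m, comp$ext[spNames], comp$int[spNames])
  y0 <- c(p0, comp$ext[spNames], comp$int[spNames])
  deriv <- function(t, y, parms) {
    p <- y[1:24]
    ce <- y[24 + seq_len(nsp)]
    ci <- y[24 + nsp + seq_len(nsp)]
    Q <- static
    for (j in seq_len(nsp)) {
      Q[op$ext, 8L * j + op$ext] <- kon * max(ce[j], 0)
      Q[op$int, 8L * j + op$int] <- kon * max(ci[j], 0)
    }
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    dp <- as.numeric(crossprod(Q, p))
    dce <- dci <- numeric(nsp)
    for (j in seq_len(nsp)) {
      sp <- m@species[[j]]
      o <- 8L * j
      ## net release into each compartment (molecules/s per transporter)
      relExt <- kon * sp$kdExt * p[o + op$ext] - kon * max(ce[j], 0) * p[op$ext]
      relInt <- kon * sp$kdInt * p[o + op$int] - kon * max(ci[j], 0) * p[op$int]
      dce[j] <- nT * relExt / (.AVOGADRO * ve)
      dci[j] <- nT * relInt / (.AVOGADRO * vi)
    }
    list(c(dp, dce, dci))
  }
  sol <- deSolve::lsoda(y0, tGrid, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  p <- sol[, 1 + 1:24, drop = FALSE]
  ce <- sol[, 1 + 24 + seq_len(nsp), drop = FALSE]
  ci <- sol[, 1 + 24 + nsp + seq_len(nsp), drop = FALSE]
  out <- data.frame(time = sol[, 1])
  worst <- 0
  for (j in seq_len(nsp)) {
    o <- 8L * j
    bound <- rowSums(p[, o + 1:8, drop = FALSE])
    nInt <- ci[, j] * .AVOGADRO * vi
    nExt <- ce[, j] * .AVOGADRO * ve
    tot <- nInt + nExt + nT * bound
    out[[paste0("frac_", spNames[j])]] <-
      comp$recoveryEfficiency * nInt / tot
    out[[paste0("ext_", spNames[j])]] <- ce[, j]
    out[[paste0("int_", spNames[j])]] <- ci[, j]
    defect <- abs(tot - tot[1]) / tot[1]
    worst <- max(worst, max(defect))
  }
  out$probSum <- rowSums(p)
  attr(out, "conservation") <- worst
  attr(out, "probabilities") <- p
  out
}

#' Net flux rate through a serial transport-path transition
#'
#' The net rate (in the uptake direction, external to internal) of one of
#' the five serially related transitions along the transport path, computed
#' as the difference between the forward and backward rates, e.g.
#' \eqn{{}^{app}k_{flux} = k^L_{2,6} P^L_2 - k^L_{6,2} P^L_6} for the step
#' between the bound outward-occluded and outward-open substates.  The step
#' between the two bound communicating conformations is the sum of its three
#' underlying parallel pathways.  At quasi-steady state all five agree.
#'
#' @param m a \linkS4class{Model24}.
#' @param p numeric(24) instantaneous state probabilities.
#' @param ext,int named concentration vectors (mol/L).
#' @param transition one of \code{"binding_ext"}, \code{"serial_ext"},
#'   \code{"cross"}, \code{"serial_int"}, \code{"release_int"}, or
#'   \code{"all"}.
#' @param species index (1 or 2) of the transported species.
#' @return net rate(s) in 1/s per transporter (named if \code{"all"}).
#' @export
fluxRate <- function(m, p, ext, int, transition = "all", species = 1L) {
  op <- .openStates(m)
  sp <- m@species[[species]]
  o <- 8L * species
  kon <- m@kon
  extConf <- .confOf(op$ext)   # bound conformation on the external side
  intConf <- .confOf(op$int)
  rn <- function(i, j) sp$rates[[paste0("k_", i, "_", j)]]
  others <- setdiff(1:4, c(extConf))
  vals <- c(
    binding_ext = kon * ext[[sp$name]] * p[op$ext] -
      kon * sp$kdExt * p[o + op$ext],
    serial_ext = rn(op$ext, extConf) * p[o + op$ext] -
      rn(extConf, op$ext) * p[o + extConf],
    cross = sum(vapply(others, function(j)
      rn(extConf, j) * p[o + extConf] - rn(j, extConf) * p[o + j],
      numeric(1))),
    serial_int = rn(intConf, op$int) * p[o + intConf] -
      rn(op$int, intConf) * p[o + op$int],
    release_int = kon * sp$kdInt * p[o + op$int] -
      kon * int[[sp$name]] * p[op$int])
  if (transition == "all") return(vals)
  if (!transition %in% names(vals)) stop("unknown transition name")
  vals[[transition]]
}

#' Michaelis-Menten fit of rate versus substrate concentration
#'
#' Least-squares fit of \eqn{v = k_{max} [S] / (K_m + [S])}, optionally with
#' a nonzero offset (the modified Michaelis-Menten form, which lets the rate
#' approach a nonzero minimum as the concentration approaches zero, the
#' signature of a uniporter's substrate-independent apo pathway).
#'
#' @param s substrate concentrations (mol/L), at least 4.
#' @param v observed rates.
#' @param allowOffset fit the modified form with a floor term.
#' @return list with \code{kmax}, \code{km}, \code{offset} (0 when not
#'   allowed) and \code{fitted}.
#' @export
fitMichaelisMenten <- function(s, v, allowOffset = FALSE) {
  stopifnot(length(s) >= 4, length(s) == length(v))
  df <- data.frame(s = s, v = v)
  km0 <- max(stats::median(s), 1e-12)
  if (allowOffset) {
    fit <- minpack.lm::nlsLM(
      v ~ off + kmax * s / (km + s), data = df,
      start = list(off = max(min(v), 1e-12), kmax = max(v) - min(v), km = km0),
      lower = c(0, 0, 1e-15),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(kmax = cf[["kmax"]], km = cf[["km"]], offset = cf[["off"]],
         fitted = stats::fitted(fit))
  } else {
    fit <- minpack.lm::nlsLM(
      v ~ kmax * s / (km + s), data = df,
      start = list(kmax = max(v), km = km0),
      lower = c(0, 1e-15),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    list(kmax = cf[["kmax"]], km = cf[["km"]], offset = 0,
         fitted = stats::fitted(fit))
  }
}

#' Obligatory-exchanger variant of a 24-state model
#'
#' Removes the apo pathway for conformational changes: all 12 apo
#' inter-conformational transitions among S1--S4 are eliminated (the serial
#' apo transitions to the cul-de-sac substates are retained), so every
#' crossing of the membrane requires a bound ligand and the transporter
#' becomes an obligatory 1:1 exchanger.
#'
#' @param m a \linkS4class{Model24}.
#' @return the modified \linkS4class{Model24}.
#' @export
makeExchanger <- function(m) {
  apo <- m@apo
  for (r in seq_len(nrow(.confPairs))) {
    i <- .confPairs[r, 1]; j <- .confPairs[r, 2]
    apo[paste0("k_", i, "_", j)] <- 0
    apo[paste0("k_", j, "_", i)] <- 0
  }
  methods::initialize(m, apo = apo)
}

#' Theoretical maximal fractional uptake of a 1:1 exchanger
#'
#' Two-compartment exchange thermodynamics: with external-to-internal volume
#' ratio \eqn{r_v} and initial internal-to-external concentration ratio
#' \eqn{r_c}, the maximal fraction of the radioactive substrate that an
#' obligatory 1:1 exchange can accumulate inside the vesicles is
#' \eqn{F_{max} = 1 / (1 + r_v / r_c)}, predetermined by the initial
#' conditions and independent of all kinetic parameters.
#'
#' @param rv external-to-internal volume ratio (> 0).
#' @param rc initial concentration ratio
#'   \eqn{[NR_i](0) / [R_e](0)} (> 0).
#' @return maximal fractional uptake in (0, 1).
#' @export
fmaxExchanger <- function(rv, rc) {
  stopifnot(all(rv > 0), all(rc > 0))
  1 / (1 + rv / rc)
}

#' Volume ratio from the observed maximal fractional uptake
#'
#' Under the symmetric concentration condition (\eqn{r_c = 1}) the observed
#' maximal fractional uptake partitions the tracer by volume, so
#' \eqn{r_v = (1 - F^{obs}_{max}) / F^{obs}_{max}}.
#'
#' @param fmaxObs observed maximal fractional uptake, in (0, 1).
#' @return external-to-internal volume ratio.
#' @export
rvFromFmax <- function(fmaxObs) {
  stopifnot(all(fmaxObs > 0), all(fmaxObs < 1))
  (1 - fmaxObs) / fmaxObs
}

#' Equilibrium compositions of a two-compartment 1:1 exchange
#'
#' A pure 1:1 exchange conserves the total substrate content of each
#' compartment while mixing the radioactive and nonradioactive species;
#' entropy maximization requires the probability of picking a radioactive
#' molecule to be equal in both compartments at equilibrium, so the
#' nonradioactive-to-radioactive ratio is the same everywhere and equals the
#' global ratio \eqn{n^{NR}_i(0) / n^R_e(0)}.
#'
#' @param nRe0 initial number of radioactive molecules in the external
#'   compartment.
#' @param nNRi0 initial number of nonradioactive molecules in the internal
#'   compartment.
#' @return list with the equilibrium counts \code{nRi}, \code{nNRi},
#'   \code{nRe}, \code{nNRe}, the common ratio \code{ratio}, and the
#'   resulting \code{fmax} = nRi / nRe0.
#' @export
mixingEquilibrium <- function(nRe0, nNRi0) {
  stopifnot(nRe0 > 0, nNRi0 > 0)
  ratio <- nNRi0 / nRe0
  tot <- nRe0 + nNRi0
  pR <- nRe0 / tot
  list(nRi = nNRi0 * pR, nNRi = nNRi0 * (1 - pR),
       nRe = nRe0 * pR, nNRe = nRe0 * (1 - pR),
       ratio = ratio, fmax = nNRi0 * pR / nRe0)
}

#' Build a 24-state model from a ground truth
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param species character vector (1 or 2 of \code{"arg"}, \code{"agm"}),
#'   the ligand branches to include; a species may be repeated (e.g.
#'   radioactive and nonradioactive pools of the same substrate) by giving
#'   \code{names} distinguishing them.
#' @param names species names used in concentration vectors (default
#'   \code{species}).
#' @param kon association rate constant (1/M/s).
#' @param sidedness 1 or 2.
#' @return a \linkS4class{Model24}.
#' @export
model24FromTruth <- function(truth, species = c("arg", "agm"),
                             names = species, kon = 1e7, sidedness = 1L) {
  kd <- truthKd(truth)
  spl <- lapply(seq_along(species), function(i) {
    lig <- species[i]
    list(name = names[i], rates = rateConstants(truth, lig),
         kdExt = kd[[paste0(lig, "_ext")]], kdInt = kd[[paste0(lig, "_int")]])
  })
  Model24(apo = rateConstants(truth, "apo"), species = spl, kon = kon,
          sidedness = as.integer(sidedness))
}
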