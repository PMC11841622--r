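## Dwell-time kinetics: camera-quantized exponential mixtures, MLE fitting,
## single- vs double-exponential F tests, ligand-coupled global fits,
## inversion of (lambda1, lambda2, f, p_ij) to the serial-scheme rate
## constants, binding-isotherm fits of apparent rates, stationary substate
## probabilities, and equilibrium-constant fits.

#' Camera-quantized exponential dwell-time probability mass function
#'
#' Exact probability that an exponentially distributed dwell with rate
#' \code{lam}, starting at a uniformly distributed phase within a camera
#' frame, is recorded as spanning \code{k} frames of duration \code{dt}.
#' With \eqn{x = \lambda \Delta t}:
#' \deqn{P(1) = 1 - (1 - e^{-x})/x, \qquad
#'       P(k) = e^{-kx}(e^{x}-1)^2/x \quad (k \ge 2),}
#' which sums to 1 over \eqn{k \ge 1} and tends to the geometric law with
#' mean \eqn{1/x} as \eqn{x \to 0}.  The mass is renormalized over
#' \code{k >= kmin} when short events below \code{kmin} frames are discarded,
#' which also absorbs the bias from missed short events.
#'
#' @param lam exponential rate (1/s), > 0.
#' @param dt frame interval (s), > 0.
#' @param k recorded dwell length(s) in frames (integer >= kmin).
#' @param kmin smallest retained dwell length (frames, default 1).
#' @return probability mass at each \code{k}.
#' @export
dwellPmf <- function(lam, dt, k, kmin = 1) {
  stopifnot(lam > 0, dt > 0, kmin >= 1)
  if (any(k < kmin)) stop("k below kmin")
  x <- lam * dt
  p <- ifelse(k == 1,
              1 + expm1(-x) / x,
              exp(-x * k) * expm1(x)^2 / x)
  if (kmin > 1) {
    below <- seq_len(kmin - 1)
    norm <- 1 - sum(ifelse(below == 1, 1 + expm1(-x) / x,
                           exp(-x * below) * expm1(x)^2 / x))
    p <- p / norm
  }
  p
}

## survivor function P(K > kstar), kstar >= 1 (unrenormalized, kmin = 1)
.dwellTail <- function(lam, dt, kstar) {
  x <- lam * dt
  expm1(x)^2 / x * exp(-x * (kstar + 1)) / (-expm1(-x))
}

#' Two-component camera-quantized dwell-time mixture
#'
#' Mixture \code{f * dwellPmf(lam1) + (1 - f) * dwellPmf(lam2)} with the fast
#' component first (\code{lam1 >= lam2}).
#'
#' @inheritParams dwellPmf
#' @param lam1,lam2 fast and slow rates (1/s).
#' @param f fast-component amplitude fraction in [0, 1].
#' @return probability mass at each \code{k}.
#' @export
dwellMixPmf <- function(lam1, lam2, f, dt, k, kmin = 1) {
  f * dwellPmf(lam1, dt, k, kmin) + (1 - f) * dwellPmf(lam2, dt, k, kmin)
}

.mixTail <- function(lam1, lam2, f, dt, kstar, kmin = 1) {
  tail1 <- .dwellTail(lam1, dt, kstar)
  tail2 <- .dwellTail(lam2, dt, kstar)
  if (kmin > 1) {
    ## renormalize consistently with dwellPmf's kmin truncation
    below1 <- 1 - sum(dwellPmf(lam1, dt, seq_len(kmin - 1), kmin = 1))
    below2 <- 1 - sum(dwellPmf(lam2, dt, seq_len(kmin - 1), kmin = 1))
    tail1 <- tail1 / below1
    tail2 <- tail2 / below2
  }
  f * tail1 + (1 - f) * tail2
}

#' Maximum-likelihood fit of camera-quantized exponential dwell mixtures
#'
#' Fits the single- or double-exponential camera-quantized pmf to recorded
#' dwell lengths (in frames) by maximum likelihood with multi-start bounded
#' optimization on log-transformed rates (and logit-transformed fraction).
#'
#' @param dwells integer vector of recorded dwell lengths in frames.
#' @param dt frame interval (s).
#' @param ncomp number of exponential components, 1 or 2.
#' @param kmin smallest retained dwell length (frames).
#' @param nStarts number of optimization restarts for \code{ncomp = 2}.
#' @param seed RNG seed for the restarts.
#' @return list of class \code{"DwellFit"}: \code{lambda1 >= lambda2} (1/s),
#'   \code{tau1}, \code{tau2} (s), \code{f} (fast fraction; 1 for a single
#'   exponential), \code{loglik}, \code{n}, \code{ncomp}, \code{dt},
#'   \code{kmin}, and the tabulated \code{counts}.
#' @export
fitDwell <- function(dwells, dt, ncomp = 2, kmin = 1, nStarts = 20, seed = 1) {
  dwells <- as.integer(dwells)
  stopifnot(all(dwells >= kmin), ncomp %in% c(1, 2))
  if (ncomp == 2 && length(dwells) < 50)
    stop("at least 50 dwells are required for a two-component fit")
  tab <- table(dwells)
  ks <- as.integer(names(tab))
  cnt <- as.numeric(tab)
  n <- length(dwells)
  meanK <- sum(ks * cnt) / n
  lam0 <- 1 / (max(meanK - 0.5, 0.51) * dt)

  if (ncomp == 1) {
    nll <- function(par) {
      lam <- exp(par)
      -sum(cnt * log(pmax(dwellPmf(lam, dt, ks, kmin), 1e-300)))
    }
    opt <- stats::nlminb(log(lam0), nll,
                         lower = log(1e-6 / dt), upper = log(50 / dt))
    lam <- exp(opt$par)
    out <- list(lambda1 = lam, lambda2 = NA_real_, f = 1,
                tau1 = 1 / lam, tau2 = NA_real_,
                loglik = -opt$objective, n = n, ncomp = 1L, dt = dt,
                kmin = kmin, counts = data.frame(k = ks, n = cnt))
    class(out) <- "DwellFit"
    return(out)
  }

  nll <- function(par) {
    l1 <- exp(par[1]); l2 <- exp(par[2]); f <- stats::plogis(par[3])
    -sum(cnt * log(pmax(dwellMixPmf(l1, l2, f, dt, ks, kmin), 1e-300)))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nStarts)) {
    sep <- stats::runif(1, 1.5, 12)
    start <- c(log(lam0 * sep), log(lam0 / sep),
               stats::qlogis(stats::runif(1, 0.2, 0.9)))
    opt <- tryCatch(
      stats::nlminb(start, nll, lower = c(rep(log(1e-6 / dt), 2), -8),
                    upper = c(rep(log(50 / dt), 2), 8)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("dwell-time fit failed to converge")
  l <- exp(best$par[1:2]); f <- stats::plogis(best$par[3])
  if (l[1] < l[2]) { l <- rev(l); f <- 1 - f }
  out <- list(lambda1 = l[1], lambda2 = l[2], f = f,
              tau1 = 1 / l[1], tau2 = 1 / l[2],
              loglik = -best$objective, n = n, ncomp = 2L, dt = dt,
              kmin = kmin, counts = data.frame(k = ks, n = cnt))
  class(out) <- "DwellFit"
  out
}

#' @export
print.DwellFit <- function(x, ...) {
  if (x$ncomp == 1)
    cat(sprintf("DwellFit (1 component): tau = %.4g s (n = %d, logL = %.2f)\n",
                x$tau1, x$n, x$loglik))
  else
    cat(sprintf(
      "DwellFit (2 components): tau1 = %.4g s, tau2 = %.4g s, f = %.3f (n = %d, logL = %.2f)\n",
      x$tau1, x$tau2, x$f, x$n, x$loglik))
  invisible(x)
}

## binned Poisson deviance of a DwellFit; bins aggregated so that expected
## counts stay >= minExp, with an explicit tail bin
.binnedDeviance <- function(fit, minExp = 5) {
  ks <- fit$counts$k; cnt <- fit$counts$n
  n <- fit$n
  kmax <- max(ks)
  allk <- seq(fit$kmin, kmax)
  obs <- numeric(length(allk))
  obs[match(ks, allk)] <- cnt
  pm <- if (fit$ncomp == 1)
    dwellPmf(fit$lambda1, fit$dt, allk, fit$kmin)
  else
    dwellMixPmf(fit$lambda1, fit$lambda2, fit$f, fit$dt, allk, fit$kmin)
  exp_ <- n * pm
  tailP <- max(1 - sum(pm), 0)
  ## aggregate from the right until every bin has expected >= minExp
  oB <- c(obs, 0); eB <- c(exp_, n * tailP)
  i <- length(eB)
  while (i > 1) {
    if (eB[i] < minExp) {
      eB[i - 1] <- eB[i - 1] + eB[i]
      oB[i - 1] <- oB[i - 1] + oB[i]
      oB <- oB[-i]; eB <- eB[-i]
    }
    i <- i - 1
  }
  keep <- eB > 0
  oB <- oB[keep]; eB <- eB[keep]
  D <- 2 * sum(ifelse(oB > 0, oB * log(oB / eB), 0) - (oB - eB))
  list(D = D, nbins = length(oB))
}

#' F test of single- versus double-exponential dwell fits
#'
#' Nested-model F test based on the binned Poisson deviances of the two
#' maximum-likelihood fits to the same dwell data:
#' \eqn{F = ((D_1 - D_2)/2) / (D_2 / (n_b - 3))} with 2 extra parameters in
#' the double-exponential model and \eqn{n_b} count bins.  Returns the
#' p-value; \code{p = 1} when the richer fit is not better.
#'
#' @param fit1 single-exponential \code{"DwellFit"}.
#' @param fit2 double-exponential \code{"DwellFit"} on the same data.
#' @return p-value with attributes \code{F}, \code{D1}, \code{D2}.
#' @export
ftestComponents <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "DwellFit"), inherits(fit2, "DwellFit"))
  if (fit1$n != fit2$n)
    stop("fits must be nested fits of identical data")
  b1 <- .binnedDeviance(fit1)
  b2 <- .binnedDeviance(fit2)
  df2 <- b2$nbins - 3
  if (b2$D >= b1$D || df2 < 1) {
    p <- 1
    attr(p, "F") <- 0
  } else {
    Fstat <- ((b1$D - b2$D) / 2) / (b2$D / df2)
    p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
    attr(p, "F") <- Fstat
  }
  attr(p, "D1") <- b1$D
  attr(p, "D2") <- b2$D
  p
}

#' Eigen-rates of the serial two-substate scheme
#'
#' For a conformation whose entered substate A exits to other conformations
#' at total rate \code{kOut} and exchanges with its occluded cul-de-sac
#' partner B at rates \code{kAb} (A to B) and \code{kBa} (B to A), the dwell
#' time in the conformation is a two-exponential mixture with
#' \eqn{\lambda_1 + \lambda_2 = k_{out} + k_{ab} + k_{ba}},
#' \eqn{\lambda_1 \lambda_2 = k_{out} k_{ba}} and fast fraction
#' \eqn{f = (k_{out} - \lambda_2) / (\lambda_1 - \lambda_2)}.
#'
#' @param kOut,kAb,kBa positive rate constants (1/s), vectorized.
#' @return data.frame with columns \code{lambda1}, \code{lambda2}, \code{f}.
#' @export
serialEigenrates <- function(kOut, kAb, kBa) {
  s <- kOut + kAb + kBa
  disc <- sqrt(pmax(s^2 - 4 * kOut * kBa, 0))
  l1 <- (s + disc) / 2
  l2 <- (s - disc) / 2
  f <- ifelse(l1 > l2, (kOut - l2) / (l1 - l2), 1)
  data.frame(lambda1 = l1, lambda2 = l2, f = f)
}

#' Invert dwell parameters to the serial-scheme rate constants
#'
#' Closed-form inversion of the serial two-substate scheme: from the dwell
#' mixture parameters and the exit-conditional transition probabilities of a
#' conformation,
#' \deqn{k_{out} = f\lambda_1 + (1-f)\lambda_2,\quad
#'       k_{ba} = \lambda_1\lambda_2 / k_{out},\quad
#'       k_{ab} = \lambda_1 + \lambda_2 - k_{out} - k_{ba},}
#' and the directed inter-conformational rates are \eqn{k_{ij} = k_{out}
#' p_{ij}}.
#'
#' @param lambda1,lambda2 fast and slow dwell rates (1/s),
#'   \code{lambda1 > lambda2 > 0}.
#' @param f fast-component fraction in (0, 1].
#' @param pRow exit probabilities to the other conformations (sums to 1).
#' @return list with \code{kOut}, \code{kAb}, \code{kBa}, \code{kInter}
#'   (\code{kOut * pRow}) and \code{flag} (\code{"ok"} or
#'   \code{"single-state"} at the f = 1 boundary).
#' @export
invertSerialScheme <- function(lambda1, lambda2, f, pRow) {
  if (!(lambda1 > lambda2) || lambda2 <= 0)
    stop("requires lambda1 > lambda2 > 0")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (abs(sum(pRow) - 1) > 1e-6)
    stop("exit probabilities must sum to 1")
  kOut <- f * lambda1 + (1 - f) * lambda2
  kBa <- lambda1 * lambda2 / kOut
  ## algebraically lambda1 + lambda2 - kOut - kBa, but computed in the
  ## cancellation-free product form (lambda1 - kOut = (1-f)(lambda1 -
  ## lambda2) and kOut - lambda2 = f(lambda1 - lambda2))
  kAb <- f * (1 - f) * (lambda1 - lambda2)^2 / kOut
  flag <- "ok"
  tol <- 1e-8 * (lambda1 + lambda2)
  if (kAb < -tol)
    stop(sprintf(
      "non-physical inversion: k_ab = %.4g < 0 (lambda1 = %.4g, lambda2 = %.4g, f = %.4g)",
      kAb, lambda1, lambda2, f))
  if (kAb <= tol) {
    kAb <- max(kAb, 0)
    flag <- "single-state"
  }
  list(kOut = kOut, kAb = kAb, kBa = kBa, kInter = kOut * pRow, flag = flag)
}

#' Apparent rates for a conformation from dwell fits and transition
#' probabilities
#'
#' Combines per-conformation double-exponential dwell fits with the
#' exit-conditional transition matrix into the 20 apparent rate constants of
#' the eight-state scheme for one ligand condition.
#'
#' @param fits list of 4 \code{"DwellFit"} objects (or lists with
#'   \code{lambda1}, \code{lambda2}, \code{f}), one per conformation C1..C4.
#' @param tstats a \code{"TransitionStats"} with a 4 x 4 \code{p} matrix.
#' @return named numeric(20) of apparent rates (names as
#'   \code{\link{transitionNames}}).
#' @export
apparentRatesFromFits <- function(fits, tstats) {
  stopifnot(length(fits) == 4)
  out <- stats::setNames(numeric(20), transitionNames())
  for (i in 1:4) {
    ft <- fits[[i]]
    pr <- tstats$p[i, -i]
    inv <- invertSerialScheme(ft$lambda1, ft$lambda2, ft$f, pr)
    js <- setdiff(1:4, i)
    out[paste0("k_", i, "_", js)] <- inv$kInter
    out[paste0("k_", i, "_", i + 4)] <- inv$kAb
    out[paste0("k_", i + 4, "_", i)] <- inv$kBa
  }
  out
}

#' Apparent rate constants at a given ligand concentration
#'
#' Binding-isotherm interpolation between the apo and ligand-bound rate
#' constants:
#' \deqn{{}^{app}k_{ij} = \frac{k_{ij} + {}^{L}k_{ij}\,[L]/K_{1/2}}
#'                             {1 + [L]/K_{1/2}}.}
#'
#' @param rates a \linkS4class{RateSet}.
#' @param ligand \code{"arg"}, \code{"agm"} or \code{"apo"}.
#' @param conc ligand concentration (mol/L).
#' @return named numeric(20) of apparent rates (1/s).
#' @export
apparentRates <- function(rates, ligand, conc = 0) {
  if (ligand == "apo" || conc == 0) return(rates@apo)
  k <- rates@apo
  lk <- slot(rates, ligand)
  kh <- rates@khalf[[ligand]]
  x <- conc / kh
  (k + lk * x) / (1 + x)
}

#' Global ligand-coupled fit of dwell-time distributions
#'
#' Joint maximum-likelihood fit of the double-exponential camera-quantized
#' pmf to dwell data of one conformation collected over a concentration
#' series of one ligand, where each of \eqn{\tau_1}, \eqn{\tau_2} and
#' \eqn{f} varies with concentration as a binding isotherm
#' \eqn{(x_0 + x_L [L]/K_{1/2}) / (1 + [L]/K_{1/2})} with a shared
#' half-saturation constant.
#'
#' @param dwellSets list of lists with elements \code{conc} (mol/L) and
#'   \code{dwells} (integer frames); must include the apo condition
#'   (conc 0) and at least 3 concentrations.
#' @param dt frame interval (s).
#' @param kmin smallest retained dwell length (frames).
#' @param nStarts,seed multi-start control.
#' @return list with apo and saturating values \code{tau1_0},
#'   \code{tau1_inf}, \code{tau2_0}, \code{tau2_inf}, \code{f_0},
#'   \code{f_inf}, the shared \code{khalf} (mol/L), \code{loglik},
#'   \code{bracketed} (FALSE when the concentration range does not bracket
#'   K1/2), and \code{predict(conc)} returning (tau1, tau2, f).
#' @export
globalFitDwell <- function(dwellSets, dt, kmin = 1, nStarts = 20, seed = 1) {
  concs <- vapply(dwellSets, function(s) s$conc, numeric(1))
  if (length(concs) < 3 || !any(concs == 0))
    stop("need >= 3 concentrations including the apo condition")
  tabs <- lapply(dwellSets, function(s) {
    tb <- table(as.integer(s$dwells))
    list(k = as.integer(names(tb)), n = as.numeric(tb))
  })
  isot <- function(x0, xinf, w) x0 + (xinf - x0) * w
  ## full parameterization: each of tau1, tau2 and f follows its own
  ## binding isotherm (the fast and slow components report on different
  ## substates, whose half-saturation constants need not coincide)
  nll9 <- function(par) {
    t1 <- exp(par[1:2]); t2 <- exp(par[3:4])
    f <- stats::plogis(par[5:6]); K3 <- exp(par[7:9])
    tot <- 0
    for (i in seq_along(tabs)) {
      w <- concs[i] / (concs[i] + K3)
      tau1 <- isot(t1[1], t1[2], w[1]); tau2 <- isot(t2[1], t2[2], w[2])
      fi <- isot(f[1], f[2], w[3])
      pm <- dwellMixPmf(1 / tau1, 1 / tau2, fi, dt, tabs[[i]]$k, kmin)
      tot <- tot - sum(tabs[[i]]$n * log(pmax(pm, 1e-300)))
    }
    tot
  }
  nll <- function(par) nll9(c(par[1:6], par[7], par[7], par[7]))
  ## initialize endpoints from per-condition fits at the extreme
  ## concentrations, then profile the likelihood over the (nonconvex)
  ## half-saturation constant on a log grid, optimizing the six remaining
  ## parameters at each node, and polish the best solution jointly
  i0 <- which.min(concs); iN <- which.max(concs)
  f0 <- fitDwell(dwellSets[[i0]]$dwells, dt, 2, kmin, nStarts = 8, seed = seed)
  fN <- fitDwell(dwellSets[[iN]]$dwells, dt, 2, kmin, nStarts = 8, seed = seed + 1)
  base6 <- c(log(f0$tau1), log(fN$tau1), log(f0$tau2), log(fN$tau2),
             stats::qlogis(pmin(pmax(c(f0$f, fN$f), 0.02), 0.98)))
  cpos0 <- concs[concs > 0]
  Kgrid <- exp(seq(log(min(cpos0) / 2), log(max(cpos0) * 2),
                   length.out = max(8, nStarts)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  start6 <- base6
  for (Kv in Kgrid) {
    opt6 <- tryCatch(
      stats::nlminb(start6, function(p6) nll(c(p6, log(Kv))),
                    control = list(iter.max = 300)),
      error = function(e) NULL)
    if (is.null(opt6) || !is.finite(opt6$objective)) next
    start6 <- opt6$par            # warm-start the next grid node
    if (is.null(best) || opt6$objective < best$objective)
      best <- list(par = c(opt6$par, log(Kv)), objective = opt6$objective)
  }
  if (is.null(best)) stop("global dwell fit failed to converge")
  polish <- tryCatch(stats::nlminb(best$par, nll,
                                   control = list(iter.max = 500)),
                     error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$objective) &&
      polish$objective <= best$objective)
    best <- polish
  ## release the shared half-saturation into three per-parameter constants,
  ## seeded from the shared-K optimum and confined to the sampled range
  par9 <- c(best$par[1:6], rep(best$par[7], 3))
  lower9 <- c(rep(-Inf, 6), rep(log(min(cpos0) / 2), 3))
  upper9 <- c(rep(Inf, 6), rep(log(max(cpos0) * 2), 3))
  best9 <- list(par = par9, objective = nll9(par9))
  opt9 <- tryCatch(stats::nlminb(par9, nll9, lower = lower9, upper = upper9,
                                 control = list(iter.max = 500)),
                   error = function(e) NULL)
  if (!is.null(opt9) && is.finite(opt9$objective) &&
      opt9$objective <= best9$objective)
    best9 <- opt9
  p <- best9$par
  K3 <- exp(p[7:9])
  names(K3) <- c("tau1", "tau2", "f")
  cpos <- cpos0
  out <- list(tau1_0 = exp(p[1]), tau1_inf = exp(p[2]),
              tau2_0 = exp(p[3]), tau2_inf = exp(p[4]),
              f_0 = stats::plogis(p[5]), f_inf = stats::plogis(p[6]),
              khalf = K3, loglik = -best9$objective,
              bracketed = all(K3 >= min(cpos) & K3 <= max(cpos)))
  out$predict <- function(conc) {
    w <- conc / (conc + K3)
    list(tau1 = isot(out$tau1_0, out$tau1_inf, w[["tau1"]]),
         tau2 = isot(out$tau2_0, out$tau2_inf, w[["tau2"]]),
         f = isot(out$f_0, out$f_inf, w[["f"]]))
  }
  out
}

#' Fit binding isotherms to apparent rate constants
#'
#' For each of the 20 transitions, fits
#' \eqn{{}^{app}k_{ij}([L]) = (k_{ij} + {}^{L}k_{ij}[L]/K_{1/2}) /
#' (1 + [L]/K_{1/2})} by weighted least squares, jointly over the arginine
#' and agmatine concentration series so that both share a single apo rate
#' constant.  This yields the 60 rate constants of the scheme (20 apo +
#' 20 per ligand branch) plus a K1/2 per transition and ligand.
#'
#' @param appk data.frame with columns \code{transition} (canonical name),
#'   \code{ligand} (\code{"arg"}, \code{"agm"} or \code{"apo"}), \code{conc}
#'   (mol/L), \code{value} (1/s) and optionally \code{weight}.
#' @param nStarts,seed multi-start control.
#' @return list with \code{rates} (a \linkS4class{RateSet}) and \code{fits}
#'   (per-transition fitted parameters).
#' @export
fitRateConstants <- function(appk, nStarts = 8, seed = 1) {
  nm <- transitionNames()
  if (is.null(appk$weight)) appk$weight <- 1
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  apo <- arg <- agm <- stats::setNames(numeric(20), nm)
  khArg <- khAgm <- stats::setNames(numeric(20), nm)
  fits <- list()
  for (tn in nm) {
    d <- appk[appk$transition == tn, , drop = FALSE]
    if (nrow(d) < 3) stop(sprintf("insufficient data for transition %s", tn))
    isArg <- d$ligand == "arg" & d$conc > 0
    isAgm <- d$ligand == "agm" & d$conc > 0
    predFn <- function(par) {
      k <- exp(par[1]); lkA <- exp(par[2]); KA <- exp(par[3])
      lkG <- exp(par[4]); KG <- exp(par[5])
      pred <- rep(k, nrow(d))
      xA <- d$conc[isArg] / KA
      pred[isArg] <- (k + lkA * xA) / (1 + xA)
      xG <- d$conc[isAgm] / KG
      pred[isAgm] <- (k + lkG * xG) / (1 + xG)
      pred
    }
    rw <- rep(1, nrow(d))               # robustness weights (IRLS)
    sse <- function(par) {
      r <- predFn(par) - d$value
      sum(rw * d$weight * r^2)
    }
    k0 <- max(mean(d$value[d$conc == 0]), 1e-4)
    if (!is.finite(k0)) k0 <- stats::median(d$value)
    kAinf <- max(mean(d$value[isArg][which.max(d$conc[isArg])]), 1e-4)
    kGinf <- max(mean(d$value[isAgm][which.max(d$conc[isAgm])]), 1e-4)
    cpos <- d$conc[d$conc > 0]
    K0 <- if (length(cpos)) exp(mean(log(cpos))) else 1e-4
    ## K1/2 outside the sampled concentration range is not identifiable (a
    ## K1/2 below the lowest tested concentration would let the isotherm fit
    ## the apo point in isolation), so it is confined to the range
    Klo <- if (length(cpos)) min(cpos) else 1e-12
    Khi <- if (length(cpos)) max(cpos) else 1
    lower <- log(c(rep(1e-8, 2), Klo, 1e-8, Klo))
    upper <- log(c(rep(1e4, 2), Khi, 1e4, Khi))
    base <- pmin(pmax(log(c(k0, kAinf, K0, kGinf, K0)), lower), upper)
    fitOnce <- function() {
      best <- NULL
      for (s in seq_len(nStarts)) {
        start <- base + stats::rnorm(5, 0, c(0.1, 0.1, 0.8, 0.1, 0.8))
        start <- pmin(pmax(start, lower), upper)
        opt <- tryCatch(stats::nlminb(start, sse, lower = lower,
                                      upper = upper),
                        error = function(e) NULL)
        if (is.null(opt) || !is.finite(opt$objective)) next
        if (is.null(best) || opt$objective < best$objective) best <- opt
      }
      best
    }
    best <- fitOnce()
    if (is.null(best)) stop(sprintf("isotherm fit failed for %s", tn))
    ## robust refinement: a single outlying condition (the slow-component
    ## estimates have ~30% per-condition scatter) must not capture the
    ## fit, so re-weight by a Huber rule on standardized residuals
    for (irls in 1:2) {
      r <- sqrt(d$weight) * (predFn(best$par) - d$value)
      s <- 1.4826 * stats::median(abs(r))
      if (!is.finite(s) || s <= 0) break
      rw <- pmin(1, 1.5 * s / pmax(abs(r), 1e-12))
      base <- best$par
      nxt <- fitOnce()
      if (!is.null(nxt)) best <- nxt
    }
    p <- exp(best$par)
    apo[tn] <- p[1]; arg[tn] <- p[2]; khArg[tn] <- p[3]
    agm[tn] <- p[4]; khAgm[tn] <- p[5]
    fits[[tn]] <- c(k = p[1], lk_arg = p[2], khalf_arg = p[3],
                    lk_agm = p[4], khalf_agm = p[5], sse = best$objective)
  }
  list(rates = RateSet(apo, arg, agm, khalf = list(arg = khArg, agm = khAgm)),
       fits = fits)
}

## 8x8 generator from 20 named apparent rates
.generator8 <- function(appk) {
  Q <- matrix(0, 8, 8)
  tp <- .transitionPairs()
  for (r in seq_len(nrow(tp)))
    Q[tp$from[r], tp$to[r]] <- appk[[tp$name[r]]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary probabilities of the eight energetic substates
#'
#' Solves for the stationary distribution of the eight-state generator built
#' from the 20 apparent rate constants of one ligand condition (the null
#' space of the transposed generator, normalized to sum to 1).
#'
#' @param appk named numeric(20) of apparent rates (1/s).
#' @return numeric(8) of probabilities P(S1)..P(S8), summing to 1.
#' @export
substateProbabilities <- function(appk) {
  Q <- .generator8(appk)
  ## connectivity check on the undirected support
  adj <- (Q > 0) | (t(Q) > 0)
  reach <- adj | diag(TRUE, 8)
  for (i in 1:3) reach <- reach | (reach %*% reach > 0)
  if (!all(reach)) stop("disconnected eight-state scheme")
  ## replace one (redundant) balance equation by the normalization and
  ## equilibrate rows so that widely different rate scales stay solvable
  A <- t(Q)
  A[8, ] <- 1
  b <- c(rep(0, 7), 1)
  sc <- apply(abs(A), 1, max)
  p <- tryCatch(solve(A / sc, b / sc), error = function(e)
    stop("stationary solve failed (disconnected or degenerate scheme)"))
  if (any(!is.finite(p)) || any(p < -1e-6))
    stop("stationary solve produced negative probabilities")
  p <- pmax(p, 0)
  p / sum(p)
}

#' Fit equilibrium constants to substate probability isotherms
#'
#' Global least-squares fit of
#' \deqn{P_i([L]) = \frac{K_{i,1} + {}^{L}K_{i,1}[L]/K_{D1}}
#'       {\sum_j K_{j,1} + \sum_j {}^{L}K_{j,1}[L]/K_{D1}}}
#' to the eight substate-probability curves of each ligand, with S1 as the
#' reference state (\eqn{K_{1,1} = {}^{L}K_{1,1} = 1}) and the apo ratios
#' \eqn{K_{i,1}} shared between ligands.  Per-state dissociation constants
#' follow from the thermodynamic cycle
#' \eqn{K_{Di} = K_{D1} K_{i,1} / {}^{L}K_{i,1}}.
#'
#' @param pdata data.frame with columns \code{state} (1..8), \code{ligand}
#'   (\code{"arg"} or \code{"agm"}), \code{conc} (mol/L; include 0) and
#'   \code{P}.
#' @param nStarts,seed multi-start control.
#' @return list of class \code{"EquilibriumSet"}: \code{K} (numeric(8),
#'   \code{K[1] == 1}), \code{LK} (8 x 2 matrix by ligand), \code{KD1}
#'   (per ligand), \code{KD} (8 x 2 matrix of per-state dissociation
#'   constants), \code{consequential} (states 6 and 7, whose KD describe
#'   external and internal binding), and \code{predict(ligand, conc)}.
#' @export
fitEquilibriumConstants <- function(pdata, nStarts = 12, seed = 1) {
  ligs <- c("arg", "agm")
  stopifnot(all(pdata$ligand %in% ligs), all(pdata$state %in% 1:8))
  ## The isotherm depends on LK_i and KD1 only through B_i = LK_i / KD1
  ## (with B_1 = 1/KD1 since the reference LK_1 = 1), so the fit is
  ## parameterized in (K_2..K_8, B_1..B_8 per ligand); per-state KD follow
  ## directly as KD_i = K_i / B_i, which keeps the consequential KDs well
  ## conditioned even when KD1 itself is weakly determined.
  sArg <- pdata$ligand == "arg"
  st <- pdata$state; cc <- pdata$conc; Pobs <- pdata$P
  ## inverse-variance weights (multinomial: var P-hat proportional to P)
  w <- 1 / pmax(Pobs, 1e-3)
  objv <- function(par) {
    K <- c(1, exp(par[1:7]))
    Ba <- exp(par[8:15])
    Bg <- exp(par[16:23])
    B <- ifelse(sArg, Ba[st], Bg[st])
    sB <- ifelse(sArg, sum(Ba), sum(Bg))
    pred <- (K[st] + B * cc) / (sum(K) + sB * cc)
    sum(w * (pred - Pobs)^2)
  }
  ## initial apo ratios from the zero-concentration rows
  apoP <- tapply(pdata$P[pdata$conc == 0], pdata$state[pdata$conc == 0], mean)
  Kinit <- rep(1, 8)
  if (length(apoP) == 8) Kinit <- as.numeric(apoP / apoP[1])
  Kinit <- pmax(Kinit, 1e-3)
  cpos <- pdata$conc[pdata$conc > 0]
  KDinit <- exp(mean(log(cpos)))
  base <- c(log(Kinit[2:8]), log(Kinit / KDinit), log(Kinit / KDinit))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nStarts)) {
    start <- base + stats::rnorm(23, 0, 0.3)
    opt <- tryCatch(stats::nlminb(start, objv, control = list(iter.max = 500)),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("equilibrium fit failed to converge")
  p <- best$par
  K <- c(1, exp(p[1:7]))
  Ba <- exp(p[8:15]); Bg <- exp(p[16:23])
  KD1 <- c(arg = 1 / Ba[1], agm = 1 / Bg[1])
  LK <- cbind(arg = Ba / Ba[1], agm = Bg / Bg[1])
  KD <- cbind(arg = K / Ba, agm = K / Bg)
  rownames(KD) <- rownames(LK) <- paste0("S", 1:8)
  out <- list(K = K, LK = LK, KD1 = KD1, KD = KD,
              consequential = c(6L, 7L), sse = best$objective)
  out$predict <- function(ligand, conc, state = 1:8) {
    x <- conc / KD1[[ligand]]
    (K[state] + LK[state, ligand] * x) / (sum(K) + sum(LK[, ligand]) * x)
  }
  class(out) <- "EquilibriumSet"
  out
}

#' Global serial-scheme dwell fit with rate-level binding isotherms
#'
#' Joint maximum-likelihood fit of one conformation's dwell data over a
#' ligand concentration series, parameterized directly by the serial-scheme
#' rates: the total exit rate \eqn{k_{out}}, the cul-de-sac entry rate
#' \eqn{k_{ab}} and return rate \eqn{k_{ba}} each follow a binding isotherm
#' \eqn{(k_0 + k_L [L]/K_{1/2})/(1 + [L]/K_{1/2})} with its own
#' half-saturation constant.  At every concentration the dwell distribution
#' is the exact two-exponential mixture implied by those rates (via the
#' closed-form eigen solution), so the model is exactly correct whenever the
#' underlying rate constants interpolate as binding isotherms — unlike
#' isotherms imposed on the mixture parameters themselves, whose
#' eigenvalue-level curves are only approximately of isotherm form.  The
#' likelihood is profiled over a shared half-saturation grid and then the
#' three constants are released, confined to the sampled concentration
#' range.
#'
#' @param dwellSets list of lists with elements \code{conc} (mol/L) and
#'   \code{dwells} (integer frames); must include the apo condition and at
#'   least 3 concentrations.
#' @param dt frame interval (s).
#' @param kmin smallest retained dwell length (frames).
#' @param nStarts nodes of the half-saturation profile grid.
#' @param seed RNG seed for the endpoint initialization.
#' @return list with the apo and saturating rates (\code{kOut0},
#'   \code{kOutInf}, \code{kAb0}, \code{kAbInf}, \code{kBa0},
#'   \code{kBaInf}), \code{khalf} (named numeric(3)), \code{loglik}, and
#'   \code{predict(conc)} returning the rates and the implied
#'   (lambda1, lambda2, f).
#' @export
globalFitSerial <- function(dwellSets, dt, kmin = 1, nStarts = 14, seed = 1) {
  concs <- vapply(dwellSets, function(s) s$conc, numeric(1))
  if (length(concs) < 3 || !any(concs == 0))
    stop("need >= 3 concentrations including the apo condition")
  tabs <- lapply(dwellSets, function(s) {
    tb <- table(as.integer(s$dwells))
    list(k = as.integer(names(tb)), n = as.numeric(tb))
  })
  iso <- function(k0, kinf, K, cc) (k0 + kinf * cc / K) / (1 + cc / K)
  mixPars <- function(kOut, kAb, kBa) {
    s <- kOut + kAb + kBa
    disc <- sqrt((kOut - kBa)^2 + kAb^2 + 2 * kAb * (kOut + kBa))
    l1 <- (s + disc) / 2
    l2 <- 2 * kOut * kBa / (s + disc)
    list(l1 = l1, l2 = l2, f = (kOut - l2) / disc)
  }
  nll9 <- function(par) {
    ko <- exp(par[1:2]); ka <- exp(par[3:4]); kb <- exp(par[5:6])
    K3 <- exp(par[7:9])
    tot <- 0
    for (i in seq_along(tabs)) {
      cc <- concs[i]
      mp <- mixPars(iso(ko[1], ko[2], K3[1], cc),
                    iso(ka[1], ka[2], K3[2], cc),
                    iso(kb[1], kb[2], K3[3], cc))
      pm <- dwellMixPmf(mp$l1, mp$l2, mp$f, dt, tabs[[i]]$k, kmin)
      tot <- tot - sum(tabs[[i]]$n * log(pmax(pm, 1e-300)))
    }
    tot
  }
  nll7 <- function(par) nll9(c(par[1:6], par[7], par[7], par[7]))
  ## endpoint initialization from per-condition fits
  i0 <- which.min(concs); iN <- which.max(concs)
  f0 <- fitDwell(dwellSets[[i0]]$dwells, dt, 2, kmin, nStarts = 8,
                 seed = seed)
  fN <- fitDwell(dwellSets[[iN]]$dwells, dt, 2, kmin, nStarts = 8,
                 seed = seed + 1)
  inv0 <- invertSerialScheme(f0$lambda1, f0$lambda2, min(f0$f, 0.995), 1)
  invN <- invertSerialScheme(fN$lambda1, fN$lambda2, min(fN$f, 0.995), 1)
  base6 <- log(pmax(c(inv0$kOut, invN$kOut, inv0$kAb, invN$kAb,
                      inv0$kBa, invN$kBa), 1e-6))
  cpos <- concs[concs > 0]
  Kgrid <- exp(seq(log(min(cpos) / 2), log(max(cpos) * 2),
                   length.out = max(8, nStarts)))
  best <- NULL
  start6 <- base6
  for (Kv in Kgrid) {
    opt6 <- tryCatch(
      stats::nlminb(start6, function(p6) nll7(c(p6, log(Kv))),
                    control = list(iter.max = 300)),
      error = function(e) NULL)
    if (is.null(opt6) || !is.finite(opt6$objective)) next
    start6 <- opt6$par
    if (is.null(best) || opt6$objective < best$objective)
      best <- list(par = c(opt6$par, log(Kv)), objective = opt6$objective)
  }
  if (is.null(best)) stop("global serial dwell fit failed to converge")
  par9 <- c(best$par[1:6], rep(best$par[7], 3))
  lower9 <- c(rep(log(1e-6), 6), rep(log(min(cpos) / 2), 3))
  upper9 <- c(rep(log(1e4), 6), rep(log(max(cpos) * 2), 3))
  best9 <- list(par = par9, objective = nll9(par9))
  opt9 <- tryCatch(stats::nlminb(par9, nll9, lower = lower9,
                                 upper = upper9,
                                 control = list(iter.max = 500)),
                   error = function(e) NULL)
  if (!is.null(opt9) && is.finite(opt9$objective) &&
      opt9$objective <= best9$objective)
    best9 <- opt9
  p <- best9$par
  K3 <- stats::setNames(exp(p[7:9]), c("kOut", "kAb", "kBa"))
  out <- list(kOut0 = exp(p[1]), kOutInf = exp(p[2]),
              kAb0 = exp(p[3]), kAbInf = exp(p[4]),
              kBa0 = exp(p[5]), kBaInf = exp(p[6]),
              khalf = K3, loglik = -best9$objective)
  out$predict <- function(conc) {
    kOut <- iso(out$kOut0, out$kOutInf, K3[["kOut"]], conc)
    kAb <- iso(out$kAb0, out$kAbInf, K3[["kAb"]], conc)
    kBa <- iso(out$kBa0, out$kBaInf, K3[["kBa"]], conc)
    mp <- mixPars(kOut, kAb, kBa)
    list(kOut = kOut, kAb = kAb, kBa = kBa,
         lambda1 = mp$l1, lambda2 = mp$l2, f = mp$f)
  }
  out
}
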