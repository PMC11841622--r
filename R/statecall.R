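## Conformational-state identification: shortest-distance (k-means) clustering
## of event orientations on the unit sphere, the 2.5-sigma resolution rule,
## false-positive merging, state/transition statistics, and least-squares
## matching of conformational to structural states.

## k-means++ seeding on rows of x
.kmeansppInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j, ] <- x[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

.clusterK <- function(x, k, nRestarts) {
  best <- NULL
  for (r in seq_len(nRestarts)) {
    init <- .kmeansppInit(x, k)
    km <- tryCatch(
      stats::kmeans(x, centers = init, iter.max = 100),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

## angular SD (degrees) of cluster members along the geodesic toward another
## cluster mean; mA, mB unit vectors, v member rows
.sigmaAlong <- function(v, mA, mB) {
  t <- mB - sum(mB * mA) * mA
  nt <- sqrt(sum(t^2))
  if (nt < 1e-12) return(NA_real_)
  t <- t / nt
  a <- atan2(v %*% t, v %*% mA)
  stats::sd(a) * 180 / pi
}

## Density-dip guard against k-means fragmentation: project both clusters'
## members onto the inter-mean geodesic; two genuine states show a density
## valley between the means, whereas fragments of a single state do not.
.pairHasDip <- function(vi, vj, mA, mB, maxValley = 0.7) {
  t <- mB - sum(mB * mA) * mA
  nt <- sqrt(sum(t^2))
  if (nt < 1e-12) return(FALSE)
  t <- t / nt
  proj <- function(v) as.numeric(atan2(v %*% t, v %*% mA)) * 180 / pi
  sep <- acos(min(1, sum(mA * mB))) * 180 / pi
  xs <- c(proj(vi), proj(vj))
  if (length(xs) < 16) return(TRUE)
  d <- stats::density(xs)
  inA <- d$x <= 0.25 * sep
  inV <- d$x > 0.3 * sep & d$x < 0.7 * sep
  inB <- d$x >= 0.75 * sep
  if (!any(inA) || !any(inV) || !any(inB)) return(TRUE)
  valley <- min(d$y[inV])
  peaks <- min(max(d$y[inA]), max(d$y[inB]))
  valley < maxValley * peaks
}

#' Cluster event orientations into conformational states
#'
#' Events are mapped to unit vectors in Cartesian coordinates (computed from
#' theta and phi with unit radius) and clustered by the shortest (chord)
#' distance with k-means, seeded by k-means++ with multiple restarts.  The
#' number of states is the largest k not exceeding \code{kMax} for which
#' every pair of cluster means is separated by at least
#' \code{resolutionFactor} times the pooled angular sigma of the pair, where
#' the pooled sigma is the mean of the two clusters' angular SDs measured
#' along the inter-mean geodesic.  The procedure is not guided by any
#' preconceived kinetic model.
#'
#' @param events event table (as from \code{\link{buildEvents}}) or a list of
#'   such tables; rows flagged \code{"degenerate"} are excluded from state
#'   means.
#' @param kMax maximum number of states to consider (default 6).
#' @param resolutionFactor resolution rule multiplier (default 2.5).
#' @param nRestarts k-means restarts (default 50).
#' @param seed RNG seed for the restarts.
#' @param minFrames events at least this long (frames) define the clusters
#'   and the resolution test; shorter events (whose orientation estimates
#'   are noisier) are then labelled by the shortest distance to the state
#'   means.  Ignored when the event table has no \code{nframes} column or
#'   too few long events.
#' @return list with \code{model} (a \linkS4class{StateModel}) and
#'   \code{labels} (state label per event row, ordered so that state means
#'   have increasing phi).
#' @export
clusterOrientations <- function(events, kMax = 6, resolutionFactor = 2.5,
                                nRestarts = 50, seed = 1, minFrames = 3) {
  if (is.list(events) && !is.data.frame(events))
    events <- do.call(rbind, events)
  ok <- events$flag %in% c("ok", "clipped") & !is.na(events$theta)
  if (sum(ok) < 1) stop("no usable events")
  vAll <- anglesToVec(events$theta[ok], events$phi[ok])
  long <- if (!is.null(events$nframes)) events$nframes[ok] >= minFrames else
    rep(TRUE, nrow(vAll))
  if (sum(long) < max(16, kMax * 4)) long <- rep(TRUE, nrow(vAll))
  v <- vAll[long, , drop = FALSE]
  n <- nrow(v)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  pick <- NULL
  for (k in seq(min(kMax, n), 1)) {
    if (k == 1) {
      m <- colMeans(v)
      m <- m / sqrt(sum(m^2))
      pick <- list(k = 1L, centers = matrix(m, 1),
                   resolvable = matrix(TRUE, 1, 1))
      break
    }
    km <- .clusterK(v, k, nRestarts)
    if (is.null(km) || length(unique(km$cluster)) < k) next
    centers <- km$centers / sqrt(rowSums(km$centers^2))
    resolv <- matrix(TRUE, k, k)
    allres <- TRUE
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sep <- acos(pmin(1, sum(centers[i, ] * centers[j, ]))) * 180 / pi
      vi <- v[km$cluster == i, , drop = FALSE]
      vj <- v[km$cluster == j, , drop = FALSE]
      si <- .sigmaAlong(vi, centers[i, ], centers[j, ])
      sj <- .sigmaAlong(vj, centers[j, ], centers[i, ])
      pooled <- mean(c(si, sj), na.rm = TRUE)
      ok_ij <- is.finite(pooled) && sep >= resolutionFactor * pooled &&
        .pairHasDip(vi, vj, centers[i, ], centers[j, ])
      resolv[i, j] <- resolv[j, i] <- ok_ij
      if (!ok_ij) allres <- FALSE
    }
    if (allres) {
      pick <- list(k = as.integer(k), centers = centers,
                   resolvable = resolv)
      break
    }
  }

  ## order states by increasing mean phi (C1 has the smallest phi by the
  ## local-frame convention), then label every event by shortest distance in
  ## the polarization measurement plane (sin(theta) cos(2 phi),
  ## sin(theta) sin(2 phi)), where the photon noise is isotropic and the
  ## arcsine folding of theta estimates near 90 degrees cannot push an event
  ## across a state boundary
  ang <- vecToAngles(pick$centers)
  ord <- order(ang$phi)
  centers <- pick$centers[ord, , drop = FALSE]
  ang <- ang[ord, , drop = FALSE]
  uOf <- function(theta, phi) {
    th <- theta * pi / 180; ph2 <- 2 * phi * pi / 180
    cbind(sin(th) * cos(ph2), sin(th) * sin(ph2))
  }
  uEv <- uOf(events$theta[ok], events$phi[ok])
  uC <- uOf(ang$theta, ang$phi)
  d2 <- vapply(seq_len(pick$k), function(s)
    rowSums((uEv - matrix(uC[s, ], nrow(uEv), 2, byrow = TRUE))^2),
    numeric(nrow(uEv)))
  lab <- max.col(-matrix(d2, nrow(uEv)))

  sigTh <- sigPh <- numeric(pick$k)
  evTheta <- events$theta[ok]; evPhi <- events$phi[ok]
  for (s in seq_len(pick$k)) {
    sel <- lab == s & long
    sigTh[s] <- if (sum(sel) > 1) stats::sd(evTheta[sel]) else 0
    sigPh[s] <- if (sum(sel) > 1) stats::sd(evPhi[sel]) else 0
  }
  model <- new("StateModel", k = pick$k,
               means = cbind(theta = ang$theta, phi = ang$phi),
               sigmaTheta = sigTh, sigmaPhi = sigPh,
               resolvable = pick$resolvable[ord, ord, drop = FALSE])
  labels <- rep(NA_integer_, nrow(events))
  labels[ok] <- lab
  list(model = model, labels = labels)
}

#' Merge consecutive same-state events
#'
#' When two consecutive events belong to the same state distribution, the
#' transition between them is considered a changepoint false positive: the
#' events are merged into a single event, intensities re-averaged over the
#' merged span, and the transition count drops accordingly.
#'
#' @param events event table.
#' @param labels state label per event (as from
#'   \code{\link{clusterOrientations}}).
#' @param delta wobble half-cone angle used to recompute orientations of
#'   merged events (degrees).
#' @param transientFrames events no longer than this many frames are treated
#'   as camera-mixed transition frames (a frame straddling a transition
#'   shows an intermediate intensity and is bracketed by two changepoints):
#'   they are absorbed into the preceding event before merging.  Set to 0 to
#'   keep all events.
#' @return event table with a \code{state} column and consecutive
#'   duplicates merged (within each trace).
#' @export
mergeSameState <- function(events, labels, delta = 0, transientFrames = 1) {
  stopifnot(nrow(events) == length(labels))
  if (transientFrames > 0) {
    for (tr in unique(events$trace)) {
      ix <- which(events$trace == tr)
      if (length(ix) < 3) next
      for (j in ix[-c(1, length(ix))]) {
        if (events$nframes[j] <= transientFrames &&
            !is.na(labels[j - 1]) && !is.na(labels[j + 1]) &&
            !identical(labels[j], labels[j - 1]) &&
            !identical(labels[j], labels[j + 1]))
          labels[j] <- labels[j - 1]
      }
    }
  }
  events$state <- labels
  out <- NULL
  for (tr in unique(events$trace)) {
    ev <- events[events$trace == tr, , drop = FALSE]
    lab <- ev$state
    same <- function(a, b) !is.na(a) & !is.na(b) & a == b
    grp <- cumsum(c(TRUE, !same(lab[-1], lab[-length(lab)])))
    merged <- do.call(rbind, lapply(split(seq_len(nrow(ev)), grp), function(ix) {
      if (length(ix) == 1) return(ev[ix, , drop = FALSE])
      w <- ev$nframes[ix]
      row <- ev[ix[1], , drop = FALSE]
      row$end <- ev$end[ix[length(ix)]]
      row$nframes <- sum(w)
      for (ch in c("I0", "I45", "I90", "I135"))
        row[[ch]] <- sum(ev[[ch]][ix] * w) / sum(w)
      ang <- estimateAngles(row$I0, row$I45, row$I90, row$I135,
                            Calibration(delta = delta))
      row$theta <- ang$theta; row$phi <- ang$phi; row$flag <- ang$flag
      row
    }))
    out <- rbind(out, merged)
  }
  rownames(out) <- NULL
  out
}

#' State occupancies and state-to-state transition statistics
#'
#' Occupancy is the time-weighted fraction of observation time spent in each
#' state; transition probabilities are exit-conditional,
#' \eqn{p_{ij} = n_{ij} / \sum_j n_{ij}} over observed exits (the diagonal is
#' excluded by prior merging of consecutive same-state events).  Transitions
#' are only counted between consecutive events of the same trace.
#'
#' @param events merged, labelled event table (see
#'   \code{\link{mergeSameState}}).
#' @param k number of states (default: max label).
#' @return list of class \code{"TransitionStats"}: \code{occupancy}
#'   (numeric(k), sums to 1), \code{n} (k x k transition counts),
#'   \code{p} (k x k exit-conditional probabilities, zero diagonal),
#'   \code{undefined} (states with no observed exits).
#' @export
stateStatistics <- function(events, k = max(events$state, na.rm = TRUE)) {
  occ <- numeric(k)
  n <- matrix(0, k, k)
  for (tr in unique(events$trace)) {
    ev <- events[events$trace == tr & !is.na(events$state), , drop = FALSE]
    if (!nrow(ev)) next
    for (s in seq_len(k))
      occ[s] <- occ[s] + sum(ev$nframes[ev$state == s])
    if (nrow(ev) > 1) {
      from <- ev$state[-nrow(ev)]
      to <- ev$state[-1]
      for (i in seq_along(from))
        n[from[i], to[i]] <- n[from[i], to[i]] + 1
    }
  }
  occ <- occ / sum(occ)
  rs <- rowSums(n)
  p <- n / ifelse(rs > 0, rs, 1)
  p[rs == 0, ] <- NA_real_
  structure(list(occupancy = occ, n = n, p = p,
                 undefined = which(rs == 0)),
            class = "TransitionStats")
}

.permutations4 <- function() {
  out <- matrix(NA_integer_, 24, 4)
  r <- 1
  for (a in 1:4) for (b in setdiff(1:4, a)) for (d in setdiff(1:4, c(a, b))) {
    out[r, ] <- c(a, b, d, setdiff(1:4, c(a, b, d)))
    r <- r + 1
  }
  out
}

#' Match conformational states to structural states
#'
#' Evaluates all 24 pairings between the four conformational-state mean
#' orientations and the four structural-state orientations.  For each
#' permutation the combined least squares \eqn{LS_e} is the sum of squared
#' chord distances between paired unit vectors; the best pairing maximizes
#' \eqn{1/LS_e}.
#'
#' @param confMeans 4 x 2 matrix of conformational-state means
#'   (theta, phi in degrees), rows C1..C4.
#' @param structMeans 4 x 2 matrix of structural-state orientations,
#'   rows in a fixed order (e.g. Ex, Eo, Io, Ix).
#' @param structNames optional names for the structural states.
#' @return list with \code{best} (permutation: structural index for each
#'   conformational state), \code{assignment} (named character vector when
#'   \code{structNames} given), \code{lse} (numeric(24), one per
#'   permutation) and \code{permutations} (24 x 4 matrix).
#' @export
matchStructuralStates <- function(confMeans, structMeans,
                                  structNames = NULL) {
  stopifnot(all(dim(confMeans) == c(4, 2)), all(dim(structMeans) == c(4, 2)))
  vc <- anglesToVec(confMeans[, 1], confMeans[, 2])
  vs <- anglesToVec(structMeans[, 1], structMeans[, 2])
  ## dipoles are axes: chord distance up to the sign of either vector
  chord2 <- function(a, b) min(sum((a - b)^2), sum((a + b)^2))
  perms <- .permutations4()
  lse <- vapply(seq_len(nrow(perms)), function(r)
    sum(vapply(1:4, function(i) chord2(vc[i, ], vs[perms[r, i], ]),
               numeric(1))), numeric(1))
  best <- perms[which.min(lse), ]
  assignment <- if (!is.null(structNames))
    stats::setNames(structNames[best], paste0("C", 1:4)) else NULL
  list(best = best, assignment = assignment, lse = lse, permutations = perms)
}
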