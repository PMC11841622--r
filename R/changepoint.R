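## Changepoint detection on four-channel photon-count traces by recursive
## Poisson log-maximum-likelihood-ratio testing, with Monte-Carlo-calibrated
## thresholds, event construction, and particle-level quality control.

.thrCache <- new.env(parent = emptyenv())

.xlogy <- function(a, b) ifelse(a > 0, a * log(b), 0)

## LLR of a single rate change at every candidate split of a segment,
## summed over the four channels.  counts: k x 4; returns length k-1 vector
## (split s = boundary after row s).
.llrProfile <- function(counts) {
  k <- nrow(counts)
  if (k < 2) return(numeric(0))
  s <- seq_len(k - 1)
  total <- 0
  for (ch in 1:4) {
    cs <- cumsum(counts[, ch])
    N <- cs[k]
    m <- cs[s]
    t0 <- if (N > 0) N * log(N / k) else 0
    total <- total + .xlogy(m, m / s) + .xlogy(N - m, (N - m) / (k - s)) - t0
  }
  total
}

#' Poisson log-likelihood ratio for a rate change at a given split
#'
#' For each polarization channel the log maximum-likelihood ratio of the
#' two-rate versus one-rate model is
#' \eqn{LLR = m \ln(m/\tau) + (N - m)\ln((N - m)/(T - \tau)) - N \ln(N/T)},
#' where \eqn{m} is the photon count before the split, \eqn{N} the total
#' count, \eqn{\tau} the duration before the split and \eqn{T} the total
#' duration (terms with zero counts contribute 0; the frame interval cancels).
#' The returned value is the sum over the four channels.
#'
#' @param counts k x 4 matrix of non-negative photon counts.
#' @param split frame index in 1..(k-1); the split lies after row
#'   \code{split}.
#' @return the summed log likelihood ratio (numeric scalar).
#' @export
segmentLLR <- function(counts, split) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (split < 1 || split >= k) stop("split out of range")
  .llrProfile(counts)[split]
}

#' Monte-Carlo calibration of the changepoint detection threshold
#'
#' Simulates \code{nNull} transition-free Poisson traces at the given
#' per-channel rates and returns the \code{confidence} quantile of the
#' maximum-over-splits LLR, i.e. the threshold above which a detected split
#' in a trace of this length is accepted at the requested confidence.
#'
#' @param nFrames trace length in frames.
#' @param rate expected photons/frame: either a single total rate (split
#'   evenly over the four channels) or a length-4 vector of per-channel rates.
#' @param confidence detection confidence in (0.5, 1); default 0.95.
#' @param nNull number of simulated null traces (>= 100).
#' @param seed RNG seed; the threshold is deterministic given the seed.
#' @return numeric threshold (LLR units).
#' @export
calibrateThreshold <- function(nFrames, rate, confidence = 0.95,
                               nNull = 1000, seed = 1) {
  if (confidence <= 0.5 || confidence >= 1)
    stop("confidence must lie in (0.5, 1)")
  if (nNull < 100) stop("nNull must be at least 100")
  rates <- if (length(rate) == 4) rate else rep(rate / 4, 4)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  maxllr <- vapply(seq_len(nNull), function(i) {
    counts <- matrix(stats::rpois(nFrames * 4L, rep(rates, each = nFrames)),
                     nFrames, 4)
    max(.llrProfile(counts))
  }, numeric(1))
  as.numeric(stats::quantile(maxllr, confidence, type = 7))
}

## Threshold as a function of segment length: calibrated on a geometric grid
## of lengths and interpolated linearly in log length.  Cached per
## (rate, confidence, nNull, seed).
.thresholdFun <- function(nFrames, rates, confidence, nNull, seed) {
  nCap <- 2^max(2, ceiling(log2(nFrames)))   # share cache across lengths
  key <- paste(paste(signif(rates, 2), collapse = "_"),
               confidence, nNull, seed, nCap, sep = "|")
  if (!is.null(.thrCache[[key]])) return(.thrCache[[key]])
  lens <- sort(unique(pmin(nCap, c(2^(2:14)))))
  lens <- lens[lens >= 2]
  thr <- vapply(seq_along(lens), function(i)
    calibrateThreshold(lens[i], rates, confidence, nNull, seed + i),
    numeric(1))
  ## multiple testing grows with length, enforce monotonicity for stability
  thr <- cummax(thr)
  fn <- if (length(lens) == 1) {
    function(len) thr[1]
  } else {
    function(len) stats::approx(log(lens), thr, xout = log(pmax(2, len)),
                                rule = 2)$y
  }
  .thrCache[[key]] <- fn
  fn
}

#' Detect conformational transition points in a polarized intensity trace
#'
#' Recursive bisection search: the maximum-LLR split of the whole trace is
#' tested against the Monte-Carlo-calibrated threshold for its length; if
#' accepted, the search recurses on both sides until no further transition is
#' found.  A refinement pass then re-locates every changepoint within the
#' region demarcated by its neighbours (dropping it if it falls below
#' threshold), and a false-negative pass re-tests every inter-changepoint
#' segment; the two passes iterate to convergence (bounded by
#' \code{maxIter}).
#'
#' @param trace a \linkS4class{PolarizedTrace}.
#' @param confidence detection confidence (default 0.95).
#' @param nNull null traces per threshold calibration.
#' @param seed seed for the threshold calibration.
#' @param maxIter maximum refinement iterations.
#' @return list of class \code{"ChangePointResult"} with elements
#'   \code{changepoints} (0-based frame indices at which a new event starts,
#'   strictly increasing), \code{llrRatio} (LLR over threshold, >= 1 for all
#'   retained points) and \code{confidence}.
#' @export
detectChangepoints <- function(trace, confidence = 0.95, nNull = 500,
                               seed = 1, maxIter = 10) {
  counts <- traceCounts(trace)
  n <- nrow(counts)
  if (n < 2) stop("trace shorter than 2 frames")
  ## the null max-LLR distribution depends on the total photon rate but only
  ## weakly on how it is split across channels; calibrating on an even split
  ## of the (coarsely bucketed) total lets thresholds be cached across traces
  total <- max(signif(sum(colMeans(counts)), 1), 4e-3)
  rates <- rep(total / 4, 4)
  thr <- .thresholdFun(n, rates, confidence, nNull, seed)

  bestSplit <- function(a, b) {
    prof <- .llrProfile(counts[a:b, , drop = FALSE])
    if (!length(prof)) return(c(NA_real_, -Inf))
    i <- which.max(prof)           # earliest frame on ties (which.max)
    c(a + i - 1, prof[i])          # t: last frame of the left-hand event
  }

  ## initial recursive scan
  cps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- seg[1]; b <- seg[2]
    if (b - a + 1 < 2) next
    bs <- bestSplit(a, b)
    if (is.finite(bs[2]) && bs[2] >= thr(b - a + 1)) {
      t <- as.integer(bs[1])
      cps <- c(cps, t)
      stack <- c(stack, list(c(a, t)), list(c(t + 1L, b)))
    }
  }
  cps <- sort(unique(cps))

  ## refinement and false-negative passes
  for (iter in seq_len(maxIter)) {
    changed <- FALSE
    ## refine each point within (t_{i-1}, t_{i+1}]
    if (length(cps)) {
      newcps <- integer(0)
      bounds <- c(0L, cps, n)
      for (i in seq_along(cps)) {
        a <- bounds[i] + 1L
        b <- bounds[i + 2L]
        bs <- bestSplit(a, b)
        if (is.finite(bs[2]) && bs[2] >= thr(b - a + 1)) {
          t <- as.integer(bs[1])
          newcps <- c(newcps, t)
          if (t != cps[i]) changed <- TRUE
        } else changed <- TRUE     # dropped a sub-threshold point
      }
      cps <- sort(unique(newcps))
    }
    ## false negatives: re-test every current segment
    bounds <- c(0L, cps, n)
    added <- integer(0)
    for (i in seq_len(length(bounds) - 1L)) {
      a <- bounds[i] + 1L
      b <- bounds[i + 1L]
      if (b - a + 1 < 2) next
      bs <- bestSplit(a, b)
      if (is.finite(bs[2]) && bs[2] >= thr(b - a + 1))
        added <- c(added, as.integer(bs[1]))
    }
    if (length(added)) {
      cps <- sort(unique(c(cps, added)))
      changed <- TRUE
    }
    if (!changed) break
  }

  llr <- vapply(seq_along(cps), function(i) {
    bounds <- c(0L, cps, n)
    a <- bounds[i] + 1L; b <- bounds[i + 2L]
    segmentLLR(counts[a:b, , drop = FALSE], cps[i] - a + 1L) /
      thr(b - a + 1)
  }, numeric(1))

  structure(list(changepoints = as.integer(cps), llrRatio = llr,
                 confidence = confidence),
            class = "ChangePointResult")
}

#' Build the event table delimited by detected changepoints
#'
#' One event per inter-changepoint segment.  Intensities are averaged over
#' the event's frames (averaging markedly increases the SNR of the
#' orientation estimate), gain/background-corrected, and inverted to an
#' orientation.  The \code{omega} and \code{state} columns are filled after
#' state assignment.
#'
#' @param trace a \linkS4class{PolarizedTrace}.
#' @param cps a \code{"ChangePointResult"} from
#'   \code{\link{detectChangepoints}} (or NULL for a single spanning event).
#' @param traceId identifier stored in the \code{trace} column.
#' @return data.frame (one row per event) with columns \code{trace},
#'   \code{start}, \code{end} (0-based, half-open), \code{nframes},
#'   \code{I0}, \code{I45}, \code{I90}, \code{I135} (corrected means),
#'   \code{theta}, \code{phi}, \code{flag}, \code{omega}, \code{state}.
#' @export
buildEvents <- function(trace, cps = NULL, traceId = 1L) {
  counts <- traceCounts(trace)
  n <- nrow(counts)
  cp <- if (is.null(cps)) integer(0) else cps$changepoints
  start <- c(0L, cp)
  end <- c(cp, n)
  cal <- calibration(trace)
  g <- cal@gains; b <- cal@backgrounds
  means <- t(vapply(seq_along(start), function(i) {
    seg <- counts[(start[i] + 1L):end[i], , drop = FALSE]
    (colMeans(seg) - b) / g
  }, numeric(4)))
  colnames(means) <- c("I0", "I45", "I90", "I135")
  ## background-only events (e.g. after the bleach) have no orientation
  lit <- rowSums(means) > 0
  ang <- data.frame(theta = rep(NA_real_, nrow(means)),
                    phi = NA_real_, flag = "dark", stringsAsFactors = FALSE)
  if (any(lit))
    ang[lit, ] <- estimateAngles(means[lit, 1], means[lit, 2],
                                 means[lit, 3], means[lit, 4],
                                 Calibration(delta = cal@delta))
  data.frame(trace = traceId, start = start, end = end,
             nframes = end - start,
             means, theta = ang$theta, phi = ang$phi, flag = ang$flag,
             omega = NA_real_, state = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Signal-to-noise ratio of a trace
#'
#' SNR is defined as (mean total signal - background) / SD of the total
#' intensity, computed over the pre-bleach portion of the trace.
#'
#' @param trace a \linkS4class{PolarizedTrace}.
#' @param bleachFrame 0-based frame at which the fluorophore bleaches
#'   (NA if no bleach within the trace).
#' @return numeric SNR.
#' @export
traceSNR <- function(trace, bleachFrame = NA) {
  tot <- rowSums(traceCounts(trace))
  if (!is.na(bleachFrame) && bleachFrame >= 2)
    tot <- tot[seq_len(bleachFrame)]
  bg <- sum(calibration(trace)@backgrounds)
  (mean(tot) - bg) / stats::sd(tot)
}

## Classify bleaching behaviour from the event-level total intensities.
## A bleach is a concurrent drop of all channels to background; intermediate
## sustained levels between the last full-signal event and the terminal
## background run count as extra bleach steps (multi-fluorophore particles).
.bleachAnalysis <- function(trace, events) {
  counts <- traceCounts(trace)
  bg <- sum(calibration(trace)@backgrounds)
  tot <- vapply(seq_len(nrow(events)), function(i)
    mean(rowSums(counts[(events$start[i] + 1L):events$end[i], , drop = FALSE])),
    numeric(1))
  long <- events$nframes >= 3
  peak <- if (any(long)) max(tot[long]) else max(tot)
  if (peak - bg <= 0)
    return(list(steps = 0L, bleachFrame = NA_integer_))
  rel <- (tot - bg) / (peak - bg)
  lev <- ifelse(rel < 0.2, "bg", ifelse(rel > 0.7, "full", "mid"))
  ne <- length(lev)
  if (lev[ne] != "bg")
    return(list(steps = 0L, bleachFrame = NA_integer_))
  ## trailing background run
  i <- ne
  while (i > 1 && lev[i - 1] == "bg") i <- i - 1
  bleachFrame <- events$start[i]
  lastFull <- max(c(0L, which(lev[seq_len(i - 1)] == "full")))
  ## only sustained intermediate levels count as extra bleach steps;
  ## 1-2-frame slivers are camera-mixed transition frames, not levels
  nMid <- if (lastFull + 1 <= i - 1)
    sum(lev[(lastFull + 1):(i - 1)] == "mid" &
          events$nframes[(lastFull + 1):(i - 1)] >= 3) else 0L
  list(steps = 1L + as.integer(nMid), bleachFrame = bleachFrame)
}

#' Particle-level quality-control filter
#'
#' Applies the standard single-molecule QC rules: a particle is kept only if
#' it shows at least \code{minEvents} dwell events (required for reliable
#' state identification), an SNR above \code{minSnr} (required for the
#' minimum angle resolution), and no more than \code{maxBleachSteps}
#' photobleaching steps (multi-step bleaching indicates more than one
#' fluorophore).
#'
#' @param traces list of \linkS4class{PolarizedTrace} objects.
#' @param minEvents minimum number of pre-bleach events (default 15).
#' @param minSnr minimum SNR (default 5, exclusive).
#' @param maxBleachSteps maximum number of bleach steps (default 1).
#' @param confidence,nNull,seed forwarded to
#'   \code{\link{detectChangepoints}}.
#' @param analyses optional list of pre-computed per-trace analyses (elements
#'   \code{cps}, \code{events}) to avoid re-running detection.
#' @return list with \code{kept}: per-trace analysis results (trace index,
#'   changepoints, events truncated at the bleach, SNR), \code{keptIdx}, and
#'   \code{rejected}: data.frame of indices and reasons.
#' @export
filterParticles <- function(traces, minEvents = 15, minSnr = 5,
                            maxBleachSteps = 1, confidence = 0.95,
                            nNull = 500, seed = 1, analyses = NULL) {
  kept <- list(); keptIdx <- integer(0)
  rej <- data.frame(index = integer(0), reason = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (is.null(analyses)) {
      cps <- detectChangepoints(tr, confidence = confidence, nNull = nNull,
                                seed = seed)
      ev <- buildEvents(tr, cps, traceId = i)
    } else {
      cps <- analyses[[i]]$cps
      ev <- analyses[[i]]$events
    }
    bl <- .bleachAnalysis(tr, ev)
    if (bl$steps > maxBleachSteps) {
      rej <- rbind(rej, data.frame(index = i, reason = "multiple bleach steps"))
      next
    }
    snr <- traceSNR(tr, bl$bleachFrame)
    if (!is.finite(snr) || snr <= minSnr) {
      rej <- rbind(rej, data.frame(index = i, reason = "low SNR"))
      next
    }
    evPre <- if (!is.na(bl$bleachFrame))
      ev[ev$end <= bl$bleachFrame, , drop = FALSE] else ev
    if (nrow(evPre) < minEvents) {
      rej <- rbind(rej, data.frame(index = i, reason = "too few events"))
      next
    }
    keptIdx <- c(keptIdx, i)
    kept[[length(kept) + 1L]] <- list(index = i, cps = cps, events = evPre,
                                      snr = snr, bleachFrame = bl$bleachFrame)
  }
  list(kept = kept, keptIdx = keptIdx, rejected = rej)
}
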