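## Shared test fixtures, all generated in code.

## Poisson four-channel trace with piecewise-constant per-channel rates.
## rates: list of per-segment length-4 rate vectors; lens: segment lengths.
stepTrace <- function(rates, lens, seed = 1, frameInterval = 0.010,
                      calibration = Calibration()) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  counts <- do.call(rbind, lapply(seq_along(lens), function(i)
    matrix(rpois(lens[i] * 4L, rep(rates[[i]], each = lens[i])),
           lens[i], 4)))
  PolarizedTrace(counts, frameInterval = frameInterval,
                 calibration = calibration)
}

## channel rate vectors for two well-separated orientations at a given
## total signal (plus background), with delta = 0
channelRates <- function(theta, phi, total, background = 0) {
  as.numeric(forwardIntensities(theta, phi, 0, total)) + background
}

## camera-discretized dwells: exponential dwell with uniform frame phase
quantizedDwells <- function(n, lam, dt, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  floor((runif(n, 0, dt) + rexp(n, lam)) / dt) + 1L
}

quantizedMixDwells <- function(n, lam1, lam2, f, dt, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x <- ifelse(runif(n) < f, rexp(n, lam1), rexp(n, lam2))
  floor((runif(n, 0, dt) + x) / dt) + 1L
}

## minimal event table from angles
eventsFromAngles <- function(theta, phi, nframes = 50, trace = 1L) {
  n <- length(theta)
  I <- forwardIntensities(theta, phi, 0, 1000)
  data.frame(trace = trace, start = seq_len(n) - 1L, end = seq_len(n),
             nframes = nframes,
             I0 = I[, 1], I45 = I[, 2], I90 = I[, 3], I135 = I[, 4],
             theta = theta, phi = phi, flag = "ok",
             omega = NA_real_, state = NA_integer_,
             stringsAsFactors = FALSE)
}

## a rigid 3D rotation matrix from three angles (independent of the package)
rotationMatrix <- function(a, b, c) {
  Rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3,
               byrow = TRUE)
  Rx %*% Ry %*% Rz
}

## orientations printed for the four structural / conformational states
crystalAngles <- cbind(theta = c(93.8, 83.6, 71.7, 95.3),
                       phi = c(-1.89, 20.9, 27.5, 38.7))
polarizationAngles <- cbind(theta = c(90, 88.7, 77.4, 90),
                            phi = c(0, 17.9, 27.2, 40.5))
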