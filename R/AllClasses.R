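#' @import methods
NULL

## canonical transition names of the 8-state scheme: 12 directed
## inter-conformational rates among S1-S4 plus 8 serial rates k_i,i+4 / k_i+4,i
.confPairs <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                    c(2L, 3L), c(2L, 4L), c(3L, 4L))
.serialPairs <- cbind(1:4, 5:8)

#' Canonical transition names of the eight-state scheme
#'
#' Twenty directed transitions: the 12 inter-conformational transitions among
#' the communicating substates S1--S4 and the 8 serial transitions between each
#' communicating substate and its occluded cul-de-sac partner (S1-S5, S2-S6,
#' S3-S7, S4-S8).  Names are of the form \code{"k_1_2"}.
#'
#' @return Character vector of length 20.
#' @export
transitionNames <- function() {
  pairs <- rbind(.confPairs, .confPairs[, 2:1],
                 .serialPairs, .serialPairs[, 2:1])
  paste0("k_", pairs[, 1], "_", pairs[, 2])
}

.transitionPairs <- function() {
  nm <- transitionNames()
  from <- as.integer(sub("^k_(\\d+)_(\\d+)$", "\\1", nm))
  to <- as.integer(sub("^k_(\\d+)_(\\d+)$", "\\2", nm))
  data.frame(name = nm, from = from, to = to, stringsAsFactors = FALSE)
}

## conformation of substate s (S5-S8 are the cul-de-sac partners of S1-S4)
.confOf <- function(s) ifelse(s > 4L, s - 4L, s)

#' Calibration of a polarization microscope recording
#'
#' Holds the wobble half-cone angle \eqn{\delta} of the fluorophore (degrees),
#' per-channel multiplicative gains and per-channel additive backgrounds
#' (counts/frame) for the four polarization channels (0, 45, 90, 135 degrees).
#'
#' @slot delta numeric(1), wobble half-cone angle in degrees, in [0, 54.7).
#' @slot gains numeric(4), multiplicative channel gains, all > 0.
#' @slot backgrounds numeric(4), additive background counts per frame.
#' @export
setClass("Calibration", representation(
  delta = "numeric", gains = "numeric", backgrounds = "numeric"
))

setValidity("Calibration", function(object) {
  msg <- NULL
  if (length(object@delta) != 1 || object@delta < 0 || object@delta >= 54.7)
    msg <- c(msg, "delta must be a single angle in [0, 54.7) degrees")
  if (length(object@gains) != 4 || any(object@gains <= 0))
    msg <- c(msg, "gains must be four positive factors")
  if (length(object@backgrounds) != 4 || any(object@backgrounds < 0))
    msg <- c(msg, "backgrounds must be four non-negative counts/frame")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Calibration object
#'
#' @param delta wobble half-cone angle in degrees.
#' @param gains four per-channel multiplicative gains.
#' @param backgrounds four per-channel additive backgrounds (counts/frame).
#' @return A \linkS4class{Calibration} object.
#' @export
Calibration <- function(delta = 0, gains = rep(1, 4), backgrounds = rep(0, 4)) {
  new("Calibration", delta = as.numeric(delta), gains = as.numeric(gains),
      backgrounds = as.numeric(backgrounds))
}

#' Four-channel polarized photon-count trace
#'
#' Per-frame photon counts in the four polarization channels for one particle
#' under one ligand condition, together with the calibration needed to invert
#' intensities to dipole orientations.
#'
#' @slot counts integer matrix, frames x 4 (columns I0, I45, I90, I135).
#' @slot frameInterval numeric(1), seconds per camera frame.
#' @slot calibration a \linkS4class{Calibration}.
#' @slot condition list describing the ligand condition
#'   (\code{species}, \code{conc} in mol/L, \code{pH}).
#' @slot meta list of free-form metadata (seed, truth reference, ...).
#' @export
setClass("PolarizedTrace", representation(
  counts = "matrix", frameInterval = "numeric",
  calibration = "Calibration", condition = "list", meta = "list"
))

setValidity("PolarizedTrace", function(object) {
  msg <- NULL
  if (ncol(object@counts) != 4)
    msg <- c(msg, "counts must have 4 channels")
  if (nrow(object@counts) < 2)
    msg <- c(msg, "trace must have at least 2 frames")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a positive scalar (seconds)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PolarizedTrace
#'
#' @param counts frames x 4 non-negative count matrix (I0, I45, I90, I135).
#' @param frameInterval frame duration in seconds.
#' @param calibration a \linkS4class{Calibration}.
#' @param condition list with elements \code{species}, \code{conc}, \code{pH}.
#' @param meta optional metadata list.
#' @return A \linkS4class{PolarizedTrace}.
#' @export
PolarizedTrace <- function(counts, frameInterval = 0.010,
                           calibration = Calibration(),
                           condition = list(species = "apo", conc = 0, pH = 5),
                           meta = list()) {
  counts <- as.matrix(counts)
  colnames(counts) <- c("I0", "I45", "I90", "I135")
  new("PolarizedTrace", counts = counts, frameInterval = frameInterval,
      calibration = calibration, condition = condition, meta = meta)
}

#' Rate constants of the 24-state conformational-kinetic scheme
#'
#' Holds the 20 rate constants of the apo branch and of each ligand-bound
#' branch (60 in total), plus the half-saturation constants K1/2 that couple
#' apparent rates to the ligand concentration.
#'
#' @slot apo named numeric(20), apo rate constants (1/s).
#' @slot arg named numeric(20), arginine-bound branch rate constants (1/s).
#' @slot agm named numeric(20), agmatine-bound branch rate constants (1/s).
#' @slot khalf list with elements \code{arg} and \code{agm}, each a named
#'   numeric(20) of per-transition half-saturation constants (mol/L).
#' @export
setClass("RateSet", representation(
  apo = "numeric", arg = "numeric", agm = "numeric", khalf = "list"
))

setValidity("RateSet", function(object) {
  nm <- transitionNames()
  msg <- NULL
  for (b in c("apo", "arg", "agm")) {
    v <- slot(object, b)
    if (!identical(sort(names(v)), sort(nm)))
      msg <- c(msg, sprintf("%s must carry the 20 canonical transition names", b))
    else if (any(v <= 0))
      msg <- c(msg, sprintf("%s rates must be positive", b))
  }
  for (l in c("arg", "agm")) {
    v <- object@khalf[[l]]
    if (is.null(v) || any(v <= 0))
      msg <- c(msg, sprintf("khalf$%s must be positive", l))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a RateSet
#'
#' @param apo,arg,agm named numeric(20) rate constants (1/s), names as in
#'   \code{\link{transitionNames}}.
#' @param khalf list with named numeric(20) elements \code{arg} and \code{agm}
#'   (mol/L).
#' @return A \linkS4class{RateSet}.
#' @export
RateSet <- function(apo, arg, agm, khalf) {
  nm <- transitionNames()
  new("RateSet", apo = apo[nm], arg = arg[nm], agm = agm[nm],
      khalf = list(arg = khalf$arg[nm], agm = khalf$agm[nm]))
}

#' Ground truth for the synthetic-data generator
#'
#' A fully specified conformational-kinetic model: rate constants, the four
#' physically consequential dissociation constants (external binding at the
#' outward-facing open substate, internal binding at the inward-facing open
#' substate, for each ligand), the four dipole orientations, and the wobble
#' half-cone angle.
#'
#' @slot rates a \linkS4class{RateSet}.
#' @slot kd named numeric(4): \code{arg_ext}, \code{arg_int}, \code{agm_ext},
#'   \code{agm_int}, dissociation constants in mol/L.
#' @slot orientations 4 x 2 matrix of (theta, phi) in degrees, rows C1..C4.
#' @slot delta numeric(1), wobble half-cone angle in degrees.
#' @slot seed integer used to generate the truth.
#' @slot extra list of generator internals (per-state equilibrium ratios and
#'   per-state KD used to build a thermodynamically consistent truth).
#' @export
setClass("GroundTruth", representation(
  rates = "RateSet", kd = "numeric", orientations = "matrix",
  delta = "numeric", seed = "integer", extra = "list"
))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  if (!identical(sort(names(object@kd)),
                 sort(c("arg_ext", "arg_int", "agm_ext", "agm_int"))))
    msg <- c(msg, "kd must be named arg_ext, arg_int, agm_ext, agm_int")
  else if (any(object@kd <= 0))
    msg <- c(msg, "kd values must be positive (mol/L)")
  o <- object@orientations
  if (!all(dim(o) == c(4, 2)))
    msg <- c(msg, "orientations must be 4 x 2 (theta, phi in degrees)")
  else {
    if (any(o[, 1] < 0 | o[, 1] > 90))
      msg <- c(msg, "theta must lie in [0, 90] degrees")
    if (any(o[, 2] <= -90 | o[, 2] > 90))
      msg <- c(msg, "phi must lie in (-90, 90] degrees")
  }
  if (object@delta < 0 || object@delta >= 54.7)
    msg <- c(msg, "delta must lie in [0, 54.7) degrees")
  if (is.null(msg)) TRUE else msg
})

#' State model from clustering orientations on the unit sphere
#'
#' @slot k integer, number of resolvable conformational states (1..6).
#' @slot means k x 2 matrix of state mean orientations (theta, phi, degrees).
#' @slot sigmaTheta,sigmaPhi numeric(k), per-state angular SDs (degrees).
#' @slot resolvable logical k x k matrix: pairwise separation exceeds the
#'   resolution rule (2.5 sigma by default).
#' @export
setClass("StateModel", representation(
  k = "integer", means = "matrix", sigmaTheta = "numeric",
  sigmaPhi = "numeric", resolvable = "matrix"
))

setValidity("StateModel", function(object) {
  msg <- NULL
  if (object@k < 1L || object@k > 6L)
    msg <- c(msg, "k must lie in [1, 6]")
  if (nrow(object@means) != object@k)
    msg <- c(msg, "means must have k rows")
  if (is.null(msg)) TRUE else msg
})

#' 24-state transport model
#'
#' Assembles the apo branch and up to two ligand-species branches into a
#' 24-state scheme with second-order binding edges at the two open substates:
#' the externally facing one exchanges ligand with the external compartment,
#' the internally facing one with the internal compartment.
#'
#' @slot apo named numeric(20), apo branch rate constants (1/s).
#' @slot species list of species parameter sets, each a list with elements
#'   \code{name}, \code{rates} (named numeric(20), 1/s), \code{kdExt} and
#'   \code{kdInt} (mol/L).
#' @slot kon numeric(1), association rate constant (1/M/s).
#' @slot sidedness integer, 1 or 2.  In configuration 1 the cul-de-sac open
#'   substate S6 faces the external solution and S7 the internal solution;
#'   configuration 2 swaps them.
#' @export
setClass("Model24", representation(
  apo = "numeric", species = "list", kon = "numeric", sidedness = "integer"
))

setValidity("Model24", function(object) {
  msg <- NULL
  nm <- transitionNames()
  if (!identical(sort(names(object@apo)), sort(nm)) || any(object@apo < 0))
    msg <- c(msg, "apo must carry the 20 canonical non-negative rates")
  if (length(object@species) < 1 || length(object@species) > 2)
    msg <- c(msg, "one or two ligand species are supported (8 + 8x2 = 24 states)")
  for (sp in object@species) {
    if (!all(c("name", "rates", "kdExt", "kdInt") %in% names(sp)))
      msg <- c(msg, "each species needs name, rates, kdExt, kdInt")
    else if (sp$kdExt <= 0 || sp$kdInt <= 0)
      msg <- c(msg, "species KD values must be positive")
  }
  if (object@kon <= 0)
    msg <- c(msg, "kon must be positive")
  if (!object@sidedness %in% c(1L, 2L))
    msg <- c(msg, "sidedness must be 1 or 2")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Model24
#'
#' @param apo named numeric(20) apo rate constants (1/s).
#' @param species list of species parameter sets (see \linkS4class{Model24}).
#' @param kon association rate constant, default the near diffusion-limited
#'   1e7 /M/s.
#' @param sidedness 1 or 2 (which open substate faces the external solution).
#' @return A \linkS4class{Model24}.
#' @export
Model24 <- function(apo, species, kon = 1e7, sidedness = 1L) {
  if (!is.null(names(species)) && all(c("name", "rates") %in% names(species)))
    species <- list(species)
  new("Model24", apo = apo[transitionNames()], species = species,
      kon = as.numeric(kon), sidedness = as.integer(sidedness))
}

#' Two-compartment bookkeeping for tracer flux assays
#'
#' Describes the bath (external) and vesicle-lumen (internal) compartments of a
#' radioactive uptake assay: volume ratio, per-species initial concentrations,
#' the number of effective transporter copies, and the recovery efficiency of
#' the assay.
#'
#' @param rv external-to-internal volume ratio (dimensionless, > 0).
#' @param vi internal (vesicle) volume in litres; sets the absolute scale that
#'   links transporter turnover to concentration changes.
#' @param nTransporters effective number of transporter copies.
#' @param ext,int named numeric vectors of initial concentrations (mol/L) per
#'   species in the external and internal compartments; names must match the
#'   species names of the model the system is used with.
#' @param recoveryEfficiency fraction of vesicles recovered by the assay
#'   (multiplies reported fractional uptake).
#' @return A list with class \code{"CompartmentSystem"}.
#' @export
CompartmentSystem <- function(rv, vi = 1e-15, nTransporters = 1,
                              ext, int, recoveryEfficiency = 1) {
  stopifnot(rv > 0, vi > 0, nTransporters > 0,
            all(ext >= 0), all(int >= 0),
            recoveryEfficiency > 0, recoveryEfficiency <= 1)
  structure(list(rv = rv, vi = vi, ve = rv * vi,
                 nTransporters = nTransporters,
                 ext = ext, int = int,
                 recoveryEfficiency = recoveryEfficiency),
            class = "CompartmentSystem")
}

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: delta = %.2f deg, gains = [%s], backgrounds = [%s]\n",
              object@delta, paste(signif(object@gains, 3), collapse = ", "),
              paste(signif(object@backgrounds, 3), collapse = ", ")))
})

setMethod("show", "PolarizedTrace", function(object) {
  cat(sprintf("PolarizedTrace: %d frames x 4 channels, %.1f ms/frame\n",
              nrow(object@counts), 1000 * object@frameInterval))
  cat(sprintf("  condition: %s %.3g M, pH %.1f\n",
              object@condition$species, object@condition$conc,
              object@condition$pH))
  show(object@calibration)
})

setMethod("show", "RateSet", function(object) {
  cat("RateSet: 60 rate constants (20 apo + 20 Arg-bound + 20 Agm-bound)\n")
  cat(sprintf("  apo range: %.3g - %.3g /s\n", min(object@apo), max(object@apo)))
  cat(sprintf("  K1/2 (arg): %.3g - %.3g M; K1/2 (agm): %.3g - %.3g M\n",
              min(object@khalf$arg), max(object@khalf$arg),
              min(object@khalf$agm), max(object@khalf$agm)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth (seed %d): delta = %.2f deg\n",
              object@seed, object@delta))
  cat("  orientations (theta, phi deg):\n")
  for (i in 1:4)
    cat(sprintf("    C%d: (%.1f, %.1f)\n", i,
                object@orientations[i, 1], object@orientations[i, 2]))
  cat(sprintf("  KD: %s\n", paste(sprintf("%s=%.3g M", names(object@kd),
                                          object@kd), collapse = ", ")))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel with %d resolvable state(s)\n", object@k))
  for (i in seq_len(object@k))
    cat(sprintf("  C%d: theta %.1f +/- %.1f, phi %.1f +/- %.1f deg\n", i,
                object@means[i, 1], object@sigmaTheta[i],
                object@means[i, 2], object@sigmaPhi[i]))
})

setMethod("show", "Model24", function(object) {
  cat(sprintf("Model24: apo branch + %d ligand branch(es), kon = %.3g /M/s, sidedness %d\n",
              length(object@species), object@kon, object@sidedness))
  for (sp in object@species)
    cat(sprintf("  species %s: KD_ext = %.3g M, KD_int = %.3g M\n",
                sp$name, sp$kdExt, sp$kdInt))
})

## ---- accessors -------------------------------------------------------------

#' @describeIn PolarizedTrace-class photon-count matrix accessor
#' @param object,x a \code{PolarizedTrace}
#' @export
setGeneric("traceCounts", function(x) standardGeneric("traceCounts"))

#' @export
setMethod("traceCounts", "PolarizedTrace", function(x) x@counts)

#' Frame interval accessor
#' @param x a \linkS4class{PolarizedTrace}
#' @return frame duration in seconds.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @export
setMethod("frameInterval", "PolarizedTrace", function(x) x@frameInterval)

#' Calibration accessor
#' @param x a \linkS4class{PolarizedTrace}
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @export
setMethod("calibration", "PolarizedTrace", function(x) x@calibration)

#' Rate constants accessor
#'
#' @param x a \linkS4class{RateSet}, \linkS4class{GroundTruth} or
#'   \linkS4class{Model24}.
#' @param branch \code{"apo"}, \code{"arg"} or \code{"agm"}.
#' @return named numeric(20) of rate constants (1/s).
#' @export
setGeneric("rateConstants", function(x, branch = "apo") standardGeneric("rateConstants"))

#' @export
setMethod("rateConstants", "RateSet", function(x, branch = "apo") slot(x, branch))

#' @export
setMethod("rateConstants", "GroundTruth", function(x, branch = "apo")
  rateConstants(x@rates, branch))

#' Ground-truth rate set accessor
#' @param x a \linkS4class{GroundTruth}
#' @export
setGeneric("truthRates", function(x) standardGeneric("truthRates"))

#' @export
setMethod("truthRates", "GroundTruth", function(x) x@rates)

#' Ground-truth dissociation constants accessor
#' @param x a \linkS4class{GroundTruth}
#' @export
setGeneric("truthKd", function(x) standardGeneric("truthKd"))

#' @export
setMethod("truthKd", "GroundTruth", function(x) x@kd)

#' Ground-truth orientations accessor
#' @param x a \linkS4class{GroundTruth}
#' @return 4 x 2 matrix of (theta, phi) in degrees.
#' @export
setGeneric("truthOrientations", function(x) standardGeneric("truthOrientations"))

#' @export
setMethod("truthOrientations", "GroundTruth", function(x) x@orientations)

#' Number of resolvable states accessor
#' @param x a \linkS4class{StateModel}
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @export
setMethod("nStates", "StateModel", function(x) x@k)

#' State mean orientations accessor
#' @param x a \linkS4class{StateModel}
#' @return k x 2 matrix of (theta, phi) in degrees.
#' @export
setGeneric("stateMeans", function(x) standardGeneric("stateMeans"))

#' @export
setMethod("stateMeans", "StateModel", function(x) x@means)
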