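## File I/O (TSV traces and events, JSON models and parameters) and the
## end-to-end pipeline driver: simulate -> detect -> cluster -> fit -> model.

#' Write / read a polarized trace as TSV with a JSON sidecar
#'
#' The TSV has columns \code{frame} (0-based), \code{I0}, \code{I45},
#' \code{I90}, \code{I135} (integer counts).  Frame interval, condition,
#' calibration and metadata go to \code{<path>.json}.
#'
#' @param trace a \linkS4class{PolarizedTrace}.
#' @param path TSV file path.
#' @return \code{writeTrace} returns \code{path} invisibly;
#'   \code{readTrace} returns a \linkS4class{PolarizedTrace}.
#' @export
writeTrace <- function(trace, path) {
  counts <- traceCounts(trace)
  df <- data.frame(frame = seq_len(nrow(counts)) - 1L, counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cal <- calibration(trace)
  side <- list(frame_interval = frameInterval(trace),
               condition = trace@condition,
               calibration = list(delta_deg = cal@delta, gains = cal@gains,
                                  backgrounds = cal@backgrounds),
               meta = trace@meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  want <- c("frame", "I0", "I45", "I90", "I135")
  if (!identical(names(df), want))
    stop(sprintf("trace schema violation in %s: expected columns %s, found %s",
                 path, paste(want, collapse = ","),
                 paste(names(df), collapse = ",")))
  sidePath <- paste0(path, ".json")
  cal <- Calibration(); fi <- 0.010
  cond <- list(species = "apo", conc = 0, pH = 5); meta <- list()
  if (file.exists(sidePath)) {
    side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
    fi <- side$frame_interval
    cond <- as.list(side$condition)
    meta <- as.list(side$meta)
    cal <- Calibration(delta = side$calibration$delta_deg,
                       gains = side$calibration$gains,
                       backgrounds = side$calibration$backgrounds)
  }
  PolarizedTrace(as.matrix(df[, 2:5]), frameInterval = fi, calibration = cal,
                 condition = cond, meta = meta)
}

#' Write / read an event table as TSV
#'
#' @param events event table (see \code{\link{buildEvents}}).
#' @param path TSV file path.
#' @return \code{writeEvents} returns \code{path} invisibly;
#'   \code{readEvents} returns the event data.frame.
#' @export
writeEvents <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop(sprintf("events file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("trace", "start", "end", "nframes", "I0", "I45", "I90", "I135",
            "theta", "phi", "flag", "omega", "state")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("events schema violation in %s: missing column(s) %s",
                 path, paste(missing, collapse = ",")))
  df
}

#' Write / read a rate set as JSON
#'
#' JSON layout: \code{\{apo: \{k_1_2: ...\}, arg: ..., agm: ...,
#' khalf: \{arg: ..., agm: ...\}\}} with canonical transition names.
#'
#' @param rates a \linkS4class{RateSet}.
#' @param path JSON file path.
#' @return \code{writeRates} returns \code{path} invisibly;
#'   \code{readRates} returns a \linkS4class{RateSet}.
#' @export
writeRates <- function(rates, path) {
  jsonlite::write_json(list(apo = as.list(rates@apo),
                            arg = as.list(rates@arg),
                            agm = as.list(rates@agm),
                            khalf = lapply(rates@khalf, as.list)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRates
#' @export
readRates <- function(path) {
  if (!file.exists(path)) stop(sprintf("rates file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  RateSet(unlist(x$apo), unlist(x$arg), unlist(x$agm),
          khalf = list(arg = unlist(x$khalf$arg), agm = unlist(x$khalf$agm)))
}

#' Write / read a 24-state model as JSON
#'
#' @param m a \linkS4class{Model24}.
#' @param path JSON file path.
#' @return \code{writeModel} returns \code{path} invisibly;
#'   \code{readModel} returns a \linkS4class{Model24}.
#' @export
writeModel <- function(m, path) {
  jsonlite::write_json(
    list(apo = as.list(m@apo),
         species = lapply(m@species, function(sp)
           list(name = sp$name, rates = as.list(sp$rates),
                kdExt = sp$kdExt, kdInt = sp$kdInt)),
         kon = m@kon, sidedness = m@sidedness),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  species <- lapply(x$species, function(sp)
    list(name = sp$name, rates = unlist(sp$rates), kdExt = sp$kdExt,
         kdInt = sp$kdInt))
  Model24(apo = unlist(x$apo), species = species, kon = x$kon,
          sidedness = as.integer(x$sidedness))
}

#' Write / read a ground truth as JSON
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path JSON file path.
#' @return \code{writeGroundTruth} returns \code{path} invisibly;
#'   \code{readGroundTruth} returns a \linkS4class{GroundTruth}.
#' @export
writeGroundTruth <- function(truth, path) {
  r <- truthRates(truth)
  jsonlite::write_json(
    list(rates = list(apo = as.list(r@apo), arg = as.list(r@arg),
                      agm = as.list(r@agm),
                      khalf = lapply(r@khalf, as.list)),
         kd = as.list(truthKd(truth)),
         orientations = truthOrientations(truth),
         delta = truth@delta, seed = truth@seed,
         extra = truth@extra),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  if (!file.exists(path)) stop(sprintf("truth file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rates <- RateSet(unlist(x$rates$apo), unlist(x$rates$arg),
                   unlist(x$rates$agm),
                   khalf = list(arg = unlist(x$rates$khalf$arg),
                                agm = unlist(x$rates$khalf$agm)))
  ori <- matrix(unlist(x$orientations), 4, 2)
  colnames(ori) <- c("theta", "phi")
  extra <- if (is.null(x$extra)) list() else
    list(K = unlist(x$extra$K),
         kdState = lapply(x$extra$kdState, unlist))
  new("GroundTruth", rates = rates, kd = unlist(x$kd), orientations = ori,
      delta = x$delta, seed = as.integer(x$seed), extra = extra)
}

#' Default pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param concentrations list with numeric vectors \code{arg} and \code{agm}
#'   of nonzero ligand concentrations (mol/L); the shared apo condition is
#'   added automatically.
#' @param eventsPerCondition target number of dwell events per condition.
#' @param eventsPerParticle events per simulated particle.
#' @param spec a \code{\link{traceSpec}}.
#' @param confidence changepoint detection confidence.
#' @param minEvents,minSnr,maxBleachSteps QC thresholds.
#' @param kmin smallest dwell length (frames) used in dwell fits.
#' @param kMax maximum number of states for clustering.
#' @param outDir optional output directory for TSV/JSON artifacts.
#' @return configuration list for \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(seed = 1,
                           concentrations = list(
                             arg = c(1e-5, 2e-5, 3.5e-5, 5e-5, 7.5e-5, 1e-4,
                                     1.5e-4, 2.5e-4, 4e-4, 7e-4, 1e-3, 1.5e-3),
                             agm = c(1e-5, 2.5e-5, 5e-5, 1e-4, 1.5e-4,
                                     2.5e-4, 5e-4, 8e-4, 1.5e-3, 2.5e-3)),
                           eventsPerCondition = 3000,
                           eventsPerParticle = 150,
                           spec = traceSpec(),
                           confidence = 0.95,
                           minEvents = 15, minSnr = 5, maxBleachSteps = 1,
                           kmin = 1, kMax = 6, outDir = NULL) {
  stopifnot(confidence > 0.5, confidence < 1, minEvents > 0, minSnr > 0)
  list(seed = as.integer(seed), concentrations = concentrations,
       eventsPerCondition = eventsPerCondition,
       eventsPerParticle = eventsPerParticle, spec = spec,
       confidence = confidence, minEvents = minEvents, minSnr = minSnr,
       maxBleachSteps = maxBleachSteps, kmin = kmin, kMax = kMax,
       outDir = outDir)
}

.conditionTable <- function(concentrations) {
  out <- data.frame(ligand = "apo", conc = 0, stringsAsFactors = FALSE)
  for (lig in names(concentrations))
    out <- rbind(out, data.frame(ligand = lig,
                                 conc = sort(concentrations[[lig]]),
                                 stringsAsFactors = FALSE))
  out$id <- paste0(out$ligand, "_", signif(out$conc, 4))
  out
}

#' Run the full analysis pipeline on synthetic data
#'
#' End-to-end driver: for every ligand condition, simulates conformational
#' state paths from the ground truth, renders Poisson photon-count traces
#' with a terminal single-step photobleach, detects changepoints, builds and
#' QC-filters events; then clusters the pooled events into conformational
#' states, rotates into the molecule-local frame, merges changepoint false
#' positives, computes per-condition dwell fits and transition statistics,
#' inverts them to apparent rate constants, fits the binding isotherms to
#' obtain the 60 rate constants, and fits the equilibrium isotherms to
#' obtain the dissociation constants.  Deterministic given the config seed.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config a \code{\link{pipelineConfig}} list.
#' @return list with \code{events} (pooled labelled events), \code{states}
#'   (a \linkS4class{StateModel}), \code{conditions}, \code{perCondition}
#'   (dwell fits, transition stats, apparent rates, substate probabilities),
#'   \code{appRates} (long table), \code{rates} (fitted
#'   \linkS4class{RateSet}), \code{equilibrium} (fitted equilibrium
#'   constants with per-state KD), \code{qc} (rejection report) and
#'   \code{config}.
#' @export
runPipeline <- function(truth, config = pipelineConfig()) {
  conds <- .conditionTable(config$concentrations)
  dt <- config$spec$frameInterval
  allEvents <- NULL
  qcRej <- NULL
  traceCondition <- character(0)
  traceCounter <- 0L
  seedBase <- config$seed * 97L

  for (ci in seq_len(nrow(conds))) {
    lig <- conds$ligand[ci]; conc <- conds$conc[ci]
    nParticles <- ceiling(config$eventsPerCondition / config$eventsPerParticle)
    traces <- list(); analyses <- list()
    for (part in seq_len(nParticles)) {
      s <- (seedBase + 1000L * ci + part) %% .Machine$integer.max
      path <- simulateStatePath(truth, lig, conc,
                                nEvents = config$eventsPerParticle, seed = s)
      pathDur <- sum(path$duration)
      spec <- config$spec
      spec$bleachTime <- pathDur
      spec$nFrames <- ceiling(pathDur / dt) + 25L
      tr <- renderTrace(path, truth, spec, seed = s + 1L,
                        condition = list(species = lig, conc = conc, pH = 5))
      traces[[part]] <- tr
      cps <- detectChangepoints(tr, confidence = config$confidence,
                                seed = config$seed)
      analyses[[part]] <- list(cps = cps,
                               events = buildEvents(tr, cps,
                                                    traceId = traceCounter + part))
    }
    flt <- filterParticles(traces, minEvents = config$minEvents,
                           minSnr = config$minSnr,
                           maxBleachSteps = config$maxBleachSteps,
                           analyses = analyses)
    if (nrow(flt$rejected)) {
      flt$rejected$condition <- conds$id[ci]
      qcRej <- rbind(qcRej, flt$rejected)
    }
    for (kp in flt$kept) {
      ev <- kp$events
      ev$condition <- conds$id[ci]
      allEvents <- rbind(allEvents, ev)
    }
    traceCondition <- c(traceCondition, rep(conds$id[ci], nParticles))
    traceCounter <- traceCounter + nParticles
  }
  if (is.null(allEvents) || nrow(allEvents) < config$minEvents)
    stop("pipeline aborted at QC stage: no particles survived filtering")

  ## cluster pooled events, then register the local frame
  cl <- clusterOrientations(allEvents, kMax = config$kMax,
                            seed = config$seed)
  k <- nStates(cl$model)
  mu <- stateMeans(cl$model)
  v <- anglesToVec(allEvents$theta, allEvents$phi)
  c1m <- anglesToVec(mu[1, 1], mu[1, 2])[1, ]
  c4m <- anglesToVec(mu[k, 1], mu[k, 2])[1, ]
  loc <- toLocalFrame(v, c1m, c4m)
  allEvents$theta <- loc$angles$theta
  allEvents$phi <- loc$angles$phi

  merged <- NULL
  for (cid in unique(allEvents$condition)) {
    sel <- allEvents$condition == cid
    m <- mergeSameState(allEvents[sel, , drop = FALSE], cl$labels[sel],
                        delta = truth@delta)
    m$condition <- cid
    merged <- rbind(merged, m)
  }
  ## omega relative to the C1 mean
  c1loc <- vecToAngles(matrix(loc$rotation %*% c1m, 1))
  merged$omega <- omegaAngle(merged$theta, merged$phi,
                             c1loc$theta, c1loc$phi)

  ## dwell durations per condition and conformation; boundary events are
  ## censored dwells and are excluded from duration fits
  dwellsOf <- function(cid, conf) {
    ev <- merged[merged$condition == cid, , drop = FALSE]
    keep <- rep(TRUE, nrow(ev))
    for (tr in unique(ev$trace)) {
      ix <- which(ev$trace == tr)
      keep[ix[c(1, length(ix))]] <- FALSE
    }
    dw <- ev$nframes[keep & !is.na(ev$state) & ev$state == conf]
    dw[dw >= config$kmin]
  }

  ## global serial-scheme dwell fits (one per conformation and ligand):
  ## the slow component carries only a few percent of any one condition's
  ## events, so per-condition dwell likelihoods are information-limited;
  ## coupling the serial rates to binding isotherms across the whole
  ## concentration series pools them, and on the rate scale the isotherm
  ## form is exact
  serialFits <- list()
  for (lg in names(config$concentrations)) {
    for (conf in seq_len(k)) {
      sets <- list(list(conc = 0, dwells = dwellsOf("apo_0", conf)))
      for (cc in sort(config$concentrations[[lg]])) {
        cid <- paste0(lg, "_", signif(cc, 4))
        sets[[length(sets) + 1L]] <- list(conc = cc,
                                          dwells = dwellsOf(cid, conf))
      }
      serialFits[[paste0(lg, "_C", conf)]] <-
        globalFitSerial(sets, dt, kmin = config$kmin, nStarts = 14,
                        seed = config$seed + conf)
    }
  }
  perCondition <- list()
  appTab <- NULL
  for (ci in seq_len(nrow(conds))) {
    cid <- conds$id[ci]
    ev <- merged[merged$condition == cid, , drop = FALSE]
    st <- stateStatistics(ev, k = k)
    ## per-condition maximum-likelihood dwell fits are unbiased but noisy;
    ## the per-transition isotherm fit over the whole series (below) is
    ## their smoother.  The apo condition is special: it anchors the apo
    ## rate constants with the leverage of a single dataset, so its serial
    ## rates are taken as the per-transition median of three
    ## semi-independent estimates — the apo dwell fit itself and the two
    ## ligand series' pooled serial fits evaluated at zero concentration —
    ## which tolerates an outlier in any one of them
    fits <- lapply(seq_len(k), function(conf) {
      pc <- fitDwell(dwellsOf(cid, conf), dt, ncomp = 2,
                     kmin = config$kmin, seed = config$seed + conf)
      if (conds$ligand[ci] != "apo")
        return(list(lambda1 = pc$lambda1, lambda2 = pc$lambda2, f = pc$f))
      inv <- invertSerialScheme(pc$lambda1, pc$lambda2,
                                min(pc$f, 0.9999), 1)
      cand <- list(c(inv$kOut, inv$kAb, inv$kBa))
      for (lg in names(config$concentrations)) {
        pr <- serialFits[[paste0(lg, "_C", conf)]]$predict(0)
        cand[[length(cand) + 1L]] <- c(pr$kOut, pr$kAb, pr$kBa)
      }
      cm <- apply(do.call(rbind, cand), 2, stats::median)
      eg <- serialEigenrates(cm[1], cm[2], cm[3])
      list(lambda1 = eg$lambda1, lambda2 = eg$lambda2, f = eg$f)
    })
    appk <- apparentRatesFromFits(fits, st)
    nconf <- vapply(seq_len(k), function(s) sum(ev$state == s, na.rm = TRUE),
                    numeric(1))
    tp <- .transitionPairs()
    srcConf <- .confOf(tp$from)
    appTab <- rbind(appTab, data.frame(
      transition = names(appk), ligand = conds$ligand[ci],
      conc = conds$conc[ci], value = as.numeric(appk),
      weight = nconf[srcConf] / pmax(as.numeric(appk), 1e-6)^2,
      stringsAsFactors = FALSE))
    P <- substateProbabilities(appk)
    perCondition[[cid]] <- list(fits = fits, stats = st, appRates = appk,
                                substateP = P, nEvents = nrow(ev))
  }

  rateFit <- fitRateConstants(appTab, seed = config$seed)
  ## substate-probability isotherms for the equilibrium fit, evaluated from
  ## the isotherm-smoothed apparent rates (the per-condition probabilities
  ## are also kept, in perCondition, for inspection)
  pTab <- NULL
  for (lg in names(config$concentrations)) {
    for (cc in c(0, sort(config$concentrations[[lg]]))) {
      P <- substateProbabilities(apparentRates(rateFit$rates, lg, cc))
      pTab <- rbind(pTab, data.frame(state = 1:8, ligand = lg,
                                     conc = cc, P = P))
    }
  }
  eq <- fitEquilibriumConstants(pTab, seed = config$seed)

  out <- list(events = merged, states = cl$model, conditions = conds,
              perCondition = perCondition, appRates = appTab,
              rates = rateFit$rates, rateFits = rateFit$fits,
              equilibrium = eq, substateP = pTab,
              qc = list(rejected = qcRej), config = config)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeEvents(merged, file.path(config$outDir, "events.tsv"))
    writeRates(rateFit$rates, file.path(config$outDir, "rates.json"))
    jsonlite::write_json(
      list(k = k, means = stateMeans(cl$model),
           sigmaTheta = cl$model@sigmaTheta, sigmaPhi = cl$model@sigmaPhi,
           occupancy = lapply(perCondition, function(x) x$stats$occupancy),
           p = lapply(perCondition, function(x) x$stats$p),
           n = lapply(perCondition, function(x) x$stats$n)),
      file.path(config$outDir, "states.json"), digits = NA)
    jsonlite::write_json(
      list(K = eq$K, LK = eq$LK, KD1 = as.list(eq$KD1), KD = eq$KD),
      file.path(config$outDir, "kd.json"), digits = NA)
    jsonlite::write_json(
      list(seed = config$seed, confidence = config$confidence,
           minEvents = config$minEvents, minSnr = config$minSnr,
           package = as.character(utils::packageVersion("polkin"))),
      file.path(config$outDir, "runlog.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
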