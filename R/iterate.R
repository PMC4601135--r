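## Full workflow: deamination-based prior -> joint consensus ->
## database contamination estimate -> fragment partition / parameter
## refresh -> consensus again, until the contamination rate stabilizes.

#' Result of the iterative pipeline
#'
#' @slot calls Final [SiteCalls-class] (both tracks).
#' @slot initialCalls Iteration-0 [SiteCalls-class].
#' @slot contDeamCurve The deamination-prior [PosteriorCurve-class].
#' @slot estimate Final contamination estimate: a
#'   [ContaminationEstimate-class], or the contDeam curve's MAP when the
#'   run stopped early for lack of contaminant information.
#' @slot rate Final contamination rate reported.
#' @slot trace data.frame: per iteration `iter`, `ccIn`, `crOut`,
#'   `nInformative`, `nEndoFrags`, `nContFrags`, `deltaC`.
#' @slot converged,earlyStop Logical flags; `earlyStopReason` explains an
#'   early stop ("insufficient contaminant information").
#' @export
setClass("IterativeFit",
  representation(calls = "SiteCalls", initialCalls = "SiteCalls",
                 contDeamCurve = "PosteriorCurve", estimate = "ANY",
                 rate = "numeric", trace = "data.frame",
                 converged = "logical", earlyStop = "logical",
                 earlyStopReason = "character"))

setMethod("show", "IterativeFit", function(object) {
  cat(sprintf("IterativeFit: %d iteration(s), rate = %.3f%s\n",
              nrow(object@trace), object@rate,
              if (object@earlyStop) paste0(" [early stop: ",
                                           object@earlyStopReason, "]")
              else if (object@converged) " [converged]" else " [max iterations]"))
})

#' @rdname mapRate
#' @export
setMethod("contaminationRate", "IterativeFit", function(x) x@rate)

#' @rdname finalCalls
#' @export
iterationTrace <- function(x) x@trace

#' Accessors for IterativeFit
#'
#' @param x An [IterativeFit-class] object.
#' @name finalCalls
#' @export
finalCalls <- function(x) x@calls

#' Run the full iterative inference
#'
#' Iteration 0 estimates the deamination-conditioned contamination prior
#' and calls a first consensus with an undamaged contaminant profile and
#' length evidence disabled. Each subsequent iteration re-estimates the
#' contamination rate against the database (always including the predicted
#' contaminant consensus), partitions fragments at differing sites,
#' refreshes both deamination profiles and the length mixture, and
#' re-calls the consensus with the updated priors. The loop stops when the
#' rate moves less than `tol`, after `maxIter` iterations, or early --
#' flagged "insufficient contaminant information" -- when no differing
#' sites support a partition or the database estimate degenerates; the
#' deamination-based estimate is then reported.
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param db Optional named vector of gapped candidate contaminant genomes.
#' @param protocol Library protocol for the deamination prior.
#' @param err 4x4 substitution error matrix.
#' @param gridStep Rate grid resolution (also the convergence scale).
#' @param tol Absolute convergence tolerance on the rate.
#' @param maxIter Maximum refinement iterations.
#' @param maxDepth Deamination profile depth.
#' @param qualityThreshold Partitioning call-quality threshold.
#' @param predictedPhred Quality mask for the predicted contaminant record.
#' @param outDir Optional directory; per-iteration artifacts are written
#'   under `iter_<t>/` and a JSON config echo at the top level.
#' @param verbose Print per-iteration progress.
#' @return An [IterativeFit-class] object.
#' @export
runPipeline <- function(fa, db = NULL, protocol = c("single", "double"),
                        err = uniformErrorModel(), gridStep = 0.005,
                        tol = 0.005, maxIter = 10L, maxDepth = 10L,
                        qualityThreshold = 30, predictedPhred = 200,
                        outDir = NULL, verbose = FALSE) {
  protocol <- match.arg(protocol)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    cfg <- list(protocol = protocol, gridStep = gridStep, tol = tol,
                maxIter = maxIter, maxDepth = maxDepth,
                qualityThreshold = qualityThreshold,
                predictedPhred = predictedPhred,
                nFragments = nrow(fa@fragments), reference = fa@refName)
    jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  note <- function(...) if (verbose) message(sprintf(...))

  cd <- contDeamEstimate(fa, protocol, maxDepth = maxDepth, err = err,
                         gridStep = gridStep,
                         outPrefix = if (is.null(outDir)) NULL
                                     else file.path(outDir, "contdeam"))
  cPrev <- if (isFlat(cd$curve)) 0 else mapRate(cd$curve)
  note("contDeam prior: %.3f", cPrev)

  priors <- endoPriors(contamination = cPrev, endoProfile = cd$profile,
                       contProfile = deaminationProfile(maxDepth = maxDepth),
                       lengthModel = fragmentLengthModel(enabled = FALSE))
  calls <- callConsensus(fa, priors, err)
  initialCalls <- calls

  trace <- data.frame(iter = 0L, ccIn = cPrev, crOut = cPrev,
                      nInformative = NA_integer_, nEndoFrags = NA_integer_,
                      nContFrags = NA_integer_, deltaC = NA_real_)
  writeIter <- function(t, calls, priors) {
    if (is.null(outDir)) return(invisible(NULL))
    d <- file.path(outDir, paste0("iter_", t))
    dir.create(d, showWarnings = FALSE)
    writeConsensus(calls, file.path(d, "endo.fa"), file.path(d, "endo.log"),
                   track = "endo")
    writeConsensus(calls, file.path(d, "cont.fa"), file.path(d, "cont.log"),
                   track = "cont")
    writeDeaminationProfile(priors@endoProfile,
                            file.path(d, "endo.5p.prof"),
                            file.path(d, "endo.3p.prof"))
  }
  writeIter(0L, calls, priors)

  estimate <- cd$curve
  converged <- FALSE
  earlyStop <- FALSE
  reason <- character(0)
  lengthModel <- fragmentLengthModel(enabled = FALSE)
  contProfile <- deaminationProfile(maxDepth = maxDepth)

  for (t in seq_len(maxIter)) {
    mt <- tryCatch(
      estimateContamination(fa, calls, db = db, priors = priors,
                            gridStep = gridStep, includePredicted = TRUE,
                            predictedPhred = predictedPhred, err = err),
      error = function(e) e)
    if (inherits(mt, "error")) {
      earlyStop <- TRUE
      reason <- "insufficient contaminant information"
      note("iteration %d: mtCont degenerate (%s); stopping early",
           t, conditionMessage(mt))
      break
    }
    cr <- contaminationRate(mt)
    part <- partitionFragments(fa, calls, qualityThreshold)
    nInf <- mt@table$informativeSites[match(mt@bestContaminant, mt@table$name)]
    if (nrow(part$sites) == 0L ||
        (length(part$endo) == 0L && length(part$cont) == 0L)) {
      earlyStop <- TRUE
      reason <- "insufficient contaminant information"
      trace <- rbind(trace, data.frame(
        iter = t, ccIn = priors@contamination, crOut = cr,
        nInformative = nInf, nEndoFrags = length(part$endo),
        nContFrags = length(part$cont), deltaC = abs(cr - cPrev)))
      note("iteration %d: no differing sites; stopping early", t)
      break
    }
    endoProfile <- refitDeamination(fa, part$endo, calls, track = "endo",
                                    maxDepth = maxDepth,
                                    previous = priors@endoProfile)
    contProfile <- suppressWarnings(
      refitDeamination(fa, part$cont, calls, track = "cont",
                       maxDepth = maxDepth, previous = contProfile))
    lengthModel <- refitLengthModel(fa, part$endo, part$cont,
                                    previous = if (lengthModel@enabled)
                                      lengthModel else fragmentLengthModel())
    priors <- endoPriors(contamination = cr, endoProfile = endoProfile,
                         contProfile = contProfile,
                         lengthModel = lengthModel)
    calls <- callConsensus(fa, priors, err, prevCalls = calls)
    estimate <- mt
    delta <- abs(cr - cPrev)
    trace <- rbind(trace, data.frame(
      iter = t, ccIn = priors@contamination, crOut = cr,
      nInformative = nInf, nEndoFrags = length(part$endo),
      nContFrags = length(part$cont), deltaC = delta))
    writeIter(t, calls, priors)
    note("iteration %d: c_r = %.3f (delta %.4f)", t, cr, delta)
    if (delta < tol) { converged <- TRUE; cPrev <- cr; break }
    cPrev <- cr
  }

  rate <- if (earlyStop || !inherits(estimate, "ContaminationEstimate")) {
    if (isFlat(cd$curve)) 0 else mapRate(cd$curve)
  } else {
    contaminationRate(estimate)
  }
  fit <- new("IterativeFit", calls = calls, initialCalls = initialCalls,
             contDeamCurve = cd$curve, estimate = estimate, rate = rate,
             trace = trace, converged = converged, earlyStop = earlyStop,
             earlyStopReason = if (earlyStop) reason else character(0))
  if (!is.null(outDir)) {
    utils::write.table(trace, file.path(outDir, "trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  fit
}
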