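#' @import methods
NULL

## ---------------------------------------------------------------------------
## DeaminationProfile
## ---------------------------------------------------------------------------

#' Position-dependent deamination profile
#'
#' Rates of nucleotide substitution due to post-mortem cytosine deamination,
#' indexed by distance from each fragment end (in original-molecule
#' orientation) and ordered substitution type. Row `p` holds the rates at
#' distance `p - 1` from the respective end; positions beyond the modelled
#' depth fall back to the last row.
#'
#' @slot end5 Numeric matrix, positions from the 5' end x 12 ordered
#'   substitutions (`"A>C"`, ..., `"T>G"`), each rate in \[0, 1\].
#' @slot end3 Same layout for the 3' end.
#' @export
setClass("DeaminationProfile",
  representation(end5 = "matrix", end3 = "matrix"),
  validity = function(object) {
    for (nm in c("end5", "end3")) {
      m <- slot(object, nm)
      if (ncol(m) != 12L || !identical(colnames(m), SUBS))
        return(sprintf("%s must have the 12 ordered substitution columns", nm))
      if (nrow(m) < 1L) return(sprintf("%s must have at least one row", nm))
      if (any(m < 0 | m > 1)) return(sprintf("%s rates must lie in [0,1]", nm))
      for (b in BASES) {
        out <- rowSums(m[, grep(paste0("^", b, ">"), SUBS), drop = FALSE])
        if (any(out > 1 + 1e-9))
          return(sprintf("%s: total substitution rate out of %s exceeds 1", nm, b))
      }
    }
    TRUE
  }
)

#' Construct a deamination profile
#'
#' @param end5,end3 Matrices (positions x 12 substitutions) or `NULL`.
#' @param maxDepth Number of positions when building an empty (all-zero)
#'   profile.
#' @return A [DeaminationProfile-class] object.
#' @examples
#' emptyProfile <- deaminationProfile(maxDepth = 5)
#' @export
deaminationProfile <- function(end5 = NULL, end3 = NULL, maxDepth = 10L) {
  zero <- matrix(0, maxDepth, 12L, dimnames = list(NULL, SUBS))
  fix <- function(m) {
    if (is.null(m)) return(zero)
    m <- as.matrix(m)
    colnames(m) <- SUBS
    m
  }
  new("DeaminationProfile", end5 = fix(end5), end3 = fix(end3))
}

setMethod("show", "DeaminationProfile", function(object) {
  cat("DeaminationProfile\n")
  cat(sprintf("  5' depth %d, terminal C>T = %.4f\n",
              nrow(object@end5), object@end5[1L, "C>T"]))
  cat(sprintf("  3' depth %d, terminal C>T = %.4f, G>A = %.4f\n",
              nrow(object@end3), object@end3[1L, "C>T"], object@end3[1L, "G>A"]))
})

## ---------------------------------------------------------------------------
## FragmentLengthModel
## ---------------------------------------------------------------------------

#' Log-normal fragment length mixture
#'
#' Location/scale parameters (natural-log scale) of the endogenous and
#' contaminant fragment-length distributions. When `enabled` is `FALSE`
#' length carries no evidence and the posterior reduces to the prior.
#'
#' @slot muEndo,sigmaEndo,muCont,sigmaCont Numeric scalars.
#' @slot enabled Logical flag.
#' @export
setClass("FragmentLengthModel",
  representation(muEndo = "numeric", sigmaEndo = "numeric",
                 muCont = "numeric", sigmaCont = "numeric",
                 enabled = "logical"),
  validity = function(object) {
    if (object@enabled && (object@sigmaEndo <= 0 || object@sigmaCont <= 0))
      return("sigma must be > 0 when the model is enabled")
    TRUE
  }
)

#' @param muEndo,sigmaEndo,muCont,sigmaCont Log-normal parameters.
#' @param enabled Whether length evidence is used.
#' @rdname FragmentLengthModel-class
#' @export
fragmentLengthModel <- function(muEndo = log(45), sigmaEndo = 0.35,
                                muCont = log(85), sigmaCont = 0.35,
                                enabled = TRUE) {
  new("FragmentLengthModel", muEndo = muEndo, sigmaEndo = sigmaEndo,
      muCont = muCont, sigmaCont = sigmaCont, enabled = enabled)
}

setMethod("show", "FragmentLengthModel", function(object) {
  if (!object@enabled) { cat("FragmentLengthModel (disabled)\n"); return(invisible(NULL)) }
  cat(sprintf("FragmentLengthModel endo lnN(%.3f, %.3f)  cont lnN(%.3f, %.3f)\n",
              object@muEndo, object@sigmaEndo, object@muCont, object@sigmaCont))
})

## ---------------------------------------------------------------------------
## FragmentAlignments
## ---------------------------------------------------------------------------

#' Aligned ancient-DNA fragments in columnar form
#'
#' The unit of analysis: every mapped fragment with its per-base
#' observations against a single linear reference. Observations are stored
#' one row per aligned base (or deletion gap) with distances from the
#' fragment ends expressed in original-molecule orientation, so that
#' deamination profiles can be looked up directly; `flip` marks
#' reverse-strand observations whose substitution types must be
#' complemented before profile lookup.
#'
#' @slot refName Reference sequence name.
#' @slot refSeq Uppercase reference sequence (A/C/G/T/N).
#' @slot fragments data.frame: `id`, `start0` (0-based), `mapq`,
#'   `m` (mismapping probability \eqn{10^{-MAPQ/10}}), `reverse`, `len`.
#' @slot observations data.frame: `frag` (row index into `fragments`),
#'   `ref0`, `base` (1..4, 5 = deletion gap), `eps`, `d5`, `d3`
#'   (molecule-orientation distances from the 5'/3' fragment ends), `flip`.
#' @slot insertions data.frame: `frag`, `ref0` (insertion precedes this
#'   reference position), `seq`, `eps` (mean error probability of the
#'   inserted bases).
#' @export
setClass("FragmentAlignments",
  representation(refName = "character", refSeq = "character",
                 fragments = "data.frame", observations = "data.frame",
                 insertions = "data.frame"),
  validity = function(object) {
    if (nchar(object@refSeq) < 1L) return("reference sequence must be non-empty")
    if (grepl("[^ACGTN]", object@refSeq)) return("reference alphabet must be {A,C,G,T,N}")
    fr <- object@fragments; ob <- object@observations
    need <- c("id", "start0", "mapq", "m", "reverse", "len")
    if (!all(need %in% names(fr))) return("fragments table missing columns")
    need <- c("frag", "ref0", "base", "eps", "d5", "d3", "flip")
    if (!all(need %in% names(ob))) return("observations table missing columns")
    if (nrow(ob) && (min(ob$frag) < 1L || max(ob$frag) > nrow(fr)))
      return("observation frag index out of range")
    if (nrow(fr) && any(fr$m <= 0 | fr$m > 1))
      return("mismapping probability must lie in (0,1]")
    TRUE
  }
)

fragmentAlignments <- function(refName, refSeq, fragments, observations,
                               insertions = NULL) {
  if (is.null(insertions))
    insertions <- data.frame(frag = integer(0), ref0 = integer(0),
                             seq = character(0), eps = numeric(0))
  new("FragmentAlignments", refName = refName, refSeq = toupper(refSeq),
      fragments = fragments, observations = observations,
      insertions = insertions)
}

#' @export
setMethod("length", "FragmentAlignments", function(x) nrow(x@fragments))

setMethod("show", "FragmentAlignments", function(object) {
  cat(sprintf("FragmentAlignments: %d fragments, %d base observations on %s (%d bp)\n",
              nrow(object@fragments), nrow(object@observations),
              object@refName, nchar(object@refSeq)))
})

#' Accessors for FragmentAlignments
#'
#' @param x A [FragmentAlignments-class] object.
#' @return `fragments()` and `observations()` return the underlying
#'   data.frames; `refSequence()` the reference string; `refName()` its name.
#' @export
fragments <- function(x) x@fragments

#' @rdname fragments
#' @export
observations <- function(x) x@observations

#' @rdname fragments
#' @export
refSequence <- function(x) x@refSeq

#' @rdname fragments
#' @export
refName <- function(x) x@refName

## Integer-encoded reference, computed on demand (N -> NA).
refIntVector <- function(x) baseToInt(strsplit(x@refSeq, "", fixed = TRUE)[[1L]])

## ---------------------------------------------------------------------------
## SiteCalls
## ---------------------------------------------------------------------------

#' Per-site joint endogenous/contaminant consensus calls
#'
#' One row per reference position with the MAP endogenous and contaminant
#' bases, their PHRED-scaled error probabilities, coverage, and the four
#' marginal base probabilities for each track.
#'
#' @slot refName Reference name.
#' @slot calls data.frame with columns `ref0`, `refBase`, `endoBase`,
#'   `endoErr`, `endoPhred`, `contBase`, `contErr`, `contPhred`, `coverage`,
#'   `eA`,`eC`,`eG`,`eT` (endogenous marginals), `cA`,`cC`,`cG`,`cT`
#'   (contaminant marginals).
#' @export
setClass("SiteCalls",
  representation(refName = "character", calls = "data.frame"),
  validity = function(object) {
    need <- c("ref0", "refBase", "endoBase", "endoErr", "endoPhred",
              "contBase", "contErr", "contPhred", "coverage",
              "eA", "eC", "eG", "eT", "cA", "cC", "cG", "cT")
    if (!all(need %in% names(object@calls))) return("calls table missing columns")
    TRUE
  }
)

setMethod("show", "SiteCalls", function(object) {
  cc <- object@calls
  cat(sprintf("SiteCalls on %s: %d sites, median endo PHRED %.0f, %d uncovered\n",
              object@refName, nrow(cc),
              stats::median(cc$endoPhred), sum(cc$coverage == 0)))
})

#' @rdname siteCallsAccessors
#' @param x A [SiteCalls-class] object.
#' @export
callTable <- function(x) x@calls

#' Accessors for SiteCalls
#'
#' `endoSequence()`/`contSequence()` return the called consensus strings
#' (uncovered sites as `N`, called deletions as `-`); `endoMarginals()` the
#' sites x 4 matrix of endogenous base marginals used as priors downstream.
#'
#' @name siteCallsAccessors
#' @param x A [SiteCalls-class] object.
#' @param qualityFilter Optional PHRED threshold; sites below it become `N`.
#' @export
endoSequence <- function(x, qualityFilter = NULL) {
  cc <- x@calls
  b <- cc$endoBase
  if (!is.null(qualityFilter)) b[cc$endoPhred < qualityFilter] <- "N"
  paste0(b, collapse = "")
}

#' @rdname siteCallsAccessors
#' @export
contSequence <- function(x, qualityFilter = NULL) {
  cc <- x@calls
  b <- cc$contBase
  if (!is.null(qualityFilter)) b[cc$contPhred < qualityFilter] <- "N"
  paste0(b, collapse = "")
}

#' @rdname siteCallsAccessors
#' @export
endoMarginals <- function(x) {
  as.matrix(x@calls[, c("eA", "eC", "eG", "eT")])
}

## ---------------------------------------------------------------------------
## PosteriorCurve
## ---------------------------------------------------------------------------

#' Gridded posterior over a contamination rate
#'
#' @slot grid Ascending rates in \[0, 1\].
#' @slot logPosterior Unnormalized log posterior per grid point.
#' @slot posterior Normalized posterior (sums to 1 over the grid).
#' @slot map MAP rate (`NA` when the posterior is flat).
#' @slot ciLow,ciHigh 95\% highest-posterior-density bounds.
#' @slot flat `TRUE` when the likelihood carries no information on the rate.
#' @export
setClass("PosteriorCurve",
  representation(grid = "numeric", logPosterior = "numeric",
                 posterior = "numeric", map = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", flat = "logical"),
  validity = function(object) {
    if (length(object@grid) != length(object@logPosterior))
      return("grid and logPosterior lengths differ")
    if (abs(sum(object@posterior) - 1) > 1e-6)
      return("posterior must normalize to 1")
    if (!object@flat && (object@ciLow > object@map || object@map > object@ciHigh))
      return("ciLow <= map <= ciHigh violated")
    TRUE
  }
)

posteriorCurve <- function(grid, logPosterior, flat = FALSE) {
  post <- exp(logPosterior - logSumExp(logPosterior))
  post <- post / sum(post)
  if (flat) {
    new("PosteriorCurve", grid = grid, logPosterior = logPosterior,
        posterior = post, map = NA_real_, ciLow = min(grid),
        ciHigh = max(grid), flat = TRUE)
  } else {
    ci <- hpdInterval(grid, post)
    new("PosteriorCurve", grid = grid, logPosterior = logPosterior,
        posterior = post, map = grid[which.max(post)],
        ciLow = ci[1L], ciHigh = ci[2L], flat = FALSE)
  }
}

setMethod("show", "PosteriorCurve", function(object) {
  if (object@flat) {
    cat("PosteriorCurve: flat (rate not identifiable)\n")
  } else {
    cat(sprintf("PosteriorCurve: MAP = %.3f [%.3f, %.3f] (95%% HPD)\n",
                object@map, object@ciLow, object@ciHigh))
  }
})

#' Accessors for PosteriorCurve
#'
#' @param x A [PosteriorCurve-class] object.
#' @export
mapRate <- function(x) x@map

#' @rdname mapRate
#' @export
credibleInterval <- function(x) c(low = x@ciLow, high = x@ciHigh)

#' @rdname mapRate
#' @export
isFlat <- function(x) x@flat

## ---------------------------------------------------------------------------
## ContaminationEstimate
## ---------------------------------------------------------------------------

#' Database-driven contamination estimate
#'
#' @slot rate MAP per-nucleotide contamination rate.
#' @slot ciLow,ciHigh 95\% HPD bounds.
#' @slot bestContaminant Name of the most likely contaminant record.
#' @slot table data.frame: per-genome `name`, `logLik` (maximum over the
#'   grid), `map`, `ciLow`, `ciHigh`, `informativeSites`, `degenerate`.
#' @slot curve The [PosteriorCurve-class] of the best genome.
#' @export
setClass("ContaminationEstimate",
  representation(rate = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 bestContaminant = "character", table = "data.frame",
                 curve = "PosteriorCurve"),
  validity = function(object) {
    if (object@ciLow > object@rate || object@rate > object@ciHigh)
      return("ciLow <= rate <= ciHigh violated")
    TRUE
  }
)

setMethod("show", "ContaminationEstimate", function(object) {
  cat(sprintf("ContaminationEstimate: %.3f [%.3f, %.3f], source = %s\n",
              object@rate, object@ciLow, object@ciHigh, object@bestContaminant))
})

#' @rdname mapRate
#' @export
setGeneric("contaminationRate", function(x) standardGeneric("contaminationRate"))

#' @rdname mapRate
#' @export
setMethod("contaminationRate", "ContaminationEstimate", function(x) x@rate)

#' @rdname mapRate
#' @export
setMethod("contaminationRate", "PosteriorCurve", function(x) x@map)

#' @rdname mapRate
#' @export
bestContaminant <- function(x) x@bestContaminant

## ---------------------------------------------------------------------------
## EndoPriors
## ---------------------------------------------------------------------------

#' Priors for the joint consensus caller
#'
#' @slot contamination Prior contamination rate \eqn{c_c \in [0,1]}.
#' @slot endoProfile Endogenous [DeaminationProfile-class].
#' @slot contProfile Contaminant [DeaminationProfile-class] (all-zero at
#'   iteration 0; present-day contaminants carry little deamination).
#' @slot lengthModel A [FragmentLengthModel-class].
#' @export
setClass("EndoPriors",
  representation(contamination = "numeric", endoProfile = "DeaminationProfile",
                 contProfile = "DeaminationProfile",
                 lengthModel = "FragmentLengthModel"),
  validity = function(object) {
    if (object@contamination < 0 || object@contamination > 1)
      return("contamination prior must lie in [0,1]")
    TRUE
  }
)

#' @param contamination,endoProfile,contProfile,lengthModel See slots.
#' @rdname EndoPriors-class
#' @export
endoPriors <- function(contamination = 0.1,
                       endoProfile = deaminationProfile(),
                       contProfile = deaminationProfile(),
                       lengthModel = fragmentLengthModel(enabled = FALSE)) {
  new("EndoPriors", contamination = contamination, endoProfile = endoProfile,
      contProfile = contProfile, lengthModel = lengthModel)
}

setMethod("show", "EndoPriors", function(object) {
  cat(sprintf("EndoPriors: c_c = %.3f, length model %s\n",
              object@contamination,
              if (object@lengthModel@enabled) "enabled" else "disabled"))
})
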