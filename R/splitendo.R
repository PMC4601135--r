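## Partition fragments by the allele they support at sites where the two
## consensus tracks differ, then re-estimate deamination profiles and the
## log-normal length mixture on each set.

#' Partition fragments by supported consensus allele
#'
#' At sites where the endogenous and contaminant calls differ (both called
#' as plain bases at or above `qualityThreshold`), each overlapping
#' fragment votes with its base; majority across such sites assigns the
#' fragment, ties and fragments overlapping no differing site stay
#' unassigned. The three sets form a true partition of the fragments.
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param calls A [SiteCalls-class] with both tracks.
#' @param qualityThreshold Minimum PHRED quality for both calls at a
#'   differing site (default 30).
#' @return List: `endo`, `cont`, `unassigned` (integer fragment indices),
#'   `sites` (the differing sites used).
#' @export
partitionFragments <- function(fa, calls, qualityThreshold = 30) {
  cc <- calls@calls
  diffSites <- which(cc$endoBase %in% BASES & cc$contBase %in% BASES &
                     cc$endoBase != cc$contBase &
                     cc$endoPhred >= qualityThreshold &
                     cc$contPhred >= qualityThreshold)
  n <- nrow(fa@fragments)
  if (!length(diffSites)) {
    return(list(endo = integer(0), cont = integer(0),
                unassigned = seq_len(n),
                sites = cc[integer(0), c("ref0", "endoBase", "contBase")]))
  }
  obs <- fa@observations
  sel <- which(obs$ref0 %in% (diffSites - 1L) & obs$base <= 4L)
  o <- obs[sel, , drop = FALSE]
  eAll <- baseToInt(cc$endoBase[o$ref0 + 1L])
  cAll <- baseToInt(cc$contBase[o$ref0 + 1L])
  vE <- tabulate(o$frag[o$base == eAll], nbins = n)
  vC <- tabulate(o$frag[o$base == cAll], nbins = n)
  endo <- which(vE > vC)
  cont <- which(vC > vE)
  list(endo = endo, cont = cont,
       unassigned = setdiff(seq_len(n), c(endo, cont)),
       sites = data.frame(ref0 = diffSites - 1L,
                          endoBase = cc$endoBase[diffSites],
                          contBase = cc$contBase[diffSites],
                          stringsAsFactors = FALSE))
}

#' Re-estimate a deamination profile from a fragment set
#'
#' Measures per-position substitution rates from the template at each end
#' (molecule orientation) over the given fragments. The template is the
#' respective inferred consensus by default (avoids divergence-driven
#' false damage); pass `useReference = TRUE` for the literal mapping
#' reference.
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param fragSet Integer indices of the fragments to use.
#' @param calls [SiteCalls-class] providing the template track.
#' @param track `"endo"` or `"cont"` template.
#' @param useReference Measure against the mapping reference instead.
#' @param maxDepth Positions modelled per end.
#' @param minFragments Below this set size the `previous` profile is
#'   returned unchanged with a warning.
#' @param previous Fallback [DeaminationProfile-class].
#' @return A [DeaminationProfile-class].
#' @export
refitDeamination <- function(fa, fragSet, calls = NULL,
                             track = c("endo", "cont"),
                             useReference = FALSE, maxDepth = 10L,
                             minFragments = 30L,
                             previous = deaminationProfile(maxDepth = maxDepth)) {
  track <- match.arg(track)
  if (length(fragSet) < minFragments) {
    warning("fragment set too small (", length(fragSet),
            " < ", minFragments, "); keeping previous profile")
    return(previous)
  }
  tmplChar <- if (useReference || is.null(calls)) {
    strsplit(fa@refSeq, "", fixed = TRUE)[[1L]]
  } else {
    cc <- calls@calls
    if (track == "endo") cc$endoBase else cc$contBase
  }
  tmplInt <- baseToInt(tmplChar)
  obs <- fa@observations
  sel <- which(obs$frag %in% fragSet & obs$base <= 4L)
  o <- obs[sel, , drop = FALSE]
  tfwd <- tmplInt[o$ref0 + 1L]
  tm <- ifelse(o$flip, COMP[tfwd], tfwd)
  ro <- ifelse(o$flip, COMP[o$base], o$base)
  ok <- !is.na(tm)
  measure <- function(endDist, otherDist) {
    m <- matrix(0, maxDepth, 12L, dimnames = list(NULL, SUBS))
    use <- ok & (endDist < maxDepth - 1L |
                   (endDist >= maxDepth - 1L & otherDist >= maxDepth - 1L))
    if (!any(use)) return(m)
    pos <- pmin(endDist[use], maxDepth - 1L)
    countRates(m, pos, tm[use], ro[use], o$eps[use], maxDepth)
  }
  ends <- correctAdditiveBaseline(measure(o$d5, o$d3), measure(o$d3, o$d5))
  new("DeaminationProfile", end5 = ends$end5, end3 = ends$end3)
}

#' Re-fit the log-normal fragment length mixture
#'
#' Closed-form maximum-likelihood fit per set: \eqn{\mu =} mean of log
#' lengths, \eqn{\sigma =} their standard deviation (floored at
#' `sigmaFloor`). A set smaller than `minFragments` keeps the previous
#' parameters for that side.
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param endoSet,contSet Integer fragment indices.
#' @param previous Fallback [FragmentLengthModel-class].
#' @param minFragments Minimum set size per side.
#' @param sigmaFloor Lower bound on each scale parameter.
#' @return A [FragmentLengthModel-class] (enabled).
#' @export
refitLengthModel <- function(fa, endoSet, contSet,
                             previous = fragmentLengthModel(),
                             minFragments = 30L, sigmaFloor = 0.01) {
  fitSide <- function(set, mu0, sig0) {
    if (length(set) < minFragments) return(c(mu0, sig0))
    ll <- log(fa@fragments$len[set])
    c(mean(ll), max(stats::sd(ll), sigmaFloor, na.rm = TRUE))
  }
  e <- fitSide(endoSet, previous@muEndo, previous@sigmaEndo)
  c2 <- fitSide(contSet, previous@muCont, previous@sigmaCont)
  fragmentLengthModel(muEndo = e[1L], sigmaEndo = e[2L],
                      muCont = c2[1L], sigmaCont = c2[2L], enabled = TRUE)
}
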