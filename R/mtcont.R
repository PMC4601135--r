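## Per-nucleotide contamination rate and contaminant source from a
## database of candidate genomes, given the consensus caller's per-site
## endogenous base marginals.

#' Sites where the endogenous call and a candidate contaminant differ
#'
#' A site is informative when the MAP endogenous base is a plain
#' nucleotide, the candidate's base is neither a gap nor `N`, and the
#' endogenous base lies outside the candidate's IUPAC set.
#'
#' @param endoCalls A [SiteCalls-class] object.
#' @param contSeq Gapped candidate sequence (reference coordinates).
#' @param minPhred Minimum endogenous consensus quality at the site.
#' @return data.frame: `ref0`, `endo`, `cont` (alleles differ at every
#'   listed site); zero rows when the candidate is indistinguishable.
#' @export
informativeSites <- function(endoCalls, contSeq, minPhred = 0) {
  cc <- endoCalls@calls
  ch <- strsplit(toupper(contSeq), "", fixed = TRUE)[[1L]]
  if (length(ch) != nrow(cc))
    stop("contaminant sequence length does not match the call track")
  iupac <- Biostrings::IUPAC_CODE_MAP
  ok <- cc$coverage > 0L & cc$endoBase %in% BASES & cc$endoPhred >= minPhred &
    ch %in% names(iupac) & ch != "N"
  idx <- which(ok)
  if (!length(idx))
    return(data.frame(ref0 = integer(0), endo = character(0),
                      cont = character(0)))
  inSet <- mapply(function(e, code) grepl(e, iupac[[code]], fixed = TRUE),
                  cc$endoBase[idx], ch[idx])
  idx <- idx[!inSet]
  data.frame(ref0 = cc$ref0[idx], endo = cc$endoBase[idx], cont = ch[idx],
             stringsAsFactors = FALSE)
}

#' Likelihood of a pileup column over the contamination-rate grid
#'
#' For one site, the mixture \eqn{(1-c_r)P_e[r|b_e] + c_r P_c[r|c]}
#' marginalized over the endogenous base with the consensus marginals as
#' prior and over the contaminant base with the database's (IUPAC-uniform)
#' probabilities, wrapped with the mapping term. The endogenous branch uses
#' the deamination model; the contaminant branch sequencing errors only.
#'
#' @param column data.frame as in [siteJointPosterior()] (columns `base`,
#'   `eps`, `d5`, `d3`, `flip`, `m`).
#' @param endoMarginal Length-4 prior \eqn{P[b_e]} (consensus marginals).
#' @param contProbs Length-4 prior \eqn{P[c]} from the database record.
#' @param cr Contamination rate(s) in \[0, 1\].
#' @param priors An [EndoPriors-class] (endogenous deamination profile).
#' @param err 4x4 substitution error matrix.
#' @return Numeric log-likelihood, one per value of `cr`.
#' @export
siteRateLikelihood <- function(column, endoMarginal, contProbs, cr, priors,
                               err = uniformErrorModel()) {
  base <- if (is.character(column$base)) baseToInt(column$base)
          else as.integer(column$base)
  keep <- which(!is.na(base) & base <= 4L)
  o <- column[keep, , drop = FALSE]
  base <- base[keep]
  if (!length(base)) return(rep(0, length(cr)))
  ratesE <- deamRateMatrix(priors@endoProfile, o$d5, o$d3, o$flip)
  zero <- matrix(0, length(base), 12L)
  PE <- allTemplateProbs(base, o$eps, ratesE, err)
  PN <- allTemplateProbs(base, o$eps, zero, err)
  a <- as.numeric(PE %*% endoMarginal)    # endogenous branch, Eq-mixture
  b <- as.numeric(PN %*% contProbs)       # contaminant branch, error-only
  m <- o$m
  vapply(cr, function(cc) {
    v <- (1 - m) * ((1 - cc) * a + cc * b) + m * 0.25
    sum(log(pmax(v, 1e-300)))
  }, 0)
}

#' Estimate contamination against a database of candidate genomes
#'
#' For every candidate record, accumulates [siteRateLikelihood()] over the
#' union of informative sites across the database (so per-genome
#' likelihoods are comparable), normalizes over an evenly spaced rate grid
#' with a uniform prior, and reports the MAP rate with a 95\% HPD interval
#' for the most likely contaminant. Candidates with no informative sites of
#' their own are flagged degenerate and excluded from ranking. When
#' `includePredicted` is set, the consensus caller's contaminant track
#' (masked to `N` below `predictedPhred`) joins the database as an
#' additional record.
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param endoCalls A [SiteCalls-class] from [callConsensus()].
#' @param db Named character vector of gapped candidate sequences
#'   ([readContaminantDB()]), or `NULL` when only the predicted
#'   contaminant is used.
#' @param priors An [EndoPriors-class] object.
#' @param gridStep Rate grid resolution.
#' @param includePredicted Append the predicted contaminant consensus.
#' @param predictedCalls [SiteCalls-class] supplying the predicted
#'   contaminant (defaults to `endoCalls`, whose contaminant track it is).
#' @param predictedPhred Quality mask threshold for the predicted record.
#' @param err 4x4 substitution error matrix.
#' @return A [ContaminationEstimate-class] object.
#' @export
estimateContamination <- function(fa, endoCalls, db = NULL, priors,
                                  gridStep = 0.005, includePredicted = FALSE,
                                  predictedCalls = NULL,
                                  predictedPhred = 200, err = uniformErrorModel()) {
  records <- if (is.null(db)) character(0) else db
  if (includePredicted) {
    pc <- if (is.null(predictedCalls)) endoCalls else predictedCalls
    pred <- contSequence(pc, qualityFilter = predictedPhred)
    records <- c(records, predicted_contaminant = pred)
  }
  if (!length(records))
    stop("contaminant database empty and no predicted contaminant supplied")

  siteList <- lapply(records, informativeSites, endoCalls = endoCalls)
  degenerate <- vapply(siteList, nrow, 0L) == 0L
  if (all(degenerate))
    stop("no informative sites: every candidate matches the endogenous call")
  union0 <- sort(unique(unlist(lapply(siteList, `[[`, "ref0"))))

  obs <- fa@observations
  atUnion <- which(obs$ref0 %in% union0 & obs$base <= 4L)
  o <- obs[atUnion, , drop = FALSE]
  o$m <- fa@fragments$m[o$frag]
  ratesE <- deamRateMatrix(priors@endoProfile, o$d5, o$d3, o$flip)
  zero <- matrix(0, nrow(o), 12L)
  PE <- allTemplateProbs(o$base, o$eps, ratesE, err)
  PN <- allTemplateProbs(o$base, o$eps, zero, err)
  W <- endoMarginals(endoCalls)
  aVec <- rowSums(PE * W[o$ref0 + 1L, , drop = FALSE])

  grid <- seq(0, 1, by = gridStep)
  tab <- data.frame(name = names(records), logLik = NA_real_,
                    map = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                    informativeSites = vapply(siteList, nrow, 0L),
                    degenerate = degenerate, stringsAsFactors = FALSE)
  curves <- vector("list", length(records))
  for (g in seq_along(records)) {
    if (degenerate[g]) next
    CP <- contaminantBaseProbs(records[[g]])
    cp <- CP[o$ref0 + 1L, , drop = FALSE]
    known <- rowSums(cp) > 0            # skip the record's gaps/Ns
    if (!any(known)) { tab$degenerate[g] <- TRUE; next }
    bVec <- rowSums(PN[known, , drop = FALSE] * cp[known, , drop = FALSE])
    av <- aVec[known]; mv <- o$m[known]
    ll <- vapply(grid, function(cc) {
      v <- (1 - mv) * ((1 - cc) * av + cc * bVec) + mv * 0.25
      sum(log(pmax(v, 1e-300)))
    }, 0)
    curves[[g]] <- posteriorCurve(grid, ll)
    tab$logLik[g] <- max(ll)
    tab$map[g] <- curves[[g]]@map
    tab$ciLow[g] <- curves[[g]]@ciLow
    tab$ciHigh[g] <- curves[[g]]@ciHigh
  }
  usable <- which(!tab$degenerate)
  if (!length(usable))
    stop("no informative sites: every candidate matches the endogenous call")
  best <- usable[which.max(tab$logLik[usable])]
  new("ContaminationEstimate", rate = tab$map[best], ciLow = tab$ciLow[best],
      ciHigh = tab$ciHigh[best], bestContaminant = tab$name[best],
      table = tab, curve = curves[[best]])
}

#' Contamination from diagnostic-position base counts
#'
#' At diagnostic positions (fixed differences between the endogenous
#' lineage and present-day humans), contamination on a per-nucleotide basis
#' is simply the fraction of bases supporting the contaminant allele.
#'
#' @param endoCount Bases supporting the endogenous allele.
#' @param contCount Bases supporting the contaminant allele.
#' @return List: `rate` (fraction), `percent` (rounded to one decimal).
#' @examples
#' diagnosticRatio(2443418, 1989785)$percent   # 44.9
#' @export
diagnosticRatio <- function(endoCount, contCount) {
  stopifnot(endoCount >= 0, contCount >= 0)
  if (endoCount + contCount == 0)
    stop("no bases at diagnostic positions")
  rate <- contCount / (endoCount + contCount)
  list(rate = rate, percent = round(100 * rate, 1))
}
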