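## Joint per-site inference of the endogenous base b_e and the contaminant
## base b_c over Omega^2, with per-fragment endogenous probabilities from
## deamination and fragment-length evidence.

#' Observation likelihood under a named template
#'
#' \eqn{P[r_i | b, M]} for the endogenous branch (endogenous deamination
#' profile) or the contaminant branch (contaminant profile, typically
#' all-zero), combining deamination and sequencing-error substitution
#' probabilities.
#'
#' @param observed,template Bases (character or integer 1..4).
#' @param eps Base-caller error probability.
#' @param dist5,dist3 Distances from the fragment ends (molecule
#'   orientation).
#' @param reverse Reverse-strand flag (complements substitution types).
#' @param which `"endogenous"` or `"contaminant"` branch.
#' @param priors An [EndoPriors-class] object.
#' @param err 4x4 substitution error matrix.
#' @return Numeric probability(ies).
#' @export
pObsGivenTemplate <- function(observed, template, eps, dist5, dist3,
                              reverse = FALSE,
                              which = c("endogenous", "contaminant"),
                              priors, err = uniformErrorModel()) {
  which <- match.arg(which)
  prof <- if (which == "endogenous") priors@endoProfile else priors@contProfile
  pDeam(template, observed, eps, prof, dist5, dist3, reverse, err)
}

#' Observation likelihood given an (endogenous, contaminant) base pair
#'
#' \eqn{(1-m)[p_E P_e(r|b_e) + (1-p_E) P_c(r|b_c)] + m/4} where \eqn{p_E}
#' is the fragment's prior probability of being endogenous and \eqn{m} its
#' mismapping probability; a mismapped fragment is uninformative about
#' either template.
#'
#' @inheritParams pObsGivenTemplate
#' @param bEndo,bCont Endogenous and contaminant candidate bases.
#' @param pEndoFragment \eqn{P[R_j \in E]} for the fragment.
#' @param m Mismapping probability \eqn{10^{-MAPQ/10}}.
#' @return Numeric probability(ies).
#' @examples
#' pr <- endoPriors()
#' pObsGivenPair("A", "A", "C", eps = 0, dist5 = 5, dist3 = 5,
#'               pEndoFragment = 1, m = 1, priors = pr)   # 0.25
#' @export
pObsGivenPair <- function(observed, bEndo, bCont, eps, dist5, dist3,
                          reverse = FALSE, pEndoFragment, m, priors,
                          err = uniformErrorModel()) {
  pe <- pObsGivenTemplate(observed, bEndo, eps, dist5, dist3, reverse,
                          "endogenous", priors, err)
  pc <- pObsGivenTemplate(observed, bCont, eps, dist5, dist3, reverse,
                          "contaminant", priors, err)
  (1 - m) * (pEndoFragment * pe + (1 - pEndoFragment) * pc) + m * 0.25
}

## ---------------------------------------------------------------------------
## Fragment-level endogenous evidence
## ---------------------------------------------------------------------------

## Site-by-4 weight matrix (1 - P[not b_e]) used in the fragment
## classification sums: previous-iteration endogenous marginals, or an
## indicator on the reference base before any consensus exists.
siteWeights <- function(fa, endoCalls = NULL) {
  L <- nchar(fa@refSeq)
  if (!is.null(endoCalls)) return(endoMarginals(endoCalls))
  refInt <- refIntVector(fa)
  W <- matrix(0.25, L, 4L)
  ok <- !is.na(refInt)
  W[ok, ] <- 0
  W[cbind(which(ok), refInt[ok])] <- 1
  W
}

#' Fragment-is-endogenous posterior from deamination evidence
#'
#' For every fragment, the probability that its base pattern arose under
#' the deamination + error model rather than the error-only model,
#' marginalized over the endogenous base at each site with weights from the
#' consensus marginals (the reference base at iteration 0), combined with
#' the contamination prior \eqn{c_c}:
#' \eqn{(1-c_c)P[R|M_{deam}] / ((1-c_c)P[R|M_{deam}] + c_c P[R|M_{null}])}.
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param priors An [EndoPriors-class] object.
#' @param endoCalls Optional previous-iteration [SiteCalls-class].
#' @param err 4x4 substitution error matrix.
#' @return Numeric vector, one posterior per fragment.
#' @export
pFragmentDeamPosterior <- function(fa, priors, endoCalls = NULL,
                                   err = uniformErrorModel()) {
  ll <- fragmentModelLogLiks(fa, priors, endoCalls, err)
  cc <- priors@contamination
  posteriorFromLogs(ll$deam, ll$null, cc)
}

## log P[R_j | M_deam] and log P[R_j | M_null] per fragment.
fragmentModelLogLiks <- function(fa, priors, endoCalls = NULL,
                                 err = uniformErrorModel()) {
  obs <- fa@observations
  use <- which(obs$base <= 4L)
  o <- obs[use, , drop = FALSE]
  W <- siteWeights(fa, endoCalls)
  ratesE <- deamRateMatrix(priors@endoProfile, o$d5, o$d3, o$flip)
  zero <- matrix(0, length(use), 12L)
  PD <- allTemplateProbs(o$base, o$eps, ratesE, err)
  PN <- allTemplateProbs(o$base, o$eps, zero, err)
  Wo <- W[o$ref0 + 1L, , drop = FALSE]
  pd <- rowSums(PD * Wo)
  pn <- rowSums(PN * Wo)
  n <- nrow(fa@fragments)
  list(deam = groupSum(log(pmax(pd, 1e-300)), o$frag, n),
       null = groupSum(log(pmax(pn, 1e-300)), o$frag, n))
}

posteriorFromLogs <- function(la, lb, prior) {
  ## (1-prior) e^la / ((1-prior) e^la + prior e^lb), safe in log space
  if (prior <= 0) return(rep(1, length(la)))
  if (prior >= 1) return(rep(0, length(la)))
  1 / (1 + exp(log(prior) - log1p(-prior) + lb - la))
}

#' Fragment-is-endogenous posterior from length evidence
#'
#' Log-normal densities of the endogenous and contaminant length
#' distributions weighted by the contamination prior. With the model
#' disabled, length is uninformative and the prior \eqn{1 - c_c} is
#' returned.
#'
#' @param l Fragment length(s), \eqn{\ge 1}.
#' @param model A [FragmentLengthModel-class].
#' @param cc Contamination prior.
#' @return Numeric posterior(s).
#' @export
pFragmentLengthPosterior <- function(l, model, cc) {
  if (!model@enabled) return(rep(1 - cc, length(l)))
  le <- stats::dlnorm(l, model@muEndo, model@sigmaEndo, log = TRUE)
  lc <- stats::dlnorm(l, model@muCont, model@sigmaCont, log = TRUE)
  posteriorFromLogs(le, lc, cc)
}

#' Combined fragment-is-endogenous probability
#'
#' Deamination and length evidence enter as class-conditional likelihoods
#' multiplied together, with the contamination prior applied once
#' (chaining the two posteriors would square the prior).
#'
#' @inheritParams pFragmentDeamPosterior
#' @return Numeric vector, one \eqn{P[R_j \in E]} per fragment.
#' @export
pFragmentEndogenous <- function(fa, priors, endoCalls = NULL,
                                err = uniformErrorModel()) {
  ll <- fragmentModelLogLiks(fa, priors, endoCalls, err)
  lm <- priors@lengthModel
  l <- fa@fragments$len
  if (lm@enabled) {
    le <- stats::dlnorm(l, lm@muEndo, lm@sigmaEndo, log = TRUE)
    lc <- stats::dlnorm(l, lm@muCont, lm@sigmaCont, log = TRUE)
  } else {
    le <- lc <- numeric(length(l))
  }
  posteriorFromLogs(ll$deam + le, ll$null + lc, priors@contamination)
}

## ---------------------------------------------------------------------------
## Site-level joint posterior
## ---------------------------------------------------------------------------

## Core kernel shared by callConsensus and siteJointPosterior: given
## per-observation quantities, return the L x 16 joint log-likelihood
## matrix (pairs in (b_e-major, b_c-minor) order), before normalization.
jointLogLik <- function(site, PE, PC, pe, m, nSites) {
  ae <- (1 - m) * pe
  bcw <- (1 - m) * (1 - pe)
  mterm <- m * 0.25
  J <- matrix(0, nSites, 16L)
  for (be in 1:4) {
    aeCol <- ae * PE[, be]
    for (bc in 1:4) {
      v <- aeCol + bcw * PC[, bc] + mterm
      J[, (be - 1L) * 4L + bc] <- groupSum(log(pmax(v, 1e-300)), site, nSites)
    }
  }
  J
}

## Normalize a joint log-likelihood matrix into calls. Flat prior 1/16
## cancels in the normalization. Returns the per-site summary data.frame.
summarizeJoint <- function(J, coverage, refChar) {
  lse <- logRowSumExp(J)
  endoIdx <- lapply(1:4, function(be) (be - 1L) * 4L + 1:4)
  contIdx <- lapply(1:4, function(bc) bc + 4L * 0:3)
  eM <- matrix(vapply(endoIdx, function(ix)
    logRowSumExp(J[, ix, drop = FALSE]), lse), nrow = nrow(J))
  cM <- matrix(vapply(contIdx, function(ix)
    logRowSumExp(J[, ix, drop = FALSE]), lse), nrow = nrow(J))
  eP <- exp(eM - lse)
  cP <- exp(cM - lse)
  eP <- eP / rowSums(eP)
  cP <- cP / rowSums(cP)
  eCall <- max.col(eP, ties.method = "first")
  cCall <- max.col(cP, ties.method = "first")
  eErr <- 1 - eP[cbind(seq_len(nrow(eP)), eCall)]
  cErr <- 1 - cP[cbind(seq_len(nrow(cP)), cCall)]
  empty <- coverage == 0L
  d <- data.frame(
    ref0 = seq_len(nrow(J)) - 1L, refBase = refChar,
    endoBase = ifelse(empty, "N", BASES[eCall]),
    endoErr = ifelse(empty, 1, eErr),
    endoPhred = ifelse(empty, 0, probToPhred(eErr)),
    contBase = ifelse(empty, "N", BASES[cCall]),
    contErr = ifelse(empty, 1, cErr),
    contPhred = ifelse(empty, 0, probToPhred(cErr)),
    coverage = coverage,
    stringsAsFactors = FALSE)
  d[, c("eA", "eC", "eG", "eT")] <- eP
  d[, c("cA", "cC", "cG", "cT")] <- cP
  d
}

#' Joint posterior for a single pileup column
#'
#' Computes \eqn{P[b_e, b_c | R]} over the 16 base pairs for one site from
#' per-observation contexts, with flat prior \eqn{1/16}; marginalizes for
#' the endogenous and contaminant calls and their error probabilities.
#' An empty column yields the uniform joint and `N` calls with PHRED 0.
#'
#' @param column data.frame with one row per overlapping observation:
#'   `base` (character or 1..4), `eps`, `d5`, `d3`, `flip` (logical),
#'   `m` (mismapping probability), `pEndo` (fragment endogenous
#'   probability).
#' @param priors An [EndoPriors-class] object.
#' @param err 4x4 substitution error matrix.
#' @return List: `joint` (4x4 matrix of pair posteriors, rows b_e),
#'   `endoMarginal`, `contMarginal` (named length-4), `endoBase`,
#'   `contBase`, `endoErr`, `contErr`, `endoPhred`, `contPhred`.
#' @export
siteJointPosterior <- function(column, priors, err = uniformErrorModel()) {
  if (is.null(column) || nrow(column) == 0L) {
    joint <- matrix(1 / 16, 4, 4, dimnames = list(BASES, BASES))
    u <- stats::setNames(rep(0.25, 4), BASES)
    return(list(joint = joint, endoMarginal = u, contMarginal = u,
                endoBase = "N", contBase = "N", endoErr = 1, contErr = 1,
                endoPhred = 0, contPhred = 0))
  }
  base <- if (is.character(column$base)) baseToInt(column$base)
          else as.integer(column$base)
  keep <- which(base <= 4L & !is.na(base))
  o <- column[keep, , drop = FALSE]
  base <- base[keep]
  ratesE <- deamRateMatrix(priors@endoProfile, o$d5, o$d3, o$flip)
  ratesC <- deamRateMatrix(priors@contProfile, o$d5, o$d3, o$flip)
  PE <- allTemplateProbs(base, o$eps, ratesE, err)
  PC <- allTemplateProbs(base, o$eps, ratesC, err)
  J <- jointLogLik(rep(1L, length(base)), PE, PC, o$pEndo, o$m, 1L)
  lse <- logSumExp(J[1L, ])
  joint <- matrix(exp(J[1L, ] - lse), 4, 4, byrow = TRUE,
                  dimnames = list(BASES, BASES))
  s <- summarizeJoint(J, coverage = length(base), refChar = "N")
  list(joint = joint,
       endoMarginal = stats::setNames(as.numeric(s[1L, c("eA", "eC", "eG", "eT")]), BASES),
       contMarginal = stats::setNames(as.numeric(s[1L, c("cA", "cC", "cG", "cT")]), BASES),
       endoBase = s$endoBase, contBase = s$contBase,
       endoErr = s$endoErr, contErr = s$contErr,
       endoPhred = s$endoPhred, contPhred = s$contPhred)
}

#' Call the endogenous and contaminant consensus
#'
#' Runs the joint per-site caller over the whole reference: computes each
#' fragment's endogenous probability (deamination + length evidence under
#' the priors), then the 16-pair joint posterior at every site, and
#' marginalizes into the two consensus tracks. Sites with deletion or
#' insertion evidence are refined by the simplified indel model
#' ([siteIndelCall()]).
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param priors An [EndoPriors-class] object.
#' @param err 4x4 substitution error matrix.
#' @param prevCalls Optional previous-iteration [SiteCalls-class] whose
#'   endogenous marginals weight the fragment classification (the mapping
#'   reference is used at iteration 0).
#' @param indels Evaluate the indel extension where gap/insertion
#'   observations exist.
#' @return A [SiteCalls-class] object holding both tracks.
#' @export
callConsensus <- function(fa, priors, err = uniformErrorModel(),
                          prevCalls = NULL, indels = TRUE) {
  L <- nchar(fa@refSeq)
  obs <- fa@observations
  pe <- pFragmentEndogenous(fa, priors, prevCalls, err)
  use <- which(obs$base <= 4L)
  o <- obs[use, , drop = FALSE]
  ratesE <- deamRateMatrix(priors@endoProfile, o$d5, o$d3, o$flip)
  ratesC <- deamRateMatrix(priors@contProfile, o$d5, o$d3, o$flip)
  PE <- allTemplateProbs(o$base, o$eps, ratesE, err)
  PC <- allTemplateProbs(o$base, o$eps, ratesC, err)
  m <- fa@fragments$m[o$frag]
  peo <- pe[o$frag]
  J <- jointLogLik(o$ref0 + 1L, PE, PC, peo, m, L)
  coverage <- tabulate(o$ref0 + 1L, nbins = L)
  refChar <- strsplit(fa@refSeq, "", fixed = TRUE)[[1L]]
  d <- summarizeJoint(J, coverage, refChar)

  if (indels) {
    gapSites <- unique(obs$ref0[obs$base == GAP_CODE])
    for (s0 in gapSites) {
      ic <- siteIndelCall(pileupColumn(fa, s0, pe), priors)
      if (isTRUE(ic$endoDeletion)) {
        d$endoBase[s0 + 1L] <- "-"
        d$endoErr[s0 + 1L] <- ic$endoErr
        d$endoPhred[s0 + 1L] <- probToPhred(ic$endoErr)
      }
      if (isTRUE(ic$contDeletion)) {
        d$contBase[s0 + 1L] <- "-"
        d$contErr[s0 + 1L] <- ic$contErr
        d$contPhred[s0 + 1L] <- probToPhred(ic$contErr)
      }
    }
  }
  new("SiteCalls", refName = fa@refName, calls = d)
}

## Extract one site's observations as a column data.frame (with fragment
## m and pEndo attached), including deletion gap rows.
pileupColumn <- function(fa, ref0, pEndo = NULL) {
  obs <- fa@observations
  sel <- which(obs$ref0 == ref0)
  o <- obs[sel, , drop = FALSE]
  o$m <- fa@fragments$m[o$frag]
  o$pEndo <- if (is.null(pEndo)) rep(1, nrow(o)) else pEndo[o$frag]
  o
}

#' Simplified per-site indel call
#'
#' Deletions extend the symbol set at a site with a gap symbol: a read
#' covering the site supports the gap if its alignment deletes the base,
#' with a binary error channel at the neighbouring base quality
#' (\eqn{P[gap|gap] = 1-\epsilon}; a spurious gap arises with probability
#' \eqn{\epsilon}; given a gap template, residual bases are uniform).
#' Insertions are keyed on observed insertion strings with a flat prior
#' over the observed strings plus "no insertion", through the same joint
#' (endogenous, contaminant) machinery. This is a deliberately simplified
#' stand-in for a full indel likelihood model.
#'
#' @param column data.frame as in [siteJointPosterior()] (gap rows carry
#'   `base = 5`); for insertion calling attach `attr(column, "insertions")`
#'   as a data.frame with `seq`, `eps`, `m`, `pEndo`, `frag` and
#'   `attr(column, "nCovering")` fragments spanning the junction.
#' @param priors An [EndoPriors-class] object.
#' @return List: `endoDeletion`, `contDeletion` (logical), `endoErr`,
#'   `contErr`; and when insertion evidence exists `endoInsertion`,
#'   `contInsertion` (called strings, `""` = none).
#' @export
siteIndelCall <- function(column, priors) {
  out <- list(endoDeletion = FALSE, contDeletion = FALSE,
              endoErr = 1, contErr = 1,
              endoInsertion = "", contInsertion = "")
  if (!is.null(column) && nrow(column)) {
    isGap <- column$base == GAP_CODE
    if (any(isGap)) {
      ## two-symbol channel per template class {base, gap}
      pGapGivenGap <- 1 - column$eps
      pGapGivenBase <- column$eps
      pBaseGivenGap <- column$eps / 4
      pBaseGivenBase <- 1 - column$eps
      pg <- ifelse(isGap, pGapGivenGap, pBaseGivenGap)
      pb <- ifelse(isGap, pGapGivenBase, pBaseGivenBase)
      m <- column$m; pe <- column$pEndo
      half <- 0.5 * m                       # uninformative if mismapped
      ll <- function(eGap, cGap) {
        ve <- if (eGap) pg else pb
        vc <- if (cGap) pg else pb
        sum(log(pmax((1 - m) * (pe * ve + (1 - pe) * vc) + half, 1e-300)))
      }
      J <- c(`bb` = ll(FALSE, FALSE), `bg` = ll(FALSE, TRUE),
             `gb` = ll(TRUE, FALSE), `gg` = ll(TRUE, TRUE))
      P <- exp(J - logSumExp(J))
      pEndoGap <- P[["gb"]] + P[["gg"]]
      pContGap <- P[["bg"]] + P[["gg"]]
      out$endoDeletion <- pEndoGap > 0.5
      out$contDeletion <- pContGap > 0.5
      out$endoErr <- if (out$endoDeletion) 1 - pEndoGap else pEndoGap
      out$contErr <- if (out$contDeletion) 1 - pContGap else pContGap
    }
  }
  ins <- attr(column, "insertions")
  if (!is.null(ins) && nrow(ins)) {
    nCov <- attr(column, "nCovering")
    if (is.null(nCov)) nCov <- nrow(ins)
    cand <- c("", unique(ins$seq))
    obsStr <- c(ins$seq, rep("", max(0L, nCov - nrow(ins))))
    epsv <- c(ins$eps, rep(stats::median(ins$eps), max(0L, nCov - nrow(ins))))
    mv <- c(ins$m, rep(stats::median(ins$m), max(0L, nCov - nrow(ins))))
    pev <- c(ins$pEndo, rep(stats::median(ins$pEndo), max(0L, nCov - nrow(ins))))
    lik <- function(s) ifelse(obsStr == s, 1 - epsv, epsv / length(cand))
    J <- matrix(0, length(cand), length(cand))
    for (a in seq_along(cand)) for (b in seq_along(cand)) {
      v <- (1 - mv) * (pev * lik(cand[a]) + (1 - pev) * lik(cand[b])) +
        mv / length(cand)
      J[a, b] <- sum(log(pmax(v, 1e-300)))
    }
    P <- exp(J - logSumExp(J))
    eMarg <- rowSums(P)
    cMarg <- colSums(P)
    out$endoInsertion <- cand[which.max(eMarg)]
    out$contInsertion <- cand[which.max(cMarg)]
  }
  out
}
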