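## Contamination prior from deamination patterns.
##
## Rationale: only endogenous molecules carry post-mortem terminal
## deamination. Conditioning on one fragment end being deaminated selects a
## (nearly) endogenous subset whose *other* end yields the endogenous
## per-position damage rates; the mixture weight that best explains the
## whole dataset's fragments under deaminated-vs-error-only models is the
## contamination prior.

## deamination substitution expected at each end, molecule orientation
protocolSubstitutions <- function(protocol) {
  if (protocol == "single")
    list(end5 = c(from = 2L, to = 4L), end3 = c(from = 2L, to = 4L))   # C>T / C>T
  else
    list(end5 = c(from = 2L, to = 4L), end3 = c(from = 3L, to = 1L))   # C>T / G>A
}

## Identifiability correction for the additive two-end damage model.
## Raw per-end rates measured by distance from one end each absorb the
## other end's interior baseline (raw5(p) = f(p) + g_inf), so summing the
## two ends double-counts the baseline. Subtracting half of the shared
## asymptote from every row of both ends makes end5 + end3 reproduce the
## measured total rate at every (d5, d3). Applied only when the profile is
## deep enough for the asymptote to be identified.
correctAdditiveBaseline <- function(end5, end3, minDepth = 6L) {
  if (nrow(end5) < minDepth || nrow(end3) < minDepth)
    return(list(end5 = end5, end3 = end3))
  tailRows <- function(m) colMeans(m[(nrow(m) - 1L):nrow(m), , drop = FALSE])
  asym <- (tailRows(end5) + tailRows(end3)) / 2
  adj <- function(m) {
    m <- sweep(m, 2L, asym / 2, "-")
    m[m < 0] <- 0
    m
  }
  list(end5 = adj(end5), end3 = adj(end3))
}

## Shared counting kernel for per-position substitution rates. Observed
## mismatch rates include a sequencing-error floor of roughly eps/3 per
## ordered substitution; the expected error-driven count is subtracted
## from the numerator so the profile estimates deamination alone.
countRates <- function(m, pos, tm, ro, eps, maxDepth) {
  denom <- matrix(0, maxDepth, 4L)
  tt <- table(factor(pos, levels = 0:(maxDepth - 1L)),
              factor(tm, levels = 1:4))
  denom[] <- as.numeric(tt)
  errFloor <- numeric(maxDepth)
  efs <- rowsum(eps / 3, group = pos)
  errFloor[as.integer(rownames(efs)) + 1L] <- efs[, 1L]
  mis <- tm != ro
  if (any(mis)) {
    sub <- SUB_IDX[cbind(tm[mis], ro[mis])]
    cnt <- table(factor(pos[mis], levels = 0:(maxDepth - 1L)),
                 factor(sub, levels = 1:12))
    num <- matrix(as.numeric(cnt), maxDepth, 12L)
    for (s in 1:12) {
      from <- ((s - 1L) %/% 3L) + 1L
      d <- denom[, from]
      ## error floor scaled to this template's share of the column
      ef <- errFloor * ifelse(rowSums(denom) > 0,
                              d / pmax(rowSums(denom), 1), 0)
      m[, s] <- ifelse(d > 0, pmax(num[, s] - ef, 0) / d, 0)
    }
  }
  m
}

## Molecule-space template (reference base, complemented for flipped obs)
## and molecule-space observed base for every observation.
moleculeSpace <- function(fa) {
  obs <- fa@observations
  refInt <- refIntVector(fa)
  tfwd <- refInt[obs$ref0 + 1L]
  list(tmpl = ifelse(obs$flip, COMP[tfwd], tfwd),
       robs = ifelse(obs$flip & obs$base <= 4L, COMP[obs$base], obs$base))
}

#' Estimate endogenous deamination rates by end-conditioning
#'
#' For each fragment end, selects the fragments whose *opposite* end's
#' terminal base (within `window` positions) shows the library protocol's
#' deamination substitution against the reference (C>T at 5'; C>T at 3' for
#' single-stranded, G>A at 3' for double-stranded), and measures
#' per-position substitution rates from the reference on the selected set.
#' The reference sequence acts as the endogenous template.
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param protocol `"single"` or `"double"`.
#' @param maxDepth Positions modelled per end.
#' @param window Number of terminal positions inspected when conditioning
#'   (default 1: the terminal base itself).
#' @return List: `profile` (a [DeaminationProfile-class]),
#'   `nConditioning5`, `nConditioning3` (fragments conditioning each end's
#'   measurement).
#' @export
estimateConditionalDeamination <- function(fa, protocol = c("single", "double"),
                                           maxDepth = 10L, window = 1L) {
  protocol <- match.arg(protocol)
  subs <- protocolSubstitutions(protocol)
  obs <- fa@observations
  ms <- moleculeSpace(fa)
  valid <- !is.na(ms$tmpl) & obs$base <= 4L

  deamAtEnd <- function(endDist, sub) {
    hit <- valid & endDist < window & ms$tmpl == sub[["from"]] &
      ms$robs == sub[["to"]]
    unique(obs$frag[hit])
  }
  ## condition on 3' -> measure 5'; condition on 5' -> measure 3'
  cond3 <- deamAtEnd(obs$d3, subs$end3)
  cond5 <- deamAtEnd(obs$d5, subs$end5)
  if (length(cond3) == 0L && length(cond5) == 0L)
    stop("no fragment shows terminal deamination; supply a deamination ",
         "profile instead of estimating one")

  measure <- function(fragSet, endDist, otherDist) {
    m <- matrix(0, maxDepth, 12L, dimnames = list(NULL, SUBS))
    ## last row pools the deep interior (both ends far away): it backs the
    ## beyond-depth extrapolation, so it needs a large denominator
    sel <- valid & obs$frag %in% fragSet &
      (endDist < maxDepth - 1L |
         (endDist >= maxDepth - 1L & otherDist >= maxDepth - 1L))
    if (!any(sel)) return(m)
    pos <- pmin(endDist[sel], maxDepth - 1L)
    countRates(m, pos, ms$tmpl[sel], ms$robs[sel], obs$eps[sel], maxDepth)
  }
  ends <- correctAdditiveBaseline(measure(cond3, obs$d5, obs$d3),
                                  measure(cond5, obs$d3, obs$d5))
  prof <- new("DeaminationProfile", end5 = ends$end5, end3 = ends$end3)
  list(profile = prof, nConditioning5 = length(cond3),
       nConditioning3 = length(cond5))
}

#' Per-fragment alignment log-likelihoods
#'
#' `fragmentLogLikNull()` scores each fragment's aligned bases against the
#' reference under the sequencing-error-only model;
#' `fragmentLogLikDeam()` under the deamination + error model with the
#' given profile. Bases are independent; deletions are excluded.
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param profile A [DeaminationProfile-class].
#' @param err 4x4 substitution error matrix.
#' @param endWindow When positive, only bases within `endWindow` positions
#'   of either fragment end enter the product. Deamination evidence is
#'   concentrated there, and restricting the window keeps the per-fragment
#'   information roughly length-independent: because contaminant molecules
#'   are typically longer than endogenous ones, scoring whole fragments
#'   lets the (length-correlated) interior baseline dominate the mixture
#'   and bias the rate estimate. 0 scores every base.
#' @return Numeric vector: one log-likelihood per fragment.
#' @export
fragmentLogLikNull <- function(fa, err = uniformErrorModel(), endWindow = 0L) {
  fragmentLogLik(fa, rates = NULL, err = err, endWindow = endWindow)
}

#' @rdname fragmentLogLikNull
#' @export
fragmentLogLikDeam <- function(fa, profile, err = uniformErrorModel(),
                               endWindow = 0L) {
  fragmentLogLik(fa, profile = profile, err = err, endWindow = endWindow)
}

fragmentLogLik <- function(fa, profile = NULL, rates = NULL,
                           err = uniformErrorModel(), endWindow = 0L) {
  obs <- fa@observations
  refInt <- refIntVector(fa)
  tmpl <- refInt[obs$ref0 + 1L]
  keep <- !is.na(tmpl) & obs$base <= 4L
  if (endWindow > 0L)
    keep <- keep & (obs$d5 < endWindow | obs$d3 < endWindow)
  use <- which(keep)
  if (is.null(rates)) {
    rates <- if (is.null(profile))
      matrix(0, length(use), 12L, dimnames = list(NULL, SUBS))
    else deamRateMatrix(profile, obs$d5[use], obs$d3[use], obs$flip[use])
  }
  p <- templateObsProb(tmpl[use], obs$base[use], obs$eps[use], rates, err)
  groupSum(log(pmax(p, 1e-300)), obs$frag[use], nrow(fa@fragments))
}

#' Posterior over the contamination rate from deamination evidence
#'
#' Mixture over fragments: each fragment is endogenous (deaminated model)
#' with probability \eqn{1 - c_d} or contaminant (error-only model) with
#' probability \eqn{c_d}; a uniform prior on \eqn{c_d} over an evenly
#' spaced grid yields the posterior, its MAP and a 95\% HPD interval.
#'
#' @param fa A [FragmentAlignments-class] object.
#' @param profile Endogenous [DeaminationProfile-class] (typically from
#'   [estimateConditionalDeamination()]).
#' @param err 4x4 substitution error matrix.
#' @param gridStep Grid resolution in (0, 0.1\].
#' @param endWindow Terminal window entering the per-fragment products
#'   (default 5; see [fragmentLogLikNull()]). Terminal damage decays
#'   roughly two-fold per position, so a short window keeps nearly all of
#'   the deamination signal while minimizing exposure to
#'   endogenous/contaminant divergence sites that masquerade as damage.
#' @return A [PosteriorCurve-class]; `flat` is set when no fragment
#'   separates the two models (no deaminatable evidence).
#' @export
contaminationPosterior <- function(fa, profile, err = uniformErrorModel(),
                                   gridStep = 0.005, endWindow = 5L) {
  stopifnot(gridStep > 0, gridStep <= 0.1)
  ld <- fragmentLogLikDeam(fa, profile, err, endWindow = endWindow)
  ln <- fragmentLogLikNull(fa, err, endWindow = endWindow)
  grid <- seq(0, 1, by = gridStep)
  if (max(abs(ld - ln)) < 1e-12) {
    return(posteriorCurve(grid, rep(0, length(grid)), flat = TRUE))
  }
  ## log sum over the two-component mixture, numerically safe:
  ## log((1-c) e^ld + c e^ln) = mx + log((1-c) e^(ld-mx) + c e^(ln-mx))
  mx <- pmax(ld, ln)
  ed <- exp(ld - mx)
  en <- exp(ln - mx)
  logpost <- vapply(grid, function(cd) {
    w <- (1 - cd) * ed + cd * en
    sum(mx + log(pmax(w, 1e-300)))
  }, 0)
  posteriorCurve(grid, logpost)
}

#' Deamination-based contamination prior (one call)
#'
#' Convenience wrapper: estimate the conditional endogenous deamination
#' profile, then the contamination posterior, optionally writing the
#' artifacts (`<prefix>.cont.est` TSV, `<prefix>.endo.5p.prof` /
#' `.3p.prof`, `<prefix>.curve.tsv`).
#'
#' @inheritParams estimateConditionalDeamination
#' @inheritParams contaminationPosterior
#' @param outPrefix Optional output path prefix.
#' @return List: `profile`, `curve` (a [PosteriorCurve-class]),
#'   `nConditioning5`, `nConditioning3`.
#' @export
contDeamEstimate <- function(fa, protocol = c("single", "double"),
                             maxDepth = 10L, window = 1L,
                             err = uniformErrorModel(), gridStep = 0.005,
                             outPrefix = NULL) {
  protocol <- match.arg(protocol)
  est <- estimateConditionalDeamination(fa, protocol, maxDepth, window)
  curve <- contaminationPosterior(fa, est$profile, err, gridStep)
  if (!is.null(outPrefix)) {
    utils::write.table(
      data.frame(map = curve@map, ciLow = curve@ciLow, ciHigh = curve@ciHigh),
      paste0(outPrefix, ".cont.est"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeDeaminationProfile(est$profile, paste0(outPrefix, ".endo.5p.prof"),
                            paste0(outPrefix, ".endo.3p.prof"))
    writePosteriorCurve(curve, paste0(outPrefix, ".curve.tsv"))
  }
  list(profile = est$profile, curve = curve,
       nConditioning5 = est$nConditioning5,
       nConditioning3 = est$nConditioning3)
}
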