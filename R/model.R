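## Per-base observation likelihoods shared by every estimator.
##
## Two models for an observed base r against a template base b:
##   null  : differences arise from sequencing error only
##           P = (1-eps)        if b == r
##               eps * P[b->r|E] otherwise
##   deam  : differences arise from deamination or sequencing error
##           P = (1-eps) * (1 - sum_{b' != b} rate(b->b'))   if b == r
##               (1-eps) * rate(b->r) + eps * P[b->r|E]      otherwise
## The joint event "deamination AND sequencing error" is deliberately
## ignored (second-order, as in the underlying model).

#' Substitution error models
#'
#' A sequencing-error model is a 4x4 matrix `P[x -> y | E]` with zero
#' diagonal and rows summing to 1: the conditional probability that a
#' miscalled template `x` is read as `y`. `uniformErrorModel()` returns the
#' 1/3-per-alternative default; `readErrorModel()`/`writeErrorModel()`
#' exchange the matrix as TSV (columns `from`, `to`, `count`; counts are
#' normalized per source base).
#'
#' @param path TSV file path.
#' @param model 4x4 error matrix.
#' @return A 4x4 numeric matrix with `dimnames` `list(BASES, BASES)`.
#' @examples
#' uniformErrorModel()["C", "T"]   # 1/3
#' @export
uniformErrorModel <- function() {
  m <- matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- 0
  m
}

#' @rdname uniformErrorModel
#' @export
readErrorModel <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("from", "to", "count") %in% names(d)))
    stop("error-model TSV needs columns: from, to, count")
  m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  m[cbind(match(d$from, BASES), match(d$to, BASES))] <- d$count
  diag(m) <- 0
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("error model has a source base with no counts")
  m / rs
}

#' @rdname uniformErrorModel
#' @export
writeErrorModel <- function(model, path) {
  idx <- which(row(model) != col(model), arr.ind = TRUE)
  d <- data.frame(from = BASES[idx[, 1L]], to = BASES[idx[, 2L]],
                  count = model[idx])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged synthetic substitution-error matrix
#'
#' A mildly non-uniform stand-in for an empirical Illumina substitution
#' matrix (the real control-lane counts are not redistributable); labelled
#' synthetic. Used to exercise the empirical-matrix code path.
#'
#' @return 4x4 normalized error matrix.
#' @export
syntheticErrorModel <- function() {
  readErrorModel(system.file("extdata", "substitution_error_synthetic.tsv",
                             package = "mitoContam", mustWork = TRUE))
}

## ---------------------------------------------------------------------------
## Rate lookup
## ---------------------------------------------------------------------------

#' Combined deamination rates at a fragment position
#'
#' The rate for each substitution at a base is the sum of the 5'-end rate at
#' `dist5` and the 3'-end rate at `dist3` (the two terminal-damage supports
#' are nearly disjoint, so contributions add), clamped to \[0, 1\].
#' Distances beyond the profile depth use the last modelled row. Distances
#' are in original-molecule orientation; set `reverse = TRUE` for an
#' observation stored in reference-forward orientation from a
#' reverse-strand fragment, which complements the substitution types.
#'
#' @param profile A [DeaminationProfile-class].
#' @param dist5,dist3 Distances (0-based) from the 5'/3' fragment ends.
#' @param reverse Complement substitution types (reference-forward view of a
#'   reverse-strand fragment).
#' @return Named numeric vector of 12 substitution rates.
#' @examples
#' p <- deaminationProfile(maxDepth = 2)
#' p@end5[1, "C>T"] <- 0.3
#' positionRates(p, 0, 10)["C>T"]   # 0.3
#' @export
positionRates <- function(profile, dist5, dist3, reverse = FALSE) {
  r5 <- profile@end5[min(dist5 + 1L, nrow(profile@end5)), ]
  r3 <- profile@end3[min(dist3 + 1L, nrow(profile@end3)), ]
  r <- pmin(r5 + r3, 1)
  if (reverse) r <- stats::setNames(r[SUB_COMP], SUBS)
  r
}

## Vectorized rate matrix for many observations: rows = observations,
## cols = 12 substitutions in reference-forward space. d5/d3 are
## molecule-orientation distances; flip complements substitution columns.
deamRateMatrix <- function(profile, d5, d3, flip) {
  i5 <- pmin(d5 + 1L, nrow(profile@end5))
  i3 <- pmin(d3 + 1L, nrow(profile@end3))
  M <- profile@end5[i5, , drop = FALSE] + profile@end3[i3, , drop = FALSE]
  M[M > 1] <- 1
  if (any(flip)) {
    Mf <- M[, SUB_COMP, drop = FALSE]
    M[flip, ] <- Mf[flip, , drop = FALSE]
  }
  colnames(M) <- SUBS
  M
}

## Per-template outflow: obs x 4 matrix of total substitution rate leaving
## each template base, from a deamRateMatrix.
outflowMatrix <- function(rates) {
  out <- matrix(0, nrow(rates), 4L)
  for (b in 1:4) {
    cols <- SUB_IDX[b, -b]
    out[, b] <- pmin(rowSums(rates[, cols, drop = FALSE]), 1)
  }
  out
}

## P[obs r | template t] for per-observation template vector, under a given
## per-observation rate matrix (zero matrix -> null model). Vectorized.
templateObsProb <- function(tmpl, robs, eps, rates, err) {
  n <- length(robs)
  p <- numeric(n)
  ok <- !is.na(tmpl) & !is.na(robs) & robs <= 4L
  match <- ok & tmpl == robs
  if (any(match)) {
    i <- which(match)
    out <- numeric(length(i))
    for (b in 1:4) {
      sel <- tmpl[i] == b
      if (any(sel)) {
        cols <- SUB_IDX[b, -b]
        out[sel] <- pmin(rowSums(rates[i[sel], cols, drop = FALSE]), 1)
      }
    }
    p[i] <- (1 - eps[i]) * (1 - out)
  }
  mis <- ok & tmpl != robs
  if (any(mis)) {
    i <- which(mis)
    sub <- SUB_IDX[cbind(tmpl[i], robs[i])]
    p[i] <- (1 - eps[i]) * rates[cbind(i, sub)] +
      eps[i] * err[cbind(tmpl[i], robs[i])]
  }
  p[!ok] <- NA_real_
  p
}

## Obs x 4 matrix of P[obs | template = b] for all four templates.
allTemplateProbs <- function(robs, eps, rates, err) {
  out <- outflowMatrix(rates)
  P <- matrix(0, length(robs), 4L)
  for (b in 1:4) {
    match <- robs == b
    pb <- numeric(length(robs))
    if (any(match)) pb[match] <- (1 - eps[match]) * (1 - out[match, b])
    mis <- which(!match & robs <= 4L)
    if (length(mis)) {
      sub <- SUB_IDX[cbind(rep(b, length(mis)), robs[mis])]
      pb[mis] <- (1 - eps[mis]) * rates[cbind(mis, sub)] +
        eps[mis] * err[b, ][robs[mis]]
    }
    P[, b] <- pb
  }
  P
}

## ---------------------------------------------------------------------------
## Scalar/vector user-facing likelihoods
## ---------------------------------------------------------------------------

#' Per-base observation likelihoods
#'
#' `pNull()` is the likelihood of observing base `observed` against
#' `template` when differences are explained by sequencing error alone;
#' `pDeam()` additionally allows deamination at the observation's position
#' in the fragment. Both accept vectors.
#'
#' @param template,observed Bases as characters (`"A"`...) or integers 1..4.
#' @param eps Sequencing error probability(ies) from the base caller.
#' @param err 4x4 substitution error matrix (default uniform 1/3).
#' @param profile A [DeaminationProfile-class].
#' @param dist5,dist3 Distances from the fragment's 5'/3' ends
#'   (molecule orientation).
#' @param reverse Logical; observation stored reference-forward from a
#'   reverse-strand fragment.
#' @return Numeric likelihood(s).
#' @examples
#' pNull("C", "T", eps = 0.3)            # 0.3 * 1/3 = 0.1
#' p <- deaminationProfile(maxDepth = 2)
#' p@end5[1, "C>T"] <- 0.3
#' pDeam("C", "T", eps = 0.01, profile = p, dist5 = 0, dist3 = 10) # ~0.30033
#' @export
pNull <- function(template, observed, eps, err = uniformErrorModel()) {
  t <- if (is.character(template)) baseToInt(template) else as.integer(template)
  r <- if (is.character(observed)) baseToInt(observed) else as.integer(observed)
  n <- max(length(t), length(r), length(eps))
  t <- rep_len(t, n); r <- rep_len(r, n); eps <- rep_len(eps, n)
  zero <- matrix(0, n, 12L, dimnames = list(NULL, SUBS))
  templateObsProb(t, r, eps, zero, err)
}

#' @rdname pNull
#' @export
pDeam <- function(template, observed, eps, profile,
                  dist5, dist3, reverse = FALSE,
                  err = uniformErrorModel()) {
  t <- if (is.character(template)) baseToInt(template) else as.integer(template)
  r <- if (is.character(observed)) baseToInt(observed) else as.integer(observed)
  n <- max(length(t), length(r), length(eps), length(dist5), length(dist3))
  t <- rep_len(t, n); r <- rep_len(r, n); eps <- rep_len(eps, n)
  dist5 <- rep_len(as.integer(dist5), n); dist3 <- rep_len(as.integer(dist3), n)
  reverse <- rep_len(reverse, n)
  rates <- deamRateMatrix(profile, dist5, dist3, reverse)
  templateObsProb(t, r, eps, rates, err)
}
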