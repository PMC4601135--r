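## Hand-built alignment fixtures and independent scalar oracles.
## The oracles re-derive every probability with their own plain loops and
## their own profile lookup, so they stay independent of the vectorized
## implementation they check.

BASES4 <- c("A", "C", "G", "T")

## Build a FragmentAlignments object from a compact fragment description:
## each fragment is list(start0=, bases="ACGT...", eps= (scalar or vector),
## mapq=, reverse=FALSE).
makeFrags <- function(refSeq, frags) {
  n <- length(frags)
  ft <- data.frame(id = sprintf("r%03d", seq_len(n)),
                   start0 = vapply(frags, function(f) as.integer(f$start0), 0L),
                   mapq = vapply(frags, function(f) as.integer(f$mapq %||% 60L), 0L),
                   m = NA_real_,
                   reverse = vapply(frags, function(f) isTRUE(f$reverse), TRUE),
                   len = vapply(frags, function(f) nchar(f$bases), 0L),
                   stringsAsFactors = FALSE)
  ft$m <- pmax(10^(-ft$mapq / 10), 1e-10)
  ob <- do.call(rbind, lapply(seq_len(n), function(i) {
    f <- frags[[i]]
    len <- nchar(f$bases)
    j <- 0:(len - 1L)
    rev <- isTRUE(f$reverse)
    d5 <- if (rev) len - 1L - j else j
    data.frame(frag = i, ref0 = f$start0 + j,
               base = match(strsplit(f$bases, "")[[1]], BASES4),
               eps = rep_len(f$eps %||% 1e-3, len), del = FALSE,
               d5 = d5, d3 = len - 1L - d5, flip = rev)
  }))
  mitoContam:::fragmentAlignments("ref", refSeq, ft, ob)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Profile matching the simulator's generative damage model (additive
## per-end decomposition): rate(d) = baseline + terminal * decay^d.
generatingProfile <- function(terminal = 0.30, decay = 0.5, baseline = 0.01,
                              depth = 10L, protocol = "single") {
  m5 <- m3 <- matrix(0, depth, 12, dimnames = list(NULL, mitoContam:::SUBS))
  r <- baseline + terminal * decay^(0:(depth - 1L))
  if (protocol == "single") {
    m5[, "C>T"] <- r
    m3[, "C>T"] <- r
  } else {
    m5[, "C>T"] <- r
    m3[, "G>A"] <- r
  }
  new("DeaminationProfile", end5 = m5, end3 = m3)
}

## ---------------------------------------------------------------------------
## Independent scalar oracles
## ---------------------------------------------------------------------------

## own profile lookup: rate of substitution "X>Y" for one observation
oracleRate <- function(prof, sub, d5, d3, flip) {
  if (flip) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    p <- strsplit(sub, ">")[[1]]
    sub <- paste0(comp[[p[1]]], ">", comp[[p[2]]])
  }
  r5 <- prof@end5[min(d5 + 1, nrow(prof@end5)), sub]
  r3 <- prof@end3[min(d3 + 1, nrow(prof@end3)), sub]
  min(r5 + r3, 1)
}

## own P[obs | template] under deamination + error
oraclePTemplate <- function(tmpl, obs, eps, prof, d5, d3, flip, err) {
  if (tmpl == obs) {
    total <- 0
    for (b2 in setdiff(BASES4, tmpl))
      total <- total + oracleRate(prof, paste0(tmpl, ">", b2), d5, d3, flip)
    (1 - eps) * (1 - min(total, 1))
  } else {
    (1 - eps) * oracleRate(prof, paste0(tmpl, ">", obs), d5, d3, flip) +
      eps * err[tmpl, obs]
  }
}

## joint posterior over the 16 (b_e, b_c) pairs for one column, by direct
## enumeration
oracleJoint <- function(column, priors, err) {
  J <- matrix(0, 4, 4, dimnames = list(BASES4, BASES4))
  for (be in BASES4) for (bc in BASES4) {
    ll <- 0
    for (k in seq_len(nrow(column))) {
      o <- column[k, ]
      obsB <- if (is.character(o$base)) o$base else BASES4[o$base]
      pe <- oraclePTemplate(be, obsB, o$eps, priors@endoProfile,
                            o$d5, o$d3, o$flip, err)
      pc <- oraclePTemplate(bc, obsB, o$eps, priors@contProfile,
                            o$d5, o$d3, o$flip, err)
      v <- (1 - o$m) * (o$pEndo * pe + (1 - o$pEndo) * pc) + o$m / 4
      ll <- ll + log(v)
    }
    J[be, bc] <- ll
  }
  P <- exp(J - max(J))
  P / sum(P)
}

## site likelihood over a rate grid by direct double marginalization
oracleRateLik <- function(column, endoMarginal, contProbs, cr, priors, err) {
  vapply(cr, function(cc) {
    ll <- 0
    for (k in seq_len(nrow(column))) {
      o <- column[k, ]
      obsB <- if (is.character(o$base)) o$base else BASES4[o$base]
      tot <- 0
      for (be in 1:4) for (ci in 1:4) {
        pe <- oraclePTemplate(BASES4[be], obsB, o$eps, priors@endoProfile,
                              o$d5, o$d3, o$flip, err)
        pc <- oraclePTemplate(BASES4[ci], obsB, o$eps,
                              deaminationProfile(maxDepth = 2L),
                              o$d5, o$d3, o$flip, err)
        pObs <- (1 - o$m) * ((1 - cc) * pe + cc * pc) + o$m / 4
        tot <- tot + endoMarginal[be] * contProbs[ci] * pObs
      }
      ll <- ll + log(tot)
    }
    ll
  }, 0)
}

## random small pileup column for oracle comparisons
randomColumn <- function(nReads = 5L, prof = NULL) {
  data.frame(base = sample(BASES4, nReads, replace = TRUE),
             eps = 10^(-stats::runif(nReads, 1, 4)),
             d5 = sample(0:15, nReads, replace = TRUE),
             d3 = sample(0:15, nReads, replace = TRUE),
             flip = sample(c(TRUE, FALSE), nReads, replace = TRUE),
             m = 10^(-stats::runif(nReads, 0.3, 4)),
             pEndo = stats::runif(nReads),
             stringsAsFactors = FALSE)
}

randomPriors <- function() {
  ep <- deaminationProfile(maxDepth = 6L)
  ep@end5[, "C>T"] <- stats::runif(6, 0, 0.4)
  ep@end3[, "G>A"] <- stats::runif(6, 0, 0.4)
  cp <- deaminationProfile(maxDepth = 6L)
  cp@end5[, "C>T"] <- stats::runif(6, 0, 0.05)
  endoPriors(contamination = stats::runif(1), endoProfile = ep,
             contProfile = cp)
}

## shared expensive fixtures, built on first use
.fixtureCache <- new.env(parent = emptyenv())
cachedFixture <- function(name, build) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, build(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## Consensus accuracy metric. Uncalled (N) sites are not mismatches, and
## one minimum fragment length at each terminus is excluded: a linear
## rendering of a circular genome leaves the termini covered only by
## fragment-terminal (maximally damage-prone) bases at vanishing depth,
## a geometry real circular-coverage data does not have.
countMismatches <- function(called, truth, edge = 20L) {
  a <- strsplit(called, "")[[1]]
  b <- strsplit(truth, "")[[1]]
  keep <- seq_along(a) > edge & seq_along(a) <= length(a) - edge
  sum(a[keep] != b[keep] & a[keep] != "N")
}
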