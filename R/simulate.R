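## Synthetic ancient-DNA alignments with known truth.
##
## The generator emulates the stated test-data world: fragments with
## log-normal lengths (ancient shorter than modern), protocol-specific
## terminal deamination (single-stranded: C>T at both ends; double-stranded:
## C>T at the 5' end, G>A at the 3' end) with geometric positional decay,
## PHRED-scored sequencing errors, and mixing of endogenous and contaminant
## fragments at a chosen rate. Coordinates are shared: contaminant genomes
## are substitution-only variants of the reference coordinate system.

#' Simulation configuration
#'
#' Defaults state the simulated world once: endogenous fragment lengths
#' lnN(ln 45, 0.35) and contaminant lnN(ln 85, 0.35) (ancient molecules are
#' shorter than modern contaminants), terminal deamination rate 0.30
#' decaying geometrically (factor 0.5) onto a 0.01 interior baseline,
#' single-stranded protocol, constant base quality Q30, MAPQ 37, and an
#' undamaged contaminant.
#'
#' @param endoGenome Endogenous genome string (also the mapping reference
#'   unless `reference` is given).
#' @param contGenome Contaminant genome string (same length, substitutions
#'   only), or `NULL` for a contamination-free dataset.
#' @param contFraction Fraction of fragments drawn from the contaminant.
#' @param nFragments Number of fragments.
#' @param muEndo,sigmaEndo,muCont,sigmaCont Log-normal length parameters.
#' @param protocol `"single"` or `"double"` strand library protocol.
#' @param terminalRate,decay,baseline Endogenous damage model:
#'   rate(i) = baseline + terminalRate * decay^i from the relevant end(s).
#' @param contTerminalRate,contBaseline Contaminant damage (default none).
#' @param baseQ Constant PHRED base quality.
#' @param mapq Constant mapping quality.
#' @param errorModel 4x4 substitution matrix for sequencing errors.
#' @param minLength Minimum fragment length.
#' @param seed Integer seed; every random draw flows from it.
#' @return A configuration list for [simulateDataset()].
#' @export
simulationConfig <- function(endoGenome, contGenome = NULL,
                             contFraction = 0, nFragments = 1000L,
                             muEndo = log(45), sigmaEndo = 0.35,
                             muCont = log(85), sigmaCont = 0.35,
                             protocol = c("single", "double"),
                             terminalRate = 0.30, decay = 0.5,
                             baseline = 0.01,
                             contTerminalRate = 0, contBaseline = 0,
                             baseQ = 30L, mapq = 37L,
                             errorModel = uniformErrorModel(),
                             minLength = 20L, seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(contFraction >= 0, contFraction <= 1,
            terminalRate >= 0, terminalRate <= 1, baseline >= 0)
  if (nchar(endoGenome) <= minLength)
    stop("genome shorter than the minimum fragment length")
  if (!is.null(contGenome) && nchar(contGenome) != nchar(endoGenome))
    stop("contaminant genome must match the endogenous genome length")
  list(endoGenome = toupper(endoGenome), contGenome = contGenome,
       contFraction = contFraction, nFragments = as.integer(nFragments),
       muEndo = muEndo, sigmaEndo = sigmaEndo, muCont = muCont,
       sigmaCont = sigmaCont, protocol = protocol,
       terminalRate = terminalRate, decay = decay, baseline = baseline,
       contTerminalRate = contTerminalRate, contBaseline = contBaseline,
       baseQ = as.integer(baseQ), mapq = as.integer(mapq),
       errorModel = errorModel, minLength = as.integer(minLength),
       seed = as.integer(seed))
}

#' Generate a random genome / diverged copy
#'
#' `randomGenome()` draws a uniform A/C/G/T sequence; `mutateGenome()`
#' introduces exactly `nSubstitutions` single-base differences at distinct
#' positions; `makeGenomePair()` combines the two into an endogenous /
#' contaminant pair with a known Hamming distance.
#'
#' @param length Genome length.
#' @param nSubstitutions Number of differing positions.
#' @param genome Genome string to mutate.
#' @param seed Integer seed.
#' @return Character string(s); `makeGenomePair()` returns
#'   `list(endo, cont)`.
#' @examples
#' gp <- makeGenomePair(1000, 5, seed = 42)
#' sum(strsplit(gp$endo, "")[[1]] != strsplit(gp$cont, "")[[1]])  # 5
#' @export
randomGenome <- function(length, seed = 1L) {
  set.seed(seed)
  paste0(sample(BASES, length, replace = TRUE), collapse = "")
}

#' @rdname randomGenome
#' @export
mutateGenome <- function(genome, nSubstitutions, seed = 1L) {
  set.seed(seed)
  g <- strsplit(genome, "", fixed = TRUE)[[1L]]
  if (nSubstitutions >= length(g))
    stop("nSubstitutions must be smaller than the genome length")
  pos <- sample.int(length(g), nSubstitutions)
  g[pos] <- vapply(g[pos], function(b) sample(setdiff(BASES, b), 1L), "")
  paste0(g, collapse = "")
}

#' @rdname randomGenome
#' @export
makeGenomePair <- function(length, nSubstitutions, seed = 1L) {
  endo <- randomGenome(length, seed = seed)
  cont <- mutateGenome(endo, nSubstitutions, seed = seed + 1L)
  list(endo = endo, cont = cont)
}

#' Simulate an ancient-DNA dataset with known truth
#'
#' Draws each fragment's origin (Bernoulli on the contaminant fraction),
#' length (log-normal, clamped to `[minLength, genome length]`), start
#' (uniform, no origin wrap) and strand; applies position-dependent
#' terminal deamination in original-molecule orientation, then sequencing
#' errors at the configured base quality; and records complete truth. The
#' per-nucleotide contamination rate (contaminant bases / total bases) is
#' the quantity the database estimator targets -- it exceeds the fragment
#' fraction when contaminant molecules are longer.
#'
#' @param cfg A list from [simulationConfig()].
#' @param samPath,truthPath Optional output paths (SAM alignment and
#'   per-read truth TSV).
#' @return List with `alignments` (a [FragmentAlignments-class]), `truth`
#'   (per-fragment data.frame: `id`, `origin`, `start0`, `len`, `reverse`,
#'   `nDeaminated`, `nSeqErrors`), `perNucContamination`,
#'   `fragContamination` (realized fragment fraction), and the `cfg` echo.
#' @export
simulateDataset <- function(cfg, samPath = NULL, truthPath = NULL) {
  set.seed(cfg$seed)
  L <- nchar(cfg$endoGenome)
  n <- cfg$nFragments
  endoInt <- baseToInt(cfg$endoGenome)
  contInt <- if (is.null(cfg$contGenome)) endoInt else baseToInt(cfg$contGenome)

  isCont <- if (is.null(cfg$contGenome)) rep(FALSE, n)
            else stats::runif(n) < cfg$contFraction
  mu <- ifelse(isCont, cfg$muCont, cfg$muEndo)
  sig <- ifelse(isCont, cfg$sigmaCont, cfg$sigmaEndo)
  len <- pmin(pmax(as.integer(round(stats::rlnorm(n, mu, sig))),
                   cfg$minLength), L)
  start0 <- as.integer(floor(stats::runif(n) * (L - len + 1)))
  reverse <- stats::runif(n) < 0.5

  ## columnar expansion: one row per base over all fragments
  frag <- rep.int(seq_len(n), len)
  ref0 <- sequence(len, from = start0 + 1L) - 1L
  ## template base in reference-forward space
  tfwd <- ifelse(isCont[frag], contInt[ref0 + 1L], endoInt[ref0 + 1L])
  ## molecule-orientation distances and template
  j <- sequence(len) - 1L
  lenv <- len[frag]
  rev <- reverse[frag]
  d5 <- ifelse(rev, lenv - 1L - j, j)
  d3 <- lenv - 1L - d5
  tmol <- ifelse(rev, COMP[tfwd], tfwd)

  ## deamination in molecule space
  term <- ifelse(isCont[frag], cfg$contTerminalRate, cfg$terminalRate)
  base0 <- ifelse(isCont[frag], cfg$contBaseline, cfg$baseline)
  r5 <- pmin(base0 + term * cfg$decay^d5, 1)
  r3 <- pmin(base0 + term * cfg$decay^d3, 1)
  obsMol <- tmol
  u <- stats::runif(length(tmol))
  if (cfg$protocol == "single") {
    pCT <- pmin(r5 + r3, 1)                       # C>T from both ends
    hit <- tmol == 2L & u < pCT
    obsMol[hit] <- 4L
  } else {
    hitCT <- tmol == 2L & u < r5                  # C>T at 5'
    hitGA <- tmol == 3L & u < r3                  # G>A at 3'
    obsMol[hitCT] <- 4L
    obsMol[hitGA] <- 1L
  }
  nDeam <- tabulate(frag[obsMol != tmol], nbins = n)

  ## sequencing errors on the damaged molecule
  eps <- phredToProb(cfg$baseQ)
  errHit <- stats::runif(length(obsMol)) < eps
  if (any(errHit)) {
    i <- which(errHit)
    cum <- t(apply(cfg$errorModel, 1L, cumsum))
    u2 <- stats::runif(length(i))
    pick <- 1L + rowSums(outer(u2, rep(1, 4)) > cum[obsMol[i], , drop = FALSE])
    pick[pick > 4L] <- 4L
    obsMol[i] <- pick
  }
  nErr <- tabulate(frag[errHit], nbins = n)

  obsFwd <- ifelse(rev, COMP[obsMol], obsMol)
  frags <- data.frame(
    id = sprintf("frag%06d", seq_len(n)), start0 = start0,
    mapq = rep(cfg$mapq, n), m = rep(phredToProb(cfg$mapq), n),
    reverse = reverse, len = len, stringsAsFactors = FALSE)
  obs <- data.frame(frag = frag, ref0 = ref0, base = obsFwd,
                    eps = rep(eps, length(obsFwd)), del = FALSE,
                    d5 = d5, d3 = d3, flip = rev)
  fa <- fragmentAlignments("ref", cfg$endoGenome, frags, obs)

  truth <- data.frame(
    id = frags$id, origin = ifelse(isCont, "contaminant", "endogenous"),
    start0 = start0, len = len, reverse = reverse,
    nDeaminated = nDeam, nSeqErrors = nErr, stringsAsFactors = FALSE)
  perNuc <- sum(len[isCont]) / sum(len)

  if (!is.null(samPath)) writeSAM(fa, samPath)
  if (!is.null(truthPath))
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(alignments = fa, truth = truth, perNucContamination = perNuc,
       fragContamination = mean(isCont), cfg = cfg)
}
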