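## External formats: SAM/BAM alignments in, FASTA/TSV artifacts out.
## Internal coordinates are 0-based half-open; written logs are 1-based
## (the convention of mtDNA position reporting).

#' Read a reference genome from FASTA
#'
#' @param path FASTA file with at least one record.
#' @param name Optional record name; default first record.
#' @return List with `name` and `sequence` (uppercase character string).
#' @export
readReference <- function(path, name = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  i <- if (is.null(name)) 1L else match(name, nm)
  if (is.na(i)) stop("reference '", name, "' not found in ", path)
  list(name = nm[i], sequence = toupper(as.character(ss[[i]])))
}

## Expand one CIGAR string into per-base rows. Returns a list of integer
## vectors: readIdx (0-based, NA for deletion), refIdx (0-based offset from
## alignment start), op codes; plus insertion anchors.
expandCigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  readIdx <- integer(0); refIdx <- integer(0); isDel <- logical(0)
  insRead <- list(); insRef <- integer(0)
  rpos <- 0L; gpos <- 0L
  for (k in seq_along(ops)) {
    n <- lens[k]
    switch(ops[k],
      "M" = , "=" = , "X" = {
        readIdx <- c(readIdx, rpos + 0:(n - 1L))
        refIdx <- c(refIdx, gpos + 0:(n - 1L))
        isDel <- c(isDel, rep(FALSE, n))
        rpos <- rpos + n; gpos <- gpos + n
      },
      "I" = {
        insRead[[length(insRead) + 1L]] <- rpos + 0:(n - 1L)
        insRef <- c(insRef, gpos)
        rpos <- rpos + n
      },
      "D" = , "N" = {
        readIdx <- c(readIdx, rep(NA_integer_, n))
        refIdx <- c(refIdx, gpos + 0:(n - 1L))
        isDel <- c(isDel, rep(TRUE, n))
        gpos <- gpos + n
      },
      "S" = { rpos <- rpos + n },
      "H" = , "P" = NULL
    )
  }
  list(readIdx = readIdx, refIdx = refIdx, isDel = isDel,
       insRead = insRead, insRef = insRef, readLen = rpos)
}

#' Read an alignment of ancient-DNA fragments
#'
#' Reads a BAM (or plain SAM, converted on the fly) and converts records
#' mapped to `referenceName` into the columnar [FragmentAlignments-class]
#' model. Unmapped, secondary and supplementary records are skipped;
#' soft-clipped bases are excluded; CIGAR deletions become gap observations
#' (base code 5) carrying the error probability of the preceding read base;
#' insertions are stored separately. Distances from the fragment ends are
#' converted to original-molecule orientation (mirrored for reverse-strand
#' records) so deamination profiles can be looked up directly.
#'
#' @param path BAM or SAM file.
#' @param referenceName Name of the target reference sequence in the header.
#' @param refSeq Reference sequence string (e.g. from [readReference()]).
#' @return A [FragmentAlignments-class] object. Records whose CIGAR and
#'   sequence lengths disagree are skipped; their count is reported in a
#'   warning.
#' @export
readAlignment <- function(path, referenceName, refSeq) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  if (!referenceName %in% levels(b$rname) && length(b$rname))
    stop("reference '", referenceName, "' absent from BAM header/records")
  keep <- !is.na(b$pos) & as.character(b$rname) == referenceName &
    bitwAnd(b$flag, 0x4L) == 0L & bitwAnd(b$flag, 0x100L) == 0L &
    bitwAnd(b$flag, 0x800L) == 0L
  idx <- which(keep)
  if (!length(idx))
    stop("no usable alignments to '", referenceName, "' in ", path)

  qname <- b$qname[idx]
  flag <- b$flag[idx]
  pos0 <- b$pos[idx] - 1L
  mapq <- b$mapq[idx]
  mapq[is.na(mapq) | mapq == 255L] <- 0L    # "unavailable" treated as 0
  cigar <- b$cigar[idx]
  seqs <- as.character(b$seq[idx])
  quals <- as.character(b$qual[idx])
  reverse <- bitwAnd(flag, 0x10L) != 0L

  simple <- grepl("^[0-9]+M$", cigar)
  nSkip <- 0L

  fragId <- character(0); fragStart <- integer(0); fragMapq <- integer(0)
  fragRev <- logical(0); fragLen <- integer(0)
  obsFrag <- list(); obsRef <- list(); obsBase <- list(); obsEps <- list()
  obsRd <- list(); obsDel <- list()
  insFrag <- integer(0); insRef <- integer(0); insSeq <- character(0)
  insEps <- numeric(0)

  nf <- 0L
  addFrag <- function(i, len) {
    nf <<- nf + 1L
    fragId[nf] <<- qname[i]; fragStart[nf] <<- pos0[i]
    fragMapq[nf] <<- mapq[i]; fragRev[nf] <<- reverse[i]; fragLen[nf] <<- len
    nf
  }

  ## fast path: contiguous matches
  if (any(simple)) {
    for (i in which(simple)) {
      len <- nchar(seqs[i])
      if (len != as.integer(sub("M$", "", cigar[i]))) { nSkip <- nSkip + 1L; next }
      f <- addFrag(i, len)
      q <- utf8ToInt(quals[i]) - 33L
      obsFrag[[f]] <- rep(f, len)
      obsRef[[f]] <- pos0[i] + 0:(len - 1L)
      obsBase[[f]] <- baseToInt(seqs[i])
      obsEps[[f]] <- phredToProb(q)
      obsRd[[f]] <- 0:(len - 1L)
      obsDel[[f]] <- rep(FALSE, len)
    }
  }
  for (i in which(!simple)) {
    ex <- tryCatch(expandCigar(cigar[i]), error = function(e) NULL)
    if (is.null(ex) || ex$readLen != nchar(seqs[i])) { nSkip <- nSkip + 1L; next }
    sInt <- baseToInt(seqs[i])
    q <- phredToProb(utf8ToInt(quals[i]) - 33L)
    nAligned <- sum(!ex$isDel)
    f <- addFrag(i, nAligned)
    base <- ifelse(ex$isDel, GAP_CODE, sInt[ex$readIdx + 1L])
    ## deletion eps: carry the previous aligned base's eps (or next at start)
    rdFill <- ex$readIdx
    for (k in seq_along(rdFill)) if (is.na(rdFill[k]))
      rdFill[k] <- if (k > 1L && !is.na(rdFill[k - 1L])) rdFill[k - 1L] else 0L
    eps <- q[rdFill + 1L]
    obsFrag[[f]] <- rep(f, length(base))
    obsRef[[f]] <- pos0[i] + ex$refIdx
    obsBase[[f]] <- base
    obsEps[[f]] <- eps
    obsRd[[f]] <- ifelse(ex$isDel, rdFill, ex$readIdx)
    obsDel[[f]] <- ex$isDel
    for (k in seq_along(ex$insRef)) {
      rd <- ex$insRead[[k]]
      insFrag <- c(insFrag, f)
      insRef <- c(insRef, pos0[i] + ex$insRef[k])
      insSeq <- c(insSeq, paste0(BASES[sInt[rd + 1L]], collapse = ""))
      insEps <- c(insEps, mean(q[rd + 1L]))
    }
  }
  if (nSkip > 0L)
    warning(nSkip, " record(s) skipped: CIGAR/sequence length mismatch")
  if (nf == 0L) stop("no usable alignments after filtering")

  frags <- data.frame(id = fragId, start0 = fragStart, mapq = fragMapq,
                      m = pmax(phredToProb(fragMapq), 1e-10),
                      reverse = fragRev, len = fragLen,
                      stringsAsFactors = FALSE)
  obs <- data.frame(frag = unlist(obsFrag), ref0 = unlist(obsRef),
                    base = unlist(obsBase), eps = unlist(obsEps),
                    rd = unlist(obsRd), del = unlist(obsDel))
  obs$base[obs$del] <- GAP_CODE
  obs <- obs[!is.na(obs$base), , drop = FALSE]   # ambiguous read bases (N)
  ## distances from fragment ends: read-coordinate first, then mirror to
  ## molecule orientation for reverse-strand fragments.
  len <- frags$len[obs$frag]
  rev <- frags$reverse[obs$frag]
  d5r <- obs$rd
  d3r <- len - 1L - obs$rd
  obs$d5 <- ifelse(rev, d3r, d5r)
  obs$d3 <- ifelse(rev, d5r, d3r)
  obs$flip <- rev
  obs$rd <- NULL
  ins <- data.frame(frag = insFrag, ref0 = insRef, seq = insSeq, eps = insEps,
                    stringsAsFactors = FALSE)
  fragmentAlignments(referenceName, refSeq, frags, obs, ins)
}

#' Read a database of candidate contaminant genomes
#'
#' A multi-FASTA of candidate present-day contaminant mitochondrial
#' genomes, each pre-aligned to the reference coordinate system (alignment
#' gaps `-` allowed, IUPAC ambiguity codes retained).
#'
#' @param path Multi-FASTA file.
#' @param refLength Length of the reference coordinate system; every record
#'   must have exactly this length.
#' @return Named character vector of gapped uppercase sequences.
#' @export
readContaminantDB <- function(path, refLength) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty contaminant database: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  w <- Biostrings::width(ss)
  bad <- which(w != refLength)
  if (length(bad))
    stop("contaminant record '", nm[bad[1L]], "' has length ", w[bad[1L]],
         ", expected ", refLength)
  stats::setNames(toupper(as.character(ss)), nm)
}

## Per-position base probabilities for a (possibly gapped/IUPAC) contaminant
## sequence: n x 4 matrix, uniform over the IUPAC set, all-zero rows for
## gaps and unknowns (those sites are skipped).
contaminantBaseProbs <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  iupac <- Biostrings::IUPAC_CODE_MAP
  P <- matrix(0, length(ch), 4L, dimnames = list(NULL, BASES))
  known <- ch %in% names(iupac) & ch != "N"
  for (code in unique(ch[known])) {
    set <- strsplit(iupac[[code]], "", fixed = TRUE)[[1L]]
    P[ch == code, match(set, BASES)] <- 1 / length(set)
  }
  P
}

#' Read and write deamination profiles
#'
#' Profiles are exchanged as TSV: a `pos` column (0-based distance from the
#' end) followed by one column per ordered substitution (`A.C` ... `T.G`
#' headers, written as `A>C` style on output). Both ends travel in separate
#' files by convention (`*.5p.prof`, `*.3p.prof`); `readDeaminationProfile`
#' takes both paths.
#'
#' @param path5,path3 TSV paths for the 5' and 3' end tables.
#' @param profile A [DeaminationProfile-class].
#' @return `readDeaminationProfile` returns a [DeaminationProfile-class];
#'   writers return their path(s) invisibly.
#' @export
readDeaminationProfile <- function(path5, path3) {
  readEnd <- function(path) {
    d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    if (nrow(d) == 0L) stop("empty deamination profile: ", path)
    m <- matrix(0, nrow(d), 12L, dimnames = list(NULL, SUBS))
    for (s in SUBS) {
      alt <- sub(">", ".", s, fixed = TRUE)
      src <- if (s %in% names(d)) s else if (alt %in% names(d)) alt else NULL
      if (!is.null(src)) m[, s] <- d[[src]]
    }
    if (any(m < 0 | m > 1)) stop("deamination rate outside [0,1] in ", path)
    m
  }
  new("DeaminationProfile", end5 = readEnd(path5), end3 = readEnd(path3))
}

#' @rdname readDeaminationProfile
#' @export
writeDeaminationProfile <- function(profile, path5, path3) {
  writeEnd <- function(m, path) {
    d <- data.frame(pos = seq_len(nrow(m)) - 1L, m, check.names = FALSE)
    names(d) <- c("pos", SUBS)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeEnd(profile@end5, path5)
  writeEnd(profile@end3, path3)
  invisible(c(path5, path3))
}

#' Write consensus FASTA and per-site log
#'
#' Writes the called consensus as FASTA (`N` at uncovered sites, and below
#' `qualityFilter` when given) and a 1-based TSV log with position,
#' reference base, called base, PHRED-scaled consensus quality, coverage
#' and the four marginal base probabilities.
#'
#' @param calls A [SiteCalls-class] object.
#' @param fastaPath,logPath Output paths (either may be `NULL` to skip).
#' @param track `"endo"` or `"cont"`.
#' @param qualityFilter Optional PHRED threshold for the FASTA
#'   (e.g. 200 for high-confidence bases).
#' @param name FASTA record name.
#' @return Invisibly, the consensus string that was written.
#' @export
writeConsensus <- function(calls, fastaPath = NULL, logPath = NULL,
                           track = c("endo", "cont"), qualityFilter = NULL,
                           name = NULL) {
  track <- match.arg(track)
  cc <- calls@calls
  base <- if (track == "endo") cc$endoBase else cc$contBase
  phred <- if (track == "endo") cc$endoPhred else cc$contPhred
  marg <- if (track == "endo") cc[, c("eA", "eC", "eG", "eT")]
          else cc[, c("cA", "cC", "cG", "cT")]
  out <- base
  out[cc$coverage == 0L] <- "N"
  if (!is.null(qualityFilter)) out[phred < qualityFilter] <- "N"
  if (is.null(name))
    name <- paste0(calls@refName, "_", track, "_consensus")
  if (!is.null(fastaPath)) {
    fastaSeq <- paste0(out[out != "-"], collapse = "")
    ss <- Biostrings::BStringSet(stats::setNames(fastaSeq, name))
    Biostrings::writeXStringSet(ss, fastaPath)
  }
  if (!is.null(logPath)) {
    d <- data.frame(pos = cc$ref0 + 1L, ref = cc$refBase, call = out,
                    phred = round(ifelse(cc$coverage == 0L, 0, phred), 2),
                    coverage = cc$coverage,
                    pA = signif(marg[[1L]], 6), pC = signif(marg[[2L]], 6),
                    pG = signif(marg[[3L]], 6), pT = signif(marg[[4L]], 6))
    utils::write.table(d, logPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paste0(out, collapse = ""))
}

#' Write a posterior curve as TSV
#'
#' @param curve A [PosteriorCurve-class].
#' @param path Output TSV (`rate`, `logPosterior`, `posterior`).
#' @export
writePosteriorCurve <- function(curve, path) {
  utils::write.table(
    data.frame(rate = curve@grid, logPosterior = curve@logPosterior,
               posterior = curve@posterior),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fragments to SAM
#'
#' Serializes a [FragmentAlignments-class] object as plain SAM (forward
#' reference orientation, flag 16 for reverse-strand fragments). Only
#' contiguous-match fragments are supported (the simulator never emits
#' indels), which keeps the writer honest as a round-trip counterpart of
#' [readAlignment()].
#'
#' @param x A [FragmentAlignments-class] object.
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
writeSAM <- function(x, path) {
  frags <- x@fragments
  obs <- x@observations
  if (any(obs$base == GAP_CODE) || nrow(x@insertions))
    stop("writeSAM supports contiguous-match fragments only")
  ord <- order(obs$frag, obs$ref0)
  obs <- obs[ord, ]
  seqs <- vapply(split(BASES[obs$base], obs$frag), paste0, "", collapse = "")
  qv <- as.integer(round(-10 * log10(obs$eps)))
  quals <- vapply(split(intToUtf8(qv + 33L, multiple = TRUE), obs$frag),
                  paste0, "", collapse = "")
  idx <- as.integer(names(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", x@refName, nchar(x@refSeq))), con)
  o <- idx[order(frags$start0[idx])]
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                   frags$id[o], ifelse(frags$reverse[o], 16L, 0L), x@refName,
                   frags$start0[o] + 1L, frags$mapq[o], frags$len[o],
                   seqs[match(o, idx)], quals[match(o, idx)])
  writeLines(lines, con)
  invisible(path)
}
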