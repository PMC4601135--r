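## Shared encodings and numeric helpers.

## Nucleotide alphabet Omega = {A,C,G,T}; integers 1..4, 5 = alignment gap.
BASES <- c("A", "C", "G", "T")
GAP_CODE <- 5L
## Watson-Crick complement in integer encoding (A<->T, C<->G).
COMP <- c(4L, 3L, 2L, 1L)

## Ordered substitution types x>y, x != y, row-major over Omega.
SUBS <- {
  s <- character(0)
  for (f in BASES) for (t in setdiff(BASES, f)) s <- c(s, paste0(f, ">", t))
  s
}
## SUB_IDX[from, to] -> column in a 12-column rate matrix (NA on diagonal).
SUB_IDX <- {
  m <- matrix(NA_integer_, 4, 4, dimnames = list(BASES, BASES))
  k <- 0L
  for (f in 1:4) for (t in setdiff(1:4, f)) { k <- k + 1L; m[f, t] <- k }
  m
}
## Complement-substitution map: SUB_COMP[k] is the index of the substitution
## obtained by complementing both bases (C>T <-> G>A etc.).
SUB_COMP <- {
  v <- integer(12)
  for (f in 1:4) for (t in setdiff(1:4, f)) {
    v[SUB_IDX[f, t]] <- SUB_IDX[COMP[f], COMP[t]]
  }
  v
}

baseToInt <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  match(toupper(x), BASES)
}

intToBase <- function(i) {
  out <- rep(NA_character_, length(i))
  ok <- !is.na(i) & i >= 1L & i <= 4L
  out[ok] <- BASES[i[ok]]
  out[!is.na(i) & i == GAP_CODE] <- "-"
  out
}

#' Convert between PHRED scores and error probabilities
#'
#' `phredToProb()` maps a PHRED-scaled quality to an error probability
#' \eqn{10^{-Q/10}}; `probToPhred()` is its inverse \eqn{-10\log_{10}p},
#' capped at `cap` (consensus qualities are conventionally capped).
#'
#' @param q PHRED score(s).
#' @param p Error probability(ies).
#' @param cap Upper bound applied to the returned PHRED score.
#' @return Numeric vector.
#' @examples
#' phredToProb(40)          # 1e-4
#' probToPhred(1e-20)       # 200
#' @export
phredToProb <- function(q) 10^(-q / 10)

#' @rdname phredToProb
#' @export
probToPhred <- function(p, cap = 9999) {
  out <- ifelse(p <= 0, cap, -10 * log10(p))
  pmin(out, cap)
}

## log(sum(exp(x))) along rows of a matrix, numerically safe.
logRowSumExp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = TRUE)))
  mx + log(rowSums(exp(m - mx)))
}

logSumExp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

## Sum `values` within integer groups 1..n (groups may be empty -> 0).
groupSum <- function(values, group, n) {
  out <- numeric(n)
  s <- rowsum(values, group)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

## Highest-posterior-density interval on a discrete grid.
## Returns c(low, high) covering at least `level` of the normalized mass.
hpdInterval <- function(grid, post, level = 0.95) {
  ord <- order(post, decreasing = TRUE)
  cum <- cumsum(post[ord])
  keep <- ord[seq_len(which(cum >= level)[1L])]
  c(min(grid[keep]), max(grid[keep]))
}
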