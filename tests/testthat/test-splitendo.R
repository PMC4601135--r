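twoTrackCalls <- function(endo, cont, phred = 300) {
  n <- nchar(endo)
  eB <- strsplit(endo, "")[[1]]
  cB <- strsplit(cont, "")[[1]]
  mk <- function(b) {
    P <- matrix(0, n, 4)
    P[cbind(seq_len(n), match(b, BASES4))] <- 1
    P
  }
  eP <- mk(eB); cP <- mk(cB)
  d <- data.frame(ref0 = 0:(n - 1), refBase = eB, endoBase = eB,
                  endoErr = 1e-30, endoPhred = phred, contBase = cB,
                  contErr = 1e-30, contPhred = phred, coverage = 10L,
                  eA = eP[, 1], eC = eP[, 2], eG = eP[, 3], eT = eP[, 4],
                  cA = cP[, 1], cC = cP[, 2], cG = cP[, 3], cT = cP[, 4],
                  stringsAsFactors = FALSE)
  new("SiteCalls", refName = "ref", calls = d)
}

test_that("fragments partition by supported allele with majority and ties", {
  endo <- "AAAAAAAAAA"
  cont <- "AAAACAAAAA"               # one differing site at ref0 4
  calls <- twoTrackCalls(endo, cont)
  fa <- makeFrags(endo, list(
    list(start0 = 2, bases = "AAAAA"),          # covers site, endo allele
    list(start0 = 2, bases = "AACAA"),          # covers site, cont allele
    list(start0 = 6, bases = "AAAA")))          # no differing site
  p <- partitionFragments(fa, calls)
  expect_equal(p$endo, 1L)
  expect_equal(p$cont, 2L)
  expect_equal(p$unassigned, 3L)
  ## a fragment split across two differing sites is a tie -> unassigned
  cont2 <- "AACACAAAAA"              # differing at ref0 2 and 4
  calls2 <- twoTrackCalls(endo, cont2)
  fa2 <- makeFrags(endo, list(list(start0 = 1, bases = "ACAAA")))
  p2 <- partitionFragments(fa2, calls2)   # matches cont at 2, endo at 4
  expect_equal(p2$unassigned, 1L)
  ## partition property: the three sets tile the fragment set exactly
  expect_setequal(c(p$endo, p$cont, p$unassigned), seq_len(length(fa)))
  ## no differing sites at quality: everything unassigned
  pLow <- partitionFragments(fa, twoTrackCalls(endo, cont, phred = 5))
  expect_equal(length(pLow$endo) + length(pLow$cont), 0L)
})

test_that("a mixed simulation partitions almost perfectly", {
  gp <- makeGenomePair(1500, 10, seed = 61)
  cfg <- simulationConfig(gp$endo, gp$cont, contFraction = 0.5,
                          nFragments = 5000, seed = 62)
  sim <- simulateDataset(cfg)
  calls <- twoTrackCalls(gp$endo, gp$cont)
  p <- partitionFragments(sim$alignments, calls)
  expect_setequal(c(p$endo, p$cont, p$unassigned),
                  seq_len(length(sim$alignments)))
  assigned <- c(p$endo, p$cont)
  lab <- c(rep("endogenous", length(p$endo)), rep("contaminant", length(p$cont)))
  acc <- mean(sim$truth$origin[assigned] == lab)
  expect_gte(acc, 0.95)
})

test_that("deamination refit recovers the generating rates", {
  g <- randomGenome(2000, seed = 71)
  cfg <- simulationConfig(g, NULL, nFragments = 4000, seed = 72)
  sim <- simulateDataset(cfg)
  prof <- refitDeamination(sim$alignments, seq_len(4000), useReference = TRUE)
  ## additive decomposition: terminal row carries ~ baseline/?? + 0.30 of
  ## one end; allow binomial slack
  expect_lt(abs(prof@end5[1, "C>T"] - 0.31), 0.05)
  expect_lt(abs(prof@end3[1, "C>T"] - 0.31), 0.05)
  ## an undamaged set refits to ~zero rates
  cfg0 <- simulationConfig(g, NULL, nFragments = 2000, terminalRate = 0,
                           baseline = 0, seed = 73)
  sim0 <- simulateDataset(cfg0)
  prof0 <- refitDeamination(sim0$alignments, seq_len(2000),
                            useReference = TRUE)
  expect_lt(max(prof0@end5[, "C>T"]), 0.01)
  ## too-small sets keep the previous profile, with a warning
  prev <- generatingProfile()
  expect_warning(kept <- refitDeamination(sim$alignments, integer(0),
                                          previous = prev), "too small")
  expect_identical(kept, prev)
})

test_that("length model refits via the closed-form log-normal MLE", {
  ## degenerate lengths hit the sigma floor
  ft <- data.frame(id = as.character(1:40), start0 = 0L, mapq = 60L,
                   m = 1e-6, reverse = FALSE, len = 50L)
  ob <- data.frame(frag = 1L, ref0 = 0L, base = 1L, eps = 1e-3, del = FALSE,
                   d5 = 0L, d3 = 0L, flip = FALSE)
  fa <- mitoContam:::fragmentAlignments("ref", "ACGT", ft, ob)
  lm <- refitLengthModel(fa, 1:40, integer(0),
                         previous = fragmentLengthModel())
  expect_equal(lm@muEndo, log(50), tolerance = 1e-12)
  expect_equal(lm@sigmaEndo, 0.01)            # floor
  expect_equal(lm@muCont, log(85))            # kept from previous
  ## MLE consistency on simulated log-normal lengths
  set.seed(81)
  len <- pmax(20L, as.integer(round(rlnorm(5000, 3.8, 0.4))))
  ft2 <- data.frame(id = as.character(seq_along(len)), start0 = 0L,
                    mapq = 60L, m = 1e-6, reverse = FALSE, len = len)
  fa2 <- mitoContam:::fragmentAlignments("ref", "ACGT", ft2, ob)
  lm2 <- refitLengthModel(fa2, seq_along(len), seq_along(len),
                          previous = fragmentLengthModel())
  expect_lt(abs(lm2@muEndo - 3.8), 0.02)
  expect_lt(abs(lm2@sigmaEndo - 0.4), 0.02)
  ## shorter ancient fragments: mu_endo < mu_cont after a split refit
  gp <- makeGenomePair(1500, 10, seed = 91)
  cfg <- simulationConfig(gp$endo, gp$cont, contFraction = 0.5,
                          nFragments = 4000, seed = 92)
  sim <- simulateDataset(cfg)
  p <- partitionFragments(sim$alignments, twoTrackCalls(gp$endo, gp$cont))
  lm3 <- refitLengthModel(sim$alignments, p$endo, p$cont,
                          previous = fragmentLengthModel())
  expect_lt(lm3@muEndo, lm3@muCont)
  ## assignment requires overlapping a differing site, which over-selects
  ## longer fragments; allow for that selection bias in the absolute check
  expect_lt(abs(lm3@muEndo - log(45)), 0.2)
  expect_lt(abs(lm3@muCont - log(85)), 0.2)
})
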