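test_that("conditional deamination estimation counts terminal substitutions", {
  ## 100 forward fragments on a C...C reference; every fragment's
  ## 3' terminal shows C>T (the conditioning event), and 30 of 100 carry a
  ## 5' terminal C>T: the 5' position-0 rate must come out at 0.30
  ref <- paste(rep("C", 30), collapse = "")
  frags <- lapply(1:100, function(i) {
    b <- rep("C", 10)
    b[10] <- "T"                     # conditioning end
    if (i <= 30) b[1] <- "T"         # measured end
    ## error-free bases: the measured rate is the raw count 30/100
    list(start0 = 0, bases = paste(b, collapse = ""), eps = 0)
  })
  fa <- makeFrags(ref, frags)
  est <- estimateConditionalDeamination(fa, "single", maxDepth = 5L)
  expect_equal(unname(est$profile@end5[1, "C>T"]), 0.30, tolerance = 1e-12)
  expect_equal(est$nConditioning5, 100L)
  ## no mismatches beyond the measured terminal: all other rates are zero
  expect_true(all(est$profile@end5[2:5, ] == 0))
  expect_true(all(est$profile@end5[1, setdiff(colnames(est$profile@end5),
                                              "C>T")] == 0))
  ## mismatch-free fragments give all-zero rates (and no conditioning set)
  clean <- makeFrags(ref, lapply(1:5, function(i)
    list(start0 = 0, bases = paste(rep("C", 10), collapse = ""))))
  expect_error(estimateConditionalDeamination(clean, "single"),
               "no fragment")
})

test_that("fragment log-likelihoods follow the per-base product rule", {
  ref <- "CCCC"
  fa1 <- makeFrags(ref, list(list(start0 = 0, bases = "C", eps = 0)))
  expect_equal(fragmentLogLikNull(fa1), 0)
  ## independent bases multiply
  fa2 <- makeFrags(ref, list(list(start0 = 0, bases = "CT", eps = 0.3)))
  expect_equal(fragmentLogLikNull(fa2), log(1 - 0.3) + log(0.3 / 3),
               tolerance = 1e-12)
  ## single C>T mismatch under the null: eps * 1/3
  fa3 <- makeFrags(ref, list(list(start0 = 0, bases = "T", eps = 0.3)))
  expect_equal(fragmentLogLikNull(fa3), log(0.1), tolerance = 1e-12)
  ## and under the deamination model with terminal rate 0.3
  p <- deaminationProfile(maxDepth = 2L)
  p@end5[1, "C>T"] <- 0.3
  fa4 <- makeFrags(ref, list(list(start0 = 0, bases = "TC", eps = 0.01)))
  ld <- fragmentLogLikDeam(fa4, p)
  expect_equal(ld, log(0.99 * 0.3 + 0.01 / 3) + log(0.99), tolerance = 1e-12)
  ## zero profile: the two models coincide
  z <- deaminationProfile(maxDepth = 3L)
  g <- randomGenome(200, seed = 5)
  cfg <- simulationConfig(g, NULL, nFragments = 50, seed = 6)
  fa <- simulateDataset(cfg)$alignments
  expect_equal(fragmentLogLikDeam(fa, z), fragmentLogLikNull(fa),
               tolerance = 1e-12)
  ## a deaminated fragment scores higher under the deamination model
  ## whenever rate > eps/(3(1-eps))
  eps <- 0.1
  pSmall <- deaminationProfile(maxDepth = 2L)
  pSmall@end5[1, "C>T"] <- eps / (3 * (1 - eps)) + 0.01
  faD <- makeFrags("CAAA", list(list(start0 = 0, bases = "T", eps = eps)))
  expect_gt(fragmentLogLikDeam(faD, pSmall), fragmentLogLikNull(faD))
})

test_that("contamination posterior normalizes and flags flat likelihoods", {
  g <- randomGenome(500, seed = 11)
  cfg <- simulationConfig(g, NULL, nFragments = 300, seed = 12)
  fa <- simulateDataset(cfg)$alignments
  prof <- generatingProfile()
  curve <- contaminationPosterior(fa, prof)
  expect_equal(sum(curve@posterior), 1, tolerance = 1e-9)
  expect_true(curve@ciLow <= curve@map && curve@map <= curve@ciHigh)
  ## no deaminatable evidence (all-A reference): flat flag, full-range CI
  refA <- paste(rep("A", 50), collapse = "")
  faA <- makeFrags(refA, lapply(1:10, function(i)
    list(start0 = 0, bases = paste(rep("A", 20), collapse = ""))))
  flat <- contaminationPosterior(faA, prof)
  expect_true(isFlat(flat))
  expect_true(is.na(mapRate(flat)))
  expect_equal(unname(credibleInterval(flat)), c(0, 1))
})

test_that("contamination rate is recovered across mixing fractions", {
  ## the generating damage profile is an input here: recovery isolates the
  ## mixture estimator from profile-estimation noise
  gp <- makeGenomePair(3000, 20, seed = 7)
  prof <- generatingProfile()
  ## clean dataset: estimate stays near zero (full estimation path)
  cfg0 <- simulationConfig(gp$endo, gp$cont, contFraction = 0,
                           nFragments = 1000, seed = 31)
  cd0 <- contDeamEstimate(simulateDataset(cfg0)$alignments, "single")
  expect_lte(mapRate(cd0$curve), 0.05)
  for (cTrue in c(0.1, 0.3, 0.5, 0.7)) {
    cfg <- simulationConfig(gp$endo, gp$cont, contFraction = cTrue,
                            nFragments = 2000, seed = 40 + round(10 * cTrue))
    sim <- simulateDataset(cfg)
    curve <- contaminationPosterior(sim$alignments, prof)
    expect_lt(abs(mapRate(curve) - sim$fragContamination), 0.05)
  }
})

test_that("deaminated contaminants drag the estimate downward", {
  gp <- makeGenomePair(3000, 20, seed = 7)
  base <- simulationConfig(gp$endo, gp$cont, contFraction = 0.4,
                           nFragments = 3000, seed = 51)
  deamCont <- simulationConfig(gp$endo, gp$cont, contFraction = 0.4,
                               nFragments = 3000, seed = 51,
                               contTerminalRate = 0.2, contBaseline = 0.005)
  prof <- generatingProfile()
  mapClean <- mapRate(contaminationPosterior(simulateDataset(base)$alignments, prof))
  mapDeam <- mapRate(contaminationPosterior(simulateDataset(deamCont)$alignments, prof))
  expect_lt(mapDeam, mapClean)
})

test_that("conditioning raises measured rates when contamination is present", {
  gp <- makeGenomePair(3000, 20, seed = 7)
  cfg <- simulationConfig(gp$endo, gp$cont, contFraction = 0.5,
                          nFragments = 8000, seed = 61)
  fa <- simulateDataset(cfg)$alignments
  cond <- estimateConditionalDeamination(fa, "single")$profile
  ## unconditional rates over all fragments (diluted by the contaminant)
  uncond <- refitDeamination(fa, seq_len(length(fa)), useReference = TRUE)
  expect_gt(unname(cond@end5[1, "C>T"]), unname(uncond@end5[1, "C>T"]))
  expect_gt(unname(cond@end3[1, "C>T"]), unname(uncond@end3[1, "C>T"]))
})
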