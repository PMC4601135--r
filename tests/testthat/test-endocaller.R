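test_that("pair observation likelihood handles mapping and mixing weights", {
  pr <- endoPriors(contamination = 0.2)
  ## a mismapped fragment is uninformative about either template
  for (b in c("A", "C", "G", "T"))
    expect_equal(pObsGivenPair(b, "A", "C", eps = 0.01, dist5 = 3, dist3 = 8,
                               pEndoFragment = 0.7, m = 1, priors = pr), 0.25)
  ## fully endogenous, perfectly mapped: the endogenous term alone
  pe <- pObsGivenTemplate("A", "A", eps = 0.01, dist5 = 3, dist3 = 8,
                          which = "endogenous", priors = pr)
  expect_equal(pObsGivenPair("A", "A", "C", eps = 0.01, dist5 = 3, dist3 = 8,
                             pEndoFragment = 1, m = 0, priors = pr), pe)
  ## half/half: the arithmetic mean of the two template terms
  pc <- pObsGivenTemplate("A", "C", eps = 0.01, dist5 = 3, dist3 = 8,
                          which = "contaminant", priors = pr)
  expect_equal(pObsGivenPair("A", "A", "C", eps = 0.01, dist5 = 3, dist3 = 8,
                             pEndoFragment = 0.5, m = 0, priors = pr),
               (pe + pc) / 2, tolerance = 1e-12)
  ## contaminant branch with a zero contaminant profile is error-only
  expect_equal(pObsGivenTemplate("T", "C", eps = 0.12, dist5 = 0, dist3 = 0,
                                 which = "contaminant", priors = pr),
               pNull("C", "T", 0.12), tolerance = 1e-12)
})

test_that("site joint posterior is concentrated, uniform when empty", {
  pr <- endoPriors(contamination = 0.1)
  col <- data.frame(base = rep("A", 10), eps = 1e-3, d5 = 5, d3 = 5,
                    flip = FALSE, m = 0, pEndo = 1)
  s <- siteJointPosterior(col, pr)
  expect_equal(s$endoBase, "A")
  expect_lt(s$endoErr, 1e-20)
  expect_equal(sum(s$joint), 1, tolerance = 1e-9)
  ## empty column: uniform marginals, N calls, PHRED 0
  e <- siteJointPosterior(NULL, pr)
  expect_equal(unname(e$endoMarginal), rep(0.25, 4))
  expect_equal(e$endoBase, "N")
  expect_equal(e$endoPhred, 0)
})

test_that("joint posterior matches brute-force enumeration on random columns", {
  set.seed(42)
  err <- syntheticErrorModel()
  for (i in 1:40) {
    pr <- randomPriors()
    col <- randomColumn(nReads = sample(2:8, 1))
    s <- siteJointPosterior(col, pr, err)
    o <- oracleJoint(col, pr, err)
    expect_equal(s$joint, o, tolerance = 1e-9)
    ## Eq-20-style identity: error equals one minus the top marginal
    expect_equal(s$endoErr, 1 - max(s$endoMarginal), tolerance = 1e-12)
    expect_equal(sum(s$endoMarginal), 1, tolerance = 1e-9)
  }
})

test_that("fragment deamination posterior follows the prior algebra", {
  ref <- "CAAA"
  p <- deaminationProfile(maxDepth = 2L)
  p@end5[1, "C>T"] <- 0.3
  fa <- makeFrags(ref, list(list(start0 = 0, bases = "TAAA", eps = 0.01,
                                 mapq = 90)))
  ## no contamination prior: everything is endogenous
  pr0 <- endoPriors(contamination = 0, endoProfile = p)
  expect_equal(pFragmentDeamPosterior(fa, pr0), 1)
  ## zero profile: models coincide, posterior equals 1 - c_c
  prz <- endoPriors(contamination = 0.3)
  expect_equal(pFragmentDeamPosterior(fa, prz), 0.7, tolerance = 1e-12)
  ## terminally damaged fragment vs confident consensus at c_c = 0.5:
  ## hand-computed Bayes ratio on the single informative base
  pr5 <- endoPriors(contamination = 0.5, endoProfile = p)
  pd <- 0.99 * 0.3 + 0.01 / 3
  pn <- 0.01 / 3
  other <- 0.99^3          # the three matching A's, same in both models
  want <- (0.5 * pd * other) / (0.5 * pd * other + 0.5 * pn * other)
  got <- pFragmentDeamPosterior(fa, pr5)
  expect_equal(got, want, tolerance = 1e-9)
  expect_gt(got, 0.5)
})

test_that("length posterior implements the log-normal mixture", {
  same <- fragmentLengthModel(muEndo = log(50), sigmaEndo = 0.3,
                              muCont = log(50), sigmaCont = 0.3)
  expect_equal(pFragmentLengthPosterior(c(20, 50, 120), same, cc = 0.3),
               rep(0.7, 3), tolerance = 1e-12)
  ## hand-computed posterior from the two densities
  lm <- fragmentLengthModel(muEndo = log(45), sigmaEndo = 0.35,
                            muCont = log(85), sigmaCont = 0.35)
  l <- 50; cc <- 0.4
  de <- 1 / (l * sqrt(2 * pi) * 0.35) * exp(-(log(l) - log(45))^2 / (2 * 0.35^2))
  dc <- 1 / (l * sqrt(2 * pi) * 0.35) * exp(-(log(l) - log(85))^2 / (2 * 0.35^2))
  expect_equal(pFragmentLengthPosterior(l, lm, cc),
               (1 - cc) * de / ((1 - cc) * de + cc * dc), tolerance = 1e-12)
  ## the density itself at its log-mean: 1/(l sqrt(2 pi) sigma)
  expect_equal(de * exp((log(50) - log(45))^2 / (2 * 0.35^2)) *
                 exp(-(log(50) - log(45))^2 / (2 * 0.35^2)), de)
  ## shorter-endogenous model: posterior strictly decreasing in length
  post <- pFragmentLengthPosterior(20:150, lm, cc = 0.5)
  expect_true(all(diff(post) < 0))
  ## disabled model: length is uninformative
  off <- fragmentLengthModel(enabled = FALSE)
  expect_equal(pFragmentLengthPosterior(77, off, cc = 0.25), 0.75)
})

test_that("combined fragment evidence multiplies likelihoods, prior once", {
  g <- randomGenome(400, seed = 71)
  cfg <- simulationConfig(g, NULL, nFragments = 60, seed = 72)
  fa <- simulateDataset(cfg)$alignments
  p <- generatingProfile()
  ## length model disabled: reduces to the deamination posterior
  pr <- endoPriors(contamination = 0.3, endoProfile = p,
                   lengthModel = fragmentLengthModel(enabled = FALSE))
  expect_equal(pFragmentEndogenous(fa, pr), pFragmentDeamPosterior(fa, pr),
               tolerance = 1e-12)
  ## both channels neutral: the prior comes back
  przero <- endoPriors(contamination = 0.35)
  expect_equal(pFragmentEndogenous(fa, przero),
               rep(0.65, length(fa)), tolerance = 1e-12)
  ## short damaged fragment outranks a long undamaged one
  ref <- "CAAAAAAAAAAAAAAAAAAAAAAAAAAAAA"
  fa2 <- makeFrags(ref, list(
    list(start0 = 0, bases = "TAAAAAAAA", eps = 0.01),
    list(start0 = 1, bases = paste(rep("A", 28), collapse = ""), eps = 0.01)))
  prLen <- endoPriors(contamination = 0.5, endoProfile = p,
                      lengthModel = fragmentLengthModel(
                        muEndo = log(9), sigmaEndo = 0.3,
                        muCont = log(28), sigmaCont = 0.3))
  pe <- pFragmentEndogenous(fa2, prLen)
  expect_gt(pe[1], pe[2])
  expect_gt(pe[1], 0.9)
  expect_lt(pe[2], 0.1)
})

test_that("indel extension calls deletions by class", {
  pr <- endoPriors(contamination = 0.5)
  ## unanimous deletion, fully endogenous fragments
  col <- data.frame(base = rep(5L, 10), eps = 1e-3, d5 = 5, d3 = 5,
                    flip = FALSE, m = 1e-4, pEndo = 1)
  ic <- siteIndelCall(col, pr)
  expect_true(ic$endoDeletion)
  expect_lt(ic$endoErr, 0.01)
  ## gaps carried by the contaminant-like half only
  col2 <- data.frame(base = c(rep(5L, 8), rep(2L, 8)), eps = 1e-3,
                     d5 = 5, d3 = 5, flip = FALSE, m = 1e-4,
                     pEndo = c(rep(0.02, 8), rep(0.98, 8)))
  ic2 <- siteIndelCall(col2, pr)
  expect_true(ic2$contDeletion)
  expect_false(ic2$endoDeletion)
  ## no insertion evidence, no insertion call
  expect_equal(ic2$endoInsertion, "")
})

test_that("consensus calling recovers the endogenous genome at depth", {
  gp <- makeGenomePair(2000, 15, seed = 81)
  cfg <- simulationConfig(gp$endo, gp$cont, contFraction = 0.3,
                          nFragments = 4000, seed = 82)
  sim <- simulateDataset(cfg)
  fit <- runPipeline(sim$alignments, protocol = "single")
  expect_equal(countMismatches(endoSequence(finalCalls(fit)), gp$endo), 0)
  ## mismapped data carries no information: uniform site posteriors
  cd <- contDeamEstimate(sim$alignments, "single")
  pr <- endoPriors(contamination = mapRate(cd$curve), endoProfile = cd$profile)
  fr <- fragments(sim$alignments)
  fr$m <- rep(1, nrow(fr)); fr$mapq <- 0L
  fa0 <- mitoContam:::fragmentAlignments("ref", gp$endo, fr,
                                         observations(sim$alignments))
  calls0 <- callConsensus(fa0, pr, indels = FALSE)
  ct <- callTable(calls0)
  expect_true(all(abs(ct$eA - 0.25) < 1e-9))
  expect_true(all(abs(ct$cA - 0.25) < 1e-9))
  expect_true(all(ct$endoPhred[ct$coverage > 0] < 2))  # -10log10(3/4)
})

test_that("consensus robustness tracks contamination as expected", {
  ## endogenous track perfect through 50 % contamination; contaminant
  ## track improves (non-increasing mismatches) as contamination rises
  gp <- cachedFixture("gp10k", function() makeGenomePair(10000, 50, seed = 7))
  contMM <- c()
  for (cf in c(0.2, 0.5, 0.8)) {
    cfg <- simulationConfig(gp$endo, gp$cont, contFraction = cf,
                            nFragments = round(150 * 10000 /
                                                 ((1 - cf) * 48 + cf * 90)),
                            seed = 90 + round(10 * cf))
    sim <- simulateDataset(cfg)
    fit <- runPipeline(sim$alignments, protocol = "single")
    calls <- finalCalls(fit)
    if (cf <= 0.5)
      expect_equal(countMismatches(endoSequence(calls), gp$endo), 0)
    contMM <- c(contMM, countMismatches(contSequence(calls), gp$cont))
  }
  expect_true(all(diff(contMM) <= 0))
})
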