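fakeCalls <- function(endo, phred = 300) {
  n <- nchar(endo)
  b <- strsplit(endo, "")[[1]]
  eP <- matrix(0, n, 4)
  known <- b %in% BASES4
  eP[cbind(which(known), match(b[known], BASES4))] <- 1
  eP[!known, ] <- 0.25
  d <- data.frame(ref0 = 0:(n - 1), refBase = b, endoBase = b,
                  endoErr = 1e-30, endoPhred = phred, contBase = "N",
                  contErr = 1, contPhred = 0, coverage = 10L,
                  eA = eP[, 1], eC = eP[, 2], eG = eP[, 3], eT = eP[, 4],
                  cA = 0.25, cC = 0.25, cG = 0.25, cT = 0.25,
                  stringsAsFactors = FALSE)
  new("SiteCalls", refName = "ref", calls = d)
}

test_that("informative sites require a real allele difference", {
  calls <- fakeCalls("ACGTACGTAC")
  expect_equal(nrow(informativeSites(calls, "ACGTACGTAC")), 0L)
  two <- informativeSites(calls, "TCGTACGTAG")
  expect_equal(two$ref0, c(0L, 9L))
  ## IUPAC code containing the endogenous base is not informative
  expect_equal(nrow(informativeSites(calls, "RCGTACGTAC")), 0L)   # A in {A,G}
  expect_equal(nrow(informativeSites(calls, "YCGTACGTAC")), 1L)   # A not in {C,T}
  ## gaps and N never count
  expect_equal(nrow(informativeSites(calls, "-CGTACGTAN")), 0L)
})

test_that("site rate likelihood matches closed forms and the oracle", {
  pr <- endoPriors(contamination = 0.2)
  ## five error-free-ish reads of A with the endogenous prior on A:
  ## likelihood at c_r = 0 is (1-eps)^5 (m = 0)
  col <- data.frame(base = "A", eps = 1e-3, d5 = 5, d3 = 5, flip = FALSE,
                    m = 0)[rep(1, 5), ]
  eM <- c(1, 0, 0, 0); cP <- c(0, 0, 0, 1)
  ll <- siteRateLikelihood(col, eM, cP, cr = 0, priors = pr)
  expect_equal(ll, 5 * log(1 - 1e-3), tolerance = 1e-9)
  ## fully mismapped reads: (1/4)^n at every rate
  colm <- transform(col, m = 1)
  llm <- siteRateLikelihood(colm, eM, cP, cr = c(0, 0.3, 1), priors = pr)
  expect_equal(llm, rep(5 * log(0.25), 3), tolerance = 1e-12)
  ## brute-force double marginalization over Omega^2
  set.seed(7)
  err <- syntheticErrorModel()
  for (i in 1:25) {
    prr <- randomPriors()
    colr <- randomColumn(nReads = sample(2:6, 1))
    eMr <- runif(4); eMr <- eMr / sum(eMr)
    cPr <- runif(4); cPr <- cPr / sum(cPr)
    crs <- c(0, runif(2), 1)
    expect_equal(siteRateLikelihood(colr, eMr, cPr, crs, prr, err),
                 oracleRateLik(colr, eMr, cPr, crs, prr, err),
                 tolerance = 1e-9)
  }
})

test_that("database estimation recovers the rate and ranks the source", {
  gp <- makeGenomePair(2000, 15, seed = 31)
  cfg <- simulationConfig(gp$endo, gp$cont, contFraction = 0.5,
                          nFragments = 6000, seed = 32)
  sim <- simulateDataset(cfg)
  cd <- contDeamEstimate(sim$alignments, "single")
  pr <- endoPriors(contamination = mapRate(cd$curve), endoProfile = cd$profile)
  calls <- callConsensus(sim$alignments, pr)
  db <- c(true_cont = gp$cont,
          decoy1 = mutateGenome(gp$cont, 12, seed = 41),
          decoy2 = mutateGenome(gp$cont, 25, seed = 42),
          endo_like = mutateGenome(gp$endo, 10, seed = 43))
  est <- estimateContamination(sim$alignments, calls, db, pr)
  expect_equal(bestContaminant(est), "true_cont")
  expect_lt(abs(contaminationRate(est) - sim$perNucContamination), 0.05)
  expect_true(est@ciLow <= est@rate && est@rate <= est@ciHigh)
  ## posterior over the grid normalizes
  expect_equal(sum(est@curve@posterior), 1, tolerance = 1e-9)
  ## a db holding only the endogenous consensus has no informative sites
  expect_error(estimateContamination(sim$alignments, calls,
                                     c(same = endoSequence(calls)), pr),
               "no informative sites")
  ## divergent-database degradation: a 30-substitution-divergent stand-in
  ## for the true contaminant lowers the estimate
  far <- estimateContamination(sim$alignments, calls,
                               c(far = mutateGenome(gp$cont, 30, seed = 44)),
                               pr)
  expect_lt(contaminationRate(far), contaminationRate(est))
})

test_that("true contaminant wins the likelihood ranking across replicates", {
  gp <- makeGenomePair(2000, 15, seed = 51)
  db <- c(true_cont = gp$cont,
          d1 = mutateGenome(gp$cont, 10, seed = 52),
          d2 = mutateGenome(gp$cont, 14, seed = 53),
          d3 = mutateGenome(gp$cont, 18, seed = 54))
  wins <- 0L
  nrep <- 20L
  for (r in seq_len(nrep)) {
    cfg <- simulationConfig(gp$endo, gp$cont, contFraction = 0.4,
                            nFragments = 6000, seed = 100 + r)
    sim <- simulateDataset(cfg)
    cd <- contDeamEstimate(sim$alignments, "single")
    pr <- endoPriors(contamination = mapRate(cd$curve),
                     endoProfile = cd$profile)
    calls <- callConsensus(sim$alignments, pr)
    est <- estimateContamination(sim$alignments, calls, db, pr)
    if (bestContaminant(est) == "true_cont") wins <- wins + 1L
  }
  expect_gte(wins / nrep, 0.95)
})

test_that("diagnostic ratio reproduces the worked percentages", {
  dr <- diagnosticRatio(2443418, 1989785)
  expect_equal(dr$percent, 44.9)
  expect_equal(diagnosticRatio(1234, 0)$percent, 0)
  expect_equal(diagnosticRatio(0, 77)$percent, 100)
  expect_error(diagnosticRatio(0, 0), "no bases")
})
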