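# mitoContam

Joint inference of an ancient mitochondrial consensus sequence and the
present-day human contamination rate from aligned ancient-DNA (aDNA)
fragments.

## The problem

DNA recovered from ancient remains is short (typically < 60 bp), carries
cytosine deamination damage concentrated at fragment ends (read as C→T at
the 5' end, and as G→A at the 3' end for double-stranded library
protocols), and is mixed with DNA from the people who handled the sample.
Those present-day fragments align to the mitochondrial reference alongside
the endogenous ones, so naive consensus calling produces a chimeric genome
once contamination exceeds a few percent — and most contamination
estimators in turn need to know the endogenous genome. `mitoContam`
resolves the circularity by estimating both iteratively:

1. **Deamination prior** (`contDeamEstimate`). Endogenous deamination
   rates are measured by conditioning on the opposite fragment end being
   deaminated; each fragment `R_j` is then scored under a
   deamination+error model `P[R_j|¬C]` and an error-only model `P[R_j|C]`,
   and the mixture
   `P[R_j|c] = (1−c)·P[R_j|¬C] + c·P[R_j|C]`
   is maximized over a grid of contamination rates `c` with a uniform
   prior (MAP with a 95% highest-posterior-density interval).
2. **Joint consensus** (`callConsensus`). At every site the posterior over
   all pairs (b_e, b_c) of endogenous and contaminant bases is
   `P[b_e,b_c|R] ∝ ∏_j P[R_j|b_e,b_c] · 1/16`, where each observation
   mixes the two templates by the fragment's probability of being
   endogenous `P[R_j ∈ E]` (from its deamination pattern and a log-normal
   fragment-length mixture) and its mapping quality:
   `P[r_i|b_e,b_c] = (1−m)·[P_E·P_e(r_i|b_e) + (1−P_E)·P_c(r_i|b_c)] + m/4`.
   Marginalizing gives both consensus tracks with PHRED-scaled qualities.
3. **Database estimate** (`estimateContamination`). At sites where the
   endogenous call and a candidate contaminant genome differ, the
   per-nucleotide rate `c_r` enters
   `(1−c_r)·P_e[r_i|b_e] + c_r·P_c[r_i|c]`, marginalized over the
   consensus marginals and the candidate's (IUPAC-aware) base; the
   candidate with the highest likelihood is the inferred contamination
   source, and the high-quality contaminant consensus itself can join the
   database.
4. **Partition and refresh** (`partitionFragments`, `refitDeamination`,
   `refitLengthModel`). Fragments supporting the endogenous vs contaminant
   allele re-estimate the deamination profiles and the two log-normal
   length distributions for the next round.

`runPipeline` repeats 2–4 until the contamination estimate stabilizes, and
stops early (reporting the deamination-based prior) when the data carry
too little information about the contaminant. A seeded aDNA simulator
(`simulateDataset`) generates alignments with complete truth labels, so
every estimator is testable without external data.

## Worked example

```r
library(mitoContam)

gp  <- makeGenomePair(10000, 50, seed = 7)     # endo genome + contaminant
cfg <- simulationConfig(gp$endo, gp$cont, contFraction = 0.5,
                        nFragments = 60000, protocol = "single", seed = 61)
sim <- simulateDataset(cfg)
sim$perNucContamination
#> [1] 0.6476331

fit <- runPipeline(sim$alignments,
                   db = c(divergent = mutateGenome(gp$cont, 30, seed = 99)),
                   protocol = "single", verbose = TRUE)
#> contDeam prior: 0.440
#> iteration 1: c_r = 0.605 (delta 0.1650)
#> iteration 2: c_r = 0.645 (delta 0.0400)
#> iteration 3: c_r = 0.645 (delta 0.0000)
contaminationRate(fit)
#> [1] 0.645
```

Half of the simulated *fragments* are contaminant, but contaminant
molecules are longer, so 64.8% of *bases* are contaminant — the quantity
the database estimator targets; the run recovers 0.645. The deamination
prior (0.44) estimates the fragment fraction instead. The final
endogenous consensus matches the simulated genome exactly
(`endoSequence(finalCalls(fit))`), even at 50% contamination, and the
database table in `fit@estimate` shows the predicted contaminant record
outranking the 30-substitution-divergent database entry, whose own
estimate (0.405) illustrates the divergence-driven underestimate.

A worked single-number helper: with 2,443,418 bases supporting the
endogenous allele and 1,989,785 supporting the contaminant allele at
diagnostic positions,

```r
diagnosticRatio(2443418, 1989785)$percent
#> [1] 44.9
```

## Command line

A thin front-end over the same functions is installed at
`system.file("scripts", "mitocontam", package = "mitoContam")` with
subcommands `contdeam`, `endocaller`, `mtcont`, `splitendo`, `run`,
`simulate` and `diagratio`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — it simulates a 10 kb genome pair at 50% fragment contamination,
runs the full iterative pipeline, and prints the recovered contamination
rate and consensus accuracy — then writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
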