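---
title: "Models and methods behind mitoContam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitoContam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitoContam)
```

# Scope

`mitoContam` infers, from ancient-DNA fragments aligned to a
mitochondrial reference, (i) the endogenous consensus genome, (ii) the
consensus of the present-day contaminant, and (iii) the contamination
rate, iterating the three estimates until the rate stabilizes. This
vignette documents the models, every tunable that matters, what the
simulator does and does not emulate, and the numerical and design choices
a maintainer would want to know.

# Observation model

Every aligned base is scored against a candidate template `b` with two
per-base likelihoods. Under the *error-only* model,

```
P_n[r] = (1 - eps)            if b == r
         eps * P[b->r | E]    otherwise
```

with `eps` the base caller's error probability and `P[b->r|E]` a
substitution matrix (uniform 1/3 by default; an empirical matrix can be
supplied as TSV — the packaged one is synthetic and exists to exercise
that code path). Under the *deamination* model the mismatch branch gains
`(1 - eps) * rate(b->r)` and the match branch loses the total
substitution outflow, `(1 - eps) * (1 - sum rate(b->b'))`. The joint
event "deaminated *and* miscalled" is ignored as second order; the
per-base likelihood still normalizes to 1 over the four observed bases.

Deamination rates are position-dependent: a `DeaminationProfile` holds
one rate row per distance from each fragment end, in original-molecule
orientation. Reverse-strand observations are mirrored (their distances
swapped, substitution types complemented) before lookup, so C→T damage
on the molecule is correctly seen as G→A in reference-forward storage.
The two ends combine *additively* with clamping at 1: terminal damage has
nearly disjoint support at the two ends, and an additive field
`rate(d5, d3) = end5[d5] + end3[d3]` is the simplest combination that is
exact when either term is zero.

**Additive identifiability.** Rates measured by counting mismatches at
distance `d` from one end estimate `f(d) + g_inf`, where `g_inf` is the
other end's interior tail — so summing two measured ends double-counts
the interior baseline. Profile estimators therefore subtract half of the
shared deep-interior asymptote from every row of both ends (the additive
decomposition is identifiable only up to this constant), pool all
deep-interior observations into the last row so the beyond-depth
extrapolation has a large denominator, and subtract the expected
sequencing-error floor (`eps/3` per ordered substitution) from the
counted rates. Without these corrections the contamination mixture
(below) inherits a bias of several percentage points.

# Deamination-based contamination prior

Only endogenous molecules are assumed deaminated (documented caveat: a
deaminated contaminant drags the estimate down, and a test asserts that
direction). Endogenous rates are estimated *conditionally*: for each end,
from fragments whose opposite terminal base shows the protocol's
deamination substitution (C→T at 5'; C→T at 3' for single-stranded
libraries, G→A for double-stranded). The conditioning window is the
terminal base by default and is configurable.

Each fragment then yields two log-likelihoods — all differences from the
reference explained by deamination+error, or by error alone — and the
fragment-level mixture over a contamination grid (step 0.005, matching
the reported precision of this class of estimator) gives a posterior
under a uniform prior; we report its MAP and a 95%
highest-posterior-density interval (the interval construction is our
choice; nothing in the underlying method pins it down).

**Terminal scoring window.** By default only bases within 5 positions of
either fragment end enter these products (`endWindow`). Two reasons,
both measured during development: (i) with interior baseline damage,
per-fragment information grows with length, and because contaminant
molecules are systematically longer, a length-blind mixture becomes
asymptotically biased upward — restricting to the ends makes information
per fragment length-independent; (ii) sites where the contaminant truly
differs from the reference masquerade as damage under the
reference-template assumption, and a short window minimizes exposure to
them while retaining >97% of a geometrically decaying damage signal.
`endWindow = 0` restores whole-fragment scoring.

# Joint consensus calling

At each reference position the caller enumerates all 16 pairs
`(b_e, b_c)` with a flat 1/16 prior. Each overlapping observation
contributes

```
(1 - m) * [ pE * P_e(r | b_e)  +  (1 - pE) * P_c(r | b_c) ]  +  m / 4
```

where `m = 10^(-MAPQ/10)` is the mismapping probability (a mismapped read
is uninformative, hence the flat 1/4) and `pE` is the fragment's
probability of being endogenous. Marginal posteriors over `b_e` and `b_c`
give the two consensus calls; the error of a call is one minus its
marginal, reported as a PHRED score capped at 9999. Empty columns yield
`N` with PHRED 0. All products run in log space with log-sum-exp
normalization; the vectorized column kernel is checked against an
independent scalar enumeration oracle at 1e-9 on hundreds of random
columns.

`pE` combines two class-conditional likelihood channels — the
deamination/error products (marginalized over the endogenous base with
the previous consensus marginals as weights) and the two log-normal
length densities — multiplied together with the contamination prior
applied **once**. Chaining the two channel posteriors instead would
square the prior; multiplying likelihoods is the naive-Bayes reading of
"combining" the evidence. At iteration 0 no consensus marginals exist
yet, so the mapping reference serves as the template with weight 1; later
iterations use the previous round's marginals.

**Indels** extend the per-site symbol set with a gap whose observation
channel is a simple binary error model at the neighbouring base quality,
and insertions are keyed on observed insertion strings with a flat prior
over observed strings plus "no insertion". This is a deliberately
simplified stand-in (the full supplementary indel likelihood of the
original method is not reproduced in its main text) and is documented as
such; the simulator does not generate indels.

# Database contamination estimate

At sites where the endogenous call differs from a candidate contaminant
record (IUPAC codes count as differing only when the called base lies
outside the code's set; gaps and N never), the per-nucleotide rate enters
a two-template mixture per observation, with the endogenous branch under
the deamination model weighted by the consensus marginals and the
candidate branch error-only. The likelihood is evaluated per candidate on
the **union** of informative sites across the database: restricting each
candidate to its own sites makes likelihoods with different term counts
incomparable (a candidate identical to the endogenous call would win with
an empty product), and the union restores comparability while candidates
with no informative sites of their own are flagged degenerate and
excluded. The high-quality (PHRED ≥ 200) contaminant consensus can be
appended to the database; at moderate-to-high contamination this record
typically wins and markedly improves the estimate, while a database whose
nearest record is tens of substitutions from the true contaminant
underestimates — both behaviours are asserted in tests.

# Partitioning and re-estimation

Fragments overlapping at least one site where the two consensus tracks
differ (both calls at or above PHRED 30 by default) are assigned by
majority vote of matching alleles; ties and non-overlapping fragments
stay unassigned (the rule for multi-site fragments is our choice). Each
set then re-fits its deamination profile — against its own inferred
consensus rather than the mapping reference, so genuine divergence is not
misread as damage; the literal reference remains available behind a flag
— and the log-normal length model via the closed-form MLE
(`mu = mean(log l)`, `sigma = sd(log l)`, floored at 0.01; sets smaller
than 30 fragments keep the previous parameters). Note the selection
effect: only fragments overlapping a differing site are assigned, which
over-samples long fragments; with few informative sites the refit length
means are biased upward by a few percent, which the iteration tolerates.

# Iteration

Iteration 0: deamination prior, zero contaminant profile, length model
disabled. Each subsequent round feeds the database estimate and the
refreshed profiles/length model back into the caller. Convergence is
declared when the rate moves less than 0.005 (the grid step); at most 10
rounds. If no differing sites support a partition or every candidate is
degenerate, the run stops early, is flagged "insufficient contaminant
information", and reports the deamination-based prior — the expected path
for contamination-free data. Runs are deterministic given the input and
seed; with `outDir` set, every iteration's consensus, profiles and a
trace table are written under `iter_<t>/` for audit.

# The simulator and what a green test establishes

`simulateDataset` draws fragment origin (Bernoulli at the contaminant
fraction), length (log-normal: endogenous ln N(ln 45, 0.35), contaminant
ln N(ln 85, 0.35) — ancient molecules are shorter), uniform start without
origin wrap, strand at 1/2, then applies terminal deamination in molecule
orientation with `rate(i) = baseline + terminal * decay^i`
(defaults 0.01 + 0.30 * 0.5^i; the originally cited empirical profiles
are not reprinted anywhere accessible, so a parametric stand-in with the
same terminal behaviour is used), sequencing errors at a constant base
quality (Q30, so `eps` is honest), and constant MAPQ 37. The truth table
records per-fragment origin and damage counts, and the per-nucleotide
contamination (contaminant bases over total bases) — the quantity the
database estimator targets, which exceeds the fragment fraction whenever
contaminant molecules are longer.

Not emulated: indel damage, paired-end reads, microbial background,
multiple simultaneous contaminants, quality-score miscalibration, and
circular coverage. The last matters for evaluation: on a linearized
circular genome the termini are covered only by fragment-terminal
(maximally damaged) bases at depth ~n/L, so accuracy comparisons in the
tests exclude one minimum fragment length (20 bp) at each end and do not
count uncalled `N` sites. A green consensus test therefore establishes
recovery under idealized mapping and quality calibration on the interior
of the reference — not robustness to alignment artifacts, reference bias,
or capture bias.

# Numerical choices

Log-space products with log-sum-exp throughout; probabilities floored at
1e-300 before logging; PHRED cap 9999; grid step 0.005 on [0, 1]; HPD
intervals on the normalized grid posterior; `which.max` ties resolve to
the first (alphabetical) base; per-base observation likelihoods are exact
(no sampling). The per-site caller and the grid likelihoods are exercised
against independent brute-force enumerations at 1e-9.

# Known limitations

Single contaminant per site by assumption; contamination below ~1% leaves
the contaminant consensus essentially uncalled (low PHRED), which is
expected and triggers the early-stop path; heavy uracil-DNA-glycosylase
treatment removes the damage signal the whole approach rests on; and the
deamination prior underestimates when the contaminant itself is
deaminated.
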