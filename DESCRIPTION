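Package: mitoContam
Title: Ancient Mitochondrial Consensus Calling and Present-Day Contamination
    Estimation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint inference of the endogenous ancient mitochondrial consensus
    sequence, the contaminant consensus, and the present-day human
    contamination rate from ancient-DNA fragments aligned to a mitochondrial
    reference. Cytosine deamination patterns at fragment ends, log-normal
    fragment-length mixtures, per-base sequencing error and mapping
    probabilities are combined in a Bayesian maximum a posteriori framework.
    Includes a deamination-conditioned contamination prior, a per-site joint
    endogenous/contaminant base caller, a database-driven contamination rate
    estimator, fragment partitioning for iterative re-estimation, and an
    ancient-DNA read simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SequenceMatching, Alignment, Coverage, Bayesian
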