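Package: clinecall
Title: Hybrid-Zone Cline Fitting, Ancestry Estimation and Bioacoustic
    Reinforcement Tests
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing narrow hybrid zones between incipient
    species: selection of species-diagnostic SNPs from reference panels,
    K=2 ancestry estimation by an EM algorithm on a binomial admixture
    likelihood, two-parameter sigmoid geographic cline fitting with
    profile-likelihood confidence intervals and barrier-locus flagging,
    and a bioacoustic test battery for reinforcement (convex-hull
    overlap, centroid distance and variance-reduction Delta statistics
    with a permutation null and a down-sampling variant). Includes
    seeded generators for genotype transects, reference panels,
    mitochondrial haplotypes and advertisement-call datasets so the full
    pipeline can be exercised end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
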