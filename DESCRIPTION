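Package: ecoevotrack
Title: Eco-Evolutionary Rate Estimation for Wild Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies ecological and evolutionary dynamics of bacterial
    communities tracked through time under environmental perturbation.
    Provides coloniser and connectivity statistics on amplicon (ASV/genus)
    count tables with compositional (CLR) transforms and diversity summaries;
    a Wright-Fisher drift calibration that turns metagenome SNV polymorphism
    and paired-timepoint allele-frequency changes into effective population
    sizes and generation times; a simplified peak-to-trough ratio (PTR)
    estimator of in-situ growth rate from circular-genome coverage; and the
    analysis of time-shift spent-media assays (interaction coefficients,
    strongest-reduction tallies, exact multinomial column tests). A
    synthetic-data generator with known ground truth makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
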