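Package: dbsa
Title: Drug-Induced Behavioral Signature Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: In silico phenotypic screening of compound libraries against
    the behavioral signature of a disease model. Implements a two-tailed,
    single-pass enrichment statistic (weighted Kolmogorov-Smirnov running
    sums over increased and decreased feature sets) that ranks drug
    profiles by their potential to reverse a disease signature, with
    permutation p-values and a cross-stratum consistency filter.
    Includes Decorrelated Ranked Feature Analysis: a Discrimination Index
    with subsampling significance for phenotypic separation of two
    groups, and a Recovery Index quantifying treatment rescue along the
    model-to-control axis in a decorrelated feature space. A synthetic
    cohort and drug-library generator with planted ground truth makes the
    whole pipeline testable without proprietary phenotyping data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, BehavioralResearch, Pharmacogenomics, GeneSetEnrichment
RoxygenNote: 7.3.3
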