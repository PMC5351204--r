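Package: methshift
Title: Case-Control RRBS Differential Methylation and Global
    Hypermethylation-Shift Testing
Version: 0.1.0
Authors@R:
    person("Methshift", "Developers", email = "methshift@example.org",
           role = c("aut", "cre"))
Description: Tools for reduced representation bisulfite sequencing (RRBS)
    case-control analysis of CpG and CpH methylation: coverage filtering and
    median normalization of cytosine counts, surrogate variable analysis with
    iterative sample-outlier removal validated by cis-meQTL recovery,
    per-site weighted linear models with a residual-bootstrap empirical null,
    a global test for an excess of hypermethylated sites at nominal p-value
    cutoffs, bump-hunting detection of differentially methylated regions with
    bootstrap family-wise error rates, Fisher-exact enrichment of
    hypermethylated sites in functional genomic categories, and two-sample
    unequal-n power calculations. Includes a synthetic RRBS data generator
    emulating the statistical structure the analysis assumes, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
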