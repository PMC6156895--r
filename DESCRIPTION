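Package: globalp
Title: Annotation-Based Detection of Differentially Methylated Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) from Illumina-style
    methylation array data by grouping probes into biologically annotated regions
    (gene functional categories and CpG island relations) and testing each region
    with a quadratic-form chi-square statistic built from per-probe EWAS z-scores
    and the estimated inter-probe partial-correlation matrix. Includes the
    kinship-aware mixed-model EWAS stage that produces the z-scores (restricted
    maximum likelihood with a pedigree-derived additive relationship matrix), the
    beta/M-value transform and probe-exclusion preprocessing, Benjamini-Hochberg
    false discovery rate control across regions, and a simulator of
    family-structured methylation studies with planted region effects for
    calibration and power experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
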