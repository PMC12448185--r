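Package: cnseg
Title: Integration, Consistent Segmentation and Feature Extraction for
    Somatic Copy-Number Profiles
Version: 0.3.0
Authors@R:
    person("Adam", "Novak", email = "anovak@example.org", role = c("aut", "cre"))
Description: Tools for integrating somatic copy-number alteration (SCNA)
    profiles from heterogeneous cohorts and callers into a single comparable
    matrix. Provides gap imputation (extension, diploid, null), sex-aware
    per-sample statistics (CN-coverage, genome-not-diploid, loss of
    heterozygosity, allelic imbalance, breakpoint counts and step sizes),
    cohort-consistent segmentation (region selection, exclusion subtraction
    with a fragment filter, greedy breakpoint merging, fixed-width binning),
    copy-number aggregation (min/max/length-weighted mean), sample-level
    quality filters (z-score outliers, knee/elbow detection on cumulative
    feature curves), exploratory segment statistics (normalized Manhattan
    distance, outlier and contrastive outlier scores, peak scores,
    Mann-Whitney U discriminatory-feature tests), a seeded synthetic-cohort
    generator with ground truth, and a command-line pipeline front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
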