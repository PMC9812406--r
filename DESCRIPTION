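Package: metaboguilt
Title: Guilt-by-Association Gene Function Inference from Dynamic Metabolome Profiles
Version: 0.1.0
Authors@R: person("Metabolomics", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for dynamic (time-course) untargeted metabolome
    profiling of mutant libraries. Implements outlier filtering and LOWESS
    detrending of flow-injection intensities against acquisition order and
    culture density, mutant-versus-wild-type log2 fold-change profiles with
    per-metabolite tests, per-timepoint Pearson correlation and Manhattan
    distance matrices with Ward clustering, a distance-to-positive-set
    classifier with permutation empirical p-values and ROC-based recovery of
    annotated regulators, candidate nomination at a fixed false-positive
    rate, growth-curve rate and lag estimation, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
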