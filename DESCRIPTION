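Package: survarea
Title: Risk Group Discovery by Optimizing the Area Under the Survival Curve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Finds patient risk groups in right-censored survival data by
    training ensembles of single-hidden-layer neural membership classifiers
    with a steady-state genetic algorithm. Each classifier is rewarded by the
    area under the Kaplan-Meier curve of the group it selects (maximized for
    low-risk groups, minimized for high-risk groups) subject to a hard minimum
    group size, and an odd-by-odd ensemble votes each subject into a high,
    intermediate, or low risk group. Includes Kaplan-Meier utilities, the
    preprocessing pipeline (categorical binarization, mean imputation,
    z-normalization, censoring-stratified splits), group-size-matched cuts on
    prognostic indices for comparator models, repeated cross-validation
    summaries, and a synthetic-data generator with known latent risk strata.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
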