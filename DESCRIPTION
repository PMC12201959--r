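Package: idscn
Title: Individualized Differential Structural Covariance Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs individualized differential structural covariance
    networks (IDSCN) from regional grey-matter-volume tables by leave-one-in
    perturbation of a covariate-adjusted control correlation network, derives
    per-patient Z-scored edge deviations with Bonferroni-corrected
    significance, stratifies patients by k-means clustering on prevalent
    deviant edges with silhouette-based model selection, and characterizes the
    resulting subtypes on edges, regional volumes, clinical scores and
    demographics. Includes a seeded synthetic-cohort generator with planted
    edge perturbations, subtype structure and symptom coupling for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
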