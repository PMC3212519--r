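Package: muscleMeta
Title: Dual-Statistic Differential Expression and Cross-Study Meta-Analysis
    of Atrophying Skeletal Muscle Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a reusable pipeline for calling differentially
    expressed genes in muscle microarray studies with two independent
    statistics (a permutation-based relative-difference statistic with
    fudge-factor standard-error regularisation, and an empirical-Bayes
    moderated t), intersecting the two calls, and cross-validating the
    resulting signature against multi-dataset compendia through
    probe collapsing, meta-matrix merging, ternary per-gene status calls
    on a 3x3 status-pair grid of meta-clusters, and a sex-bias screen.
    Direction-aware hypergeometric bias testing of gene sets (GO terms,
    transcription-factor binding-site target sets) within meta-clusters
    and candidate transcription-factor selection are included, together
    with average-linkage Pearson clustering and TreeView-compatible
    CDT/GTR output.  A synthetic-data generator reproduces the statistical
    structure of a two-condition case/control compendium (dataset offsets,
    inverse-chi-square gene variances, replicate probes, sex effects,
    planted status pairs and enriched gene sets) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    limma,
    fgsea,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
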