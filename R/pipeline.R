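## End-to-end driver on synthetic data: in-lab dual-statistic DEG calling,
## compendium meta-analysis, sex-bias screen, set-bias testing, clustering
## and TreeView export.  Fully deterministic given the configuration seed.

#' Run the full synthetic-study pipeline
#'
#' Generates an in-lab study and a multi-dataset compendium from one
#' ground truth, then runs every stage: spot consolidation, validity
#' filtering, SAM-style + moderated-t intersection calls per condition,
#' partition of the call lists, per-condition meta-matrices with ternary
#' status calls, meta-cluster assignment, cross-validation verdicts,
#' sex-bias screen, gene-set bias testing, candidate-TF selection when a
#' TFBS map is given, and average-linkage clustering of the in-lab
#' matrix.  When `outDir` is given, all result tables are written as TSV
#' and the clustered matrix as a CDT/GTR pair; identical configurations
#' yield byte-identical files.
#'
#' @param config A [syntheticConfig()].
#' @param outDir Optional output directory (created if needed).
#' @param sets Optional [GeneSetList-class] to test for cluster bias;
#'   default: sets generated from the truth by [generateGeneSets()].
#' @param tfbsToTf Optional `data.frame` (`set_name`, `tf_gene_id`) for
#'   candidate-TF selection.
#' @param nPerm Permutations for the SAM-style statistic.
#' @param qMax,pMax Intersection-rule thresholds.
#' @param pStatus Status-call p-value threshold.
#' @return Invisible list with components `truth`, `inlab` (gene-level
#'   filtered matrix), `degDmd`, `degAge`, `partition`, `metaDmd`,
#'   `metaAge`, `statusDmd`, `statusAge`, `metaClusters`, `validation`,
#'   `sexBias`, `enrichment`, `candidateTfs`, `geneTree`, and `files`
#'   (written paths, when `outDir` is used).
#' @export
runSyntheticPipeline <- function(config, outDir = NULL, sets = NULL,
                                 tfbsToTf = NULL, nPerm = 300L,
                                 qMax = 0.02, pMax = 0.01,
                                 pStatus = 0.01) {
  truth <- generateTruth(config)
  inlab <- generateInLabStudy(config, truth)
  comp <- generateCompendium(config, truth)
  if (is.null(sets)) sets <- generateGeneSets(truth, config)

  ## ---- in-lab arm: consolidate spots, filter, dual-statistic calls
  geneLevel <- consolidateReplicates(inlab$experiment)
  geneLevel <- suppressMessages(filterValid(geneLevel))
  callCohort <- function(cohort, permSeed) {
    keep <- sampleCohort(geneLevel) == cohort |
      sampleCondition(geneLevel) == "CONTROL"
    sub <- geneLevel[, keep]
    sam <- samAnalyze(sub, nPerm = nPerm, seed = permSeed)
    eb <- eBayesModeratedT(sub)
    intersectDegs(sam, eb, qMax = qMax, pMax = pMax)
  }
  degDmd <- callCohort("DMD", .subSeed(config$seed, 301L))
  degAge <- callCohort("AGE", .subSeed(config$seed, 302L))
  partition <- partitionSets(degDmd, degAge)

  ## ---- compendium arm: collapse probes, merge, status grid
  prepOne <- function(ds) {
    centered <- log2MedianCenter(ds)
    suppressMessages(collapseProbes(centered))
  }
  byCohort <- function(cohort) {
    nms <- grep(paste0("^", cohort), names(comp$datasets), value = TRUE)
    lapply(comp$datasets[nms], prepOne)
  }
  metaDmd <- buildMetaMatrix(byCohort("DMD"), condition = "DMD")
  metaAge <- buildMetaMatrix(byCohort("AGE"), condition = "AGE")
  statusDmd <- callStatus(metaDmd, pThreshold = pStatus)
  statusAge <- callStatus(metaAge, pThreshold = pStatus)
  metaClusters <- assignMetaClusters(statusDmd, statusAge)
  validation <- crossValidate(partition, statusDmd, statusAge)
  sexBias <- rbind(cbind(condition = "DMD",
                         detectSexBias(metaDmd, pThreshold = pStatus)),
                   cbind(condition = "AGE",
                         detectSexBias(metaAge, pThreshold = pStatus)))

  ## ---- set-bias arm
  universe <- metaClusters$gene_id
  enr <- suppressMessages(enrichClusters(metaClusters, sets, universe))
  tfs <- if (!is.null(tfbsToTf))
    selectCandidateTfs(enr, tfbsToTf, statusDmd, statusAge) else NULL

  ## ---- display arm
  geneTree <- suppressMessages(hierarchicalCluster(geneLevel, "genes"))

  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wTab <- function(df, nm) {
      p <- file.path(outDir, nm)
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    }
    files <- c(
      expr = writeExpressionTsv(geneLevel,
                                file.path(outDir, "inlab_genes.tsv"),
                                file.path(outDir, "inlab_annotation.tsv")),
      deg_dmd = wTab(degDmd, "deg_dmd.tsv"),
      deg_age = wTab(degAge, "deg_age.tsv"),
      partition = wTab(partition, "deg_partition.tsv"),
      status_dmd = wTab(statusDmd, "status_dmd.tsv"),
      status_age = wTab(statusAge, "status_age.tsv"),
      clusters = wTab(metaClusters, "meta_clusters.tsv"),
      validation = wTab(validation, "validation.tsv"),
      sex_bias = wTab(sexBias, "sex_bias.tsv"),
      enrichment = wTab(enr, "enrichment.tsv"))
    keep <- rownames(geneLevel) %in% attr(geneTree, "dropped") == FALSE
    files <- c(files,
               writeCdtGtr(geneLevel[keep, ], geneTree,
                           pathPrefix = file.path(outDir, "inlab")))
  }

  invisible(list(truth = truth, inlab = geneLevel,
                 degDmd = degDmd, degAge = degAge, partition = partition,
                 metaDmd = metaDmd, metaAge = metaAge,
                 statusDmd = statusDmd, statusAge = statusAge,
                 metaClusters = metaClusters, validation = validation,
                 sexBias = sexBias, enrichment = enr,
                 candidateTfs = tfs, geneTree = geneTree,
                 files = files))
}
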