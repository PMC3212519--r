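## Cross-study validation: probe collapsing, per-condition meta-matrix
## assembly, ternary status calls, 3x3 status-pair meta-clusters,
## cross-validation verdicts and the sex-bias screen.

#' Collapse multi-probe genes to their most discriminating probe
#'
#' For every gene measured by several probes, only the probe with the
#' smallest two-sided Student-t p-value between the CASE and CONTROL
#' groups is retained; exact p ties are broken by the lexicographically
#' smallest probe id so the result is deterministic.  Genes with no probe
#' on which the test is computable are dropped and reported (attribute
#' `"dropped_genes"` of the result's metadata).
#'
#' @param x Probe-level [MuscleExperiment-class].
#' @param probeMap Optional `data.frame` (`probe_id`, `gene_id`)
#'   overriding `rowData(x)$gene_id`.
#' @param grouping Passed to [studentT()].
#' @return Gene-level [MuscleExperiment-class] (rows keyed by gene id).
#' @export
collapseProbes <- function(x, probeMap = NULL, grouping = NULL) {
  m <- exprsMatrix(x)
  gene <- if (is.null(probeMap)) geneIds(x)
  else {
    hit <- match(rownames(m), probeMap$probe_id)
    if (anyNA(hit))
      stop("probe(s) absent from probe map: ", rownames(m)[is.na(hit)][1L])
    probeMap$gene_id[hit]
  }
  tt <- studentT(x, grouping)
  p <- tt$p
  p[tt$degenerate] <- NA_real_          # not a usable discriminating probe
  ord <- order(gene, p, rownames(m), na.last = TRUE)
  first <- !duplicated(gene[ord])
  pick <- ord[first]
  usable <- !is.na(p[pick])
  droppedGenes <- gene[pick][!usable]
  if (length(droppedGenes))
    message("collapseProbes: dropped ", length(droppedGenes),
            " gene(s) with no valid probe")
  pick <- pick[usable]
  ## restore first-seen gene order
  pick <- pick[order(match(gene[pick], unique(gene)))]
  out <- m[pick, , drop = FALSE]
  rownames(out) <- gene[pick]
  res <- MuscleExperiment(out,
                          as.data.frame(SummarizedExperiment::colData(x)))
  S4Vectors::metadata(res)$dropped_genes <- droppedGenes
  S4Vectors::metadata(res)$kept_probes <-
    stats::setNames(rownames(m)[pick], gene[pick])
  res
}

#' Merge gene-level datasets into a per-condition meta-matrix
#'
#' Concatenates the columns of several gene-level datasets of one case
#' condition (each with its own CONTROL samples) over their common gene
#' universe.  Every dataset is median-centered on genes before the merge
#' (idempotent if already centered), so dataset-specific offsets cannot
#' leak into downstream tests.
#'
#' @param datasets List of gene-level [MuscleExperiment-class] objects.
#' @param condition Condition label recorded in the result's metadata
#'   (`"DMD"` or `"AGE"`).
#' @param merge `"intersection"` (default) restricts to genes present in
#'   every dataset; `"union"` keeps all genes, with missing values where
#'   a dataset lacks the gene (no imputation; per-gene t-test degrees of
#'   freedom degrade accordingly).
#' @return A [MuscleExperiment-class] with `metadata(x)$condition` set.
#' @export
buildMetaMatrix <- function(datasets, condition = "DMD",
                            merge = c("intersection", "union")) {
  merge <- match.arg(merge)
  stopifnot(length(datasets) >= 1)
  datasets <- lapply(datasets, log2MedianCenter, alreadyLog = TRUE)
  geneLists <- lapply(datasets, rownames)
  genes <- if (merge == "intersection") Reduce(intersect, geneLists)
  else Reduce(union, geneLists)
  if (!length(genes))
    stop("datasets share no genes; empty meta-matrix")
  mats <- lapply(datasets, function(d) {
    m <- exprsMatrix(d)
    out <- matrix(NA_real_, length(genes), ncol(m),
                  dimnames = list(genes, colnames(m)))
    hit <- intersect(genes, rownames(m))
    out[hit, ] <- m[hit, , drop = FALSE]
    out
  })
  ann <- do.call(rbind, lapply(datasets, function(d)
    as.data.frame(SummarizedExperiment::colData(d))))
  rownames(ann) <- NULL
  if (anyDuplicated(ann$sample_id))
    stop("sample ids collide across datasets")
  meta <- MuscleExperiment(do.call(cbind, mats), ann)
  S4Vectors::metadata(meta)$condition <- condition
  meta
}

#' Ternary per-gene status calls on a meta-matrix
#'
#' Applies a two-sample Student t-test (CASE vs pooled CONTROL columns)
#' to each gene's meta-profile and assigns `+` (over-expressed,
#' p below threshold with positive difference), `-` (under-expressed) or
#' `0` (no change).  No multiple-testing correction is applied to the
#' status calls themselves (the raw p < 0.01 rule); a Benjamini-Hochberg
#' adjusted column is reported alongside for transparency only.
#'
#' @param meta A meta-matrix from [buildMetaMatrix()] (or any
#'   [MuscleExperiment-class]).
#' @param pThreshold Raw p-value threshold for a non-zero status.
#' @param condition Condition label stored in the result (defaults to
#'   the meta-matrix metadata).
#' @return `data.frame`: `gene_id`, `condition`, `status` (`+`/`-`/`0`),
#'   `p_value`, `p_bh`, `mean_difference`, `degenerate`.
#' @export
callStatus <- function(meta, pThreshold = 0.01, condition = NULL) {
  if (is.null(condition))
    condition <- S4Vectors::metadata(meta)$condition
  if (is.null(condition)) condition <- NA_character_
  tt <- studentT(meta)
  status <- ifelse(tt$p < pThreshold & !tt$degenerate,
                   ifelse(tt$log_ratio > 0, "+", "-"), "0")
  data.frame(gene_id = tt$gene_id, condition = condition,
             status = status, p_value = tt$p,
             p_bh = stats::p.adjust(tt$p, "BH"),
             mean_difference = tt$log_ratio,
             degenerate = tt$degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign genes to the nine status-pair meta-clusters
#'
#' Combines the DMD and AGE status calls of each gene into one cell of
#' the 3x3 grid (e.g. `DMD+AGE-`).  The cells partition the shared gene
#' universe: they are disjoint and their sizes sum to the universe size.
#'
#' @param dmdCalls,ageCalls Status tables from [callStatus()] over the
#'   same gene universe.
#' @return `data.frame`: `gene_id`, `status_dmd`, `status_age`,
#'   `meta_cluster`.  Attribute `"counts"` tabulates all nine cells.
#' @export
assignMetaClusters <- function(dmdCalls, ageCalls) {
  if (!setequal(dmdCalls$gene_id, ageCalls$gene_id) ||
      nrow(dmdCalls) != nrow(ageCalls))
    stop("status-call universes differ between conditions")
  ageCalls <- ageCalls[match(dmdCalls$gene_id, ageCalls$gene_id), ,
                       drop = FALSE]
  cell <- paste0("DMD", dmdCalls$status, "AGE", ageCalls$status)
  out <- data.frame(gene_id = dmdCalls$gene_id,
                    status_dmd = dmdCalls$status,
                    status_age = ageCalls$status,
                    meta_cluster = cell,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "counts") <- table(factor(cell, levels = metaClusterLabels()))
  out
}

#' Cross-validate in-lab DEG calls against the meta-analysis
#'
#' For each in-lab DEG and each condition in which it was called, the
#' verdict is `VALIDATED` when the in-lab direction matches a non-zero
#' meta status of the same sign, `DISCORDANT` when the signs oppose,
#' `UNCONFIRMED` when the meta status is `0`, and `UNVALIDATABLE` when
#' the gene is absent from the compendium universe.  `validated_any`
#' marks genes validated in at least one condition.
#'
#' @param partition Partition table from [partitionSets()] (columns
#'   `gene_id`, `dir_dmd`, `dir_age`).
#' @param dmdCalls,ageCalls Meta status tables from [callStatus()].
#' @return `data.frame`: `gene_id`, `dir_dmd`, `dir_age`, `status_dmd`,
#'   `status_age`, `verdict_dmd`, `verdict_age`, `validated_any`.
#' @export
crossValidate <- function(partition, dmdCalls, ageCalls) {
  verdictOne <- function(dir, status) {
    ifelse(is.na(dir), NA_character_,
    ifelse(is.na(status), "UNVALIDATABLE",
    ifelse(status == "0", "UNCONFIRMED",
    ifelse((dir == "up") == (status == "+"), "VALIDATED", "DISCORDANT"))))
  }
  sDmd <- dmdCalls$status[match(partition$gene_id, dmdCalls$gene_id)]
  sAge <- ageCalls$status[match(partition$gene_id, ageCalls$gene_id)]
  vDmd <- verdictOne(partition$dir_dmd, sDmd)
  vAge <- verdictOne(partition$dir_age, sAge)
  data.frame(gene_id = partition$gene_id,
             dir_dmd = partition$dir_dmd, dir_age = partition$dir_age,
             status_dmd = sDmd, status_age = sAge,
             verdict_dmd = vDmd, verdict_age = vAge,
             validated_any = (!is.na(vDmd) & vDmd == "VALIDATED") |
               (!is.na(vAge) & vAge == "VALIDATED"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-dataset concordance of an in-lab signature
#'
#' Complements [crossValidate()]: for each in-lab DEG and each compendium
#' dataset separately, reports whether the within-dataset mean
#' case-control difference agrees in sign with the in-lab direction.
#'
#' @param partition Partition table from [partitionSets()].
#' @param datasets List of gene-level [MuscleExperiment-class] datasets of
#'   one condition.
#' @param condition `"DMD"` or `"AGE"` (selects `dir_dmd` or `dir_age`).
#' @return `data.frame`: `gene_id`, `dataset_id`, `concordant` (logical,
#'   `NA` when the gene is absent from that dataset).
#' @export
perDatasetConcordance <- function(partition, datasets, condition = "DMD") {
  dir <- if (condition == "DMD") partition$dir_dmd else partition$dir_age
  keep <- !is.na(dir)
  genes <- partition$gene_id[keep]; dir <- dir[keep]
  do.call(rbind, lapply(names(datasets), function(nm) {
    d <- datasets[[nm]]
    tt <- studentT(d)
    lr <- tt$log_ratio[match(genes, tt$gene_id)]
    data.frame(gene_id = genes, dataset_id = nm,
               concordant = ifelse(is.na(lr), NA,
                                   (dir == "up") == (lr > 0)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Sex-bias screen on the control samples of a meta-matrix
#'
#' Applies the status-call strategy to sex instead of disease: a
#' two-sample t-test of male vs female expression among CONTROL samples
#' (cases can optionally be pooled in), at the same raw p-value
#' threshold.  Direction `M` means higher expression in male muscle.
#'
#' @param meta A [MuscleExperiment-class].
#' @param pThreshold Raw p-value threshold.
#' @param controlsOnly Restrict to CONTROL samples (default).
#' @return `data.frame`: `gene_id`, `sex_biased`, `direction`
#'   (`M`/`F`/`NA`), `p_value`, `mean_difference` (male - female).
#'   A single-sex compendium gives an empty result with a warning.
#' @export
detectSexBias <- function(meta, pThreshold = 0.01, controlsOnly = TRUE) {
  keep <- if (controlsOnly) sampleCondition(meta) == "CONTROL"
  else rep(TRUE, ncol(meta))
  sex <- sampleSex(meta)[keep]
  if (sum(sex == "M") < 2 || sum(sex == "F") < 2) {
    warning("need at least two samples of each sex; empty sex-bias result")
    return(data.frame(gene_id = character(), sex_biased = logical(),
                      direction = character(), p_value = numeric(),
                      mean_difference = numeric(),
                      stringsAsFactors = FALSE))
  }
  sub <- exprsMatrix(meta)[, keep, drop = FALSE]
  tt <- studentT(sub, grouping = sex == "M")
  biased <- tt$p < pThreshold & !tt$degenerate
  data.frame(gene_id = tt$gene_id, sex_biased = biased,
             direction = ifelse(biased,
                                ifelse(tt$log_ratio > 0, "M", "F"),
                                NA_character_),
             p_value = tt$p, mean_difference = tt$log_ratio,
             stringsAsFactors = FALSE, row.names = NULL)
}
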