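#' @import methods
#' @importFrom stats median
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

## required per-sample annotation columns, in canonical order
.ANNOT_COLS <- c("sample_id", "condition", "cohort", "sex",
                 "dataset_id", "subject_id", "array_id")

.CONDITIONS <- c("CASE", "CONTROL")
.COHORTS    <- c("DMD", "AGE", "NONE")
.SEXES      <- c("M", "F", "UNKNOWN")

## ternary per-gene expression status vs CONTROL
.STATUS_LEVELS <- c("+", "-", "0")

#' Labels of the 3x3 status-pair grid
#'
#' A gene's ternary status (+ over-expressed, - under-expressed, 0 unchanged)
#' in each of the two case conditions defines one of nine meta-cluster cells,
#' e.g. `"DMD+AGE-"` for genes up in dystrophic muscle and down with age.
#'
#' @return Character vector of the nine cell labels in row-major grid order.
#' @export
#' @examples
#' metaClusterLabels()
metaClusterLabels <- function() {
  as.vector(t(outer(.STATUS_LEVELS, .STATUS_LEVELS,
                    function(a, b) paste0("DMD", a, "AGE", b))))
}

#' Expression matrix with sample annotations
#'
#' `MuscleExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a fixed sample
#' annotation schema: every column (sample) carries a condition
#' (`CASE`/`CONTROL`), a cohort (`DMD`/`AGE`/`NONE`), a sex
#' (`M`/`F`/`UNKNOWN`), and dataset / subject / replicate-array identifiers.
#' Rows are probes or genes; probe-level objects carry a `gene_id` column in
#' `rowData` mapping each probe to its parent gene.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment-class].
#' @export
setClass("MuscleExperiment", contains = "SummarizedExperiment")

setValidity("MuscleExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  missing <- setdiff(.ANNOT_COLS, colnames(cd))
  if (length(missing))
    return(paste("missing annotation column(s):",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(cd$sample_id))
    return("duplicated sample_id in annotation")
  if (!all(cd$condition %in% .CONDITIONS))
    return("condition must be CASE or CONTROL")
  if (!all(cd$cohort %in% .COHORTS))
    return("cohort must be DMD, AGE or NONE")
  if (!all(cd$sex %in% .SEXES))
    return("sex must be M, F or UNKNOWN")
  if (is.null(rownames(object)))
    return("row identifiers (probe/gene ids) are required")
  if (anyDuplicated(rownames(object)))
    return(paste("duplicated row identifier:",
                 rownames(object)[duplicated(rownames(object))][1L]))
  TRUE
})

#' Construct a MuscleExperiment
#'
#' @param values Numeric matrix, rows = probes or genes, columns = samples.
#'   Row names are required and must be unique.
#' @param annotation `data.frame` with one row per sample and columns
#'   `sample_id`, `condition`, `cohort`, `sex`, `dataset_id`, `subject_id`,
#'   `array_id`.  Rows are matched to matrix columns by `sample_id`; the
#'   sample set must coincide exactly with the matrix columns.
#' @param geneIds Optional character vector mapping each row (probe) to its
#'   parent gene; stored in `rowData(x)$gene_id`.  Defaults to the row names
#'   (rows already at gene level).
#'
#' @return A [MuscleExperiment-class] object.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' ann <- data.frame(sample_id = colnames(m),
#'                   condition = c("CASE", "CASE", "CONTROL"),
#'                   cohort = c("DMD", "DMD", "NONE"),
#'                   sex = "M", dataset_id = "d1",
#'                   subject_id = colnames(m), array_id = colnames(m))
#' MuscleExperiment(m, ann)
MuscleExperiment <- function(values, annotation, geneIds = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("expression matrix must have sample ids as column names")
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  extra  <- setdiff(colnames(values), annotation$sample_id)
  orphan <- setdiff(annotation$sample_id, colnames(values))
  if (length(extra) || length(orphan))
    stop("annotation/column mismatch; unannotated column(s): [",
         paste(extra, collapse = ", "), "]; annotation row(s) without a ",
         "matrix column: [", paste(orphan, collapse = ", "), "]")
  annotation <- annotation[match(colnames(values), annotation$sample_id), ,
                           drop = FALSE]
  rownames(annotation) <- annotation$sample_id
  if (is.null(geneIds)) geneIds <- rownames(values)
  stopifnot(length(geneIds) == nrow(values))
  rd <- S4Vectors::DataFrame(gene_id = as.character(geneIds),
                             row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(annotation),
    rowData = rd)
  methods::new("MuscleExperiment", se)
}

#' @describeIn MuscleExperiment Expression matrix (identical to
#'   `assay(x, "exprs")`).
#' @param x A `MuscleExperiment`.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn MuscleExperiment CASE/CONTROL condition of each sample.
#' @export
sampleCondition <- function(x) SummarizedExperiment::colData(x)$condition

#' @describeIn MuscleExperiment Cohort (DMD/AGE/NONE) of each sample.
#' @export
sampleCohort <- function(x) SummarizedExperiment::colData(x)$cohort

#' @describeIn MuscleExperiment Sex (M/F/UNKNOWN) of each sample.
#' @export
sampleSex <- function(x) SummarizedExperiment::colData(x)$sex

#' @describeIn MuscleExperiment Source dataset identifier of each sample.
#' @export
datasetId <- function(x) SummarizedExperiment::colData(x)$dataset_id

#' @describeIn MuscleExperiment Subject identifier of each sample.
#' @export
subjectId <- function(x) SummarizedExperiment::colData(x)$subject_id

#' @describeIn MuscleExperiment Replicate-array identifier of each sample.
#' @export
arrayId <- function(x) SummarizedExperiment::colData(x)$array_id

#' @describeIn MuscleExperiment Parent gene of each row (equals row names
#'   for gene-level objects).
#' @export
geneIds <- function(x) SummarizedExperiment::rowData(x)$gene_id

#' Named gene-set collection
#'
#' Holds named sets of gene identifiers (e.g. GO-term members or the target
#' genes of a transcription-factor binding site) over an optional declared
#' gene universe.  Gene identifiers are opaque case-sensitive tokens.
#'
#' @slot sets Named list of character vectors; each vector is unique and
#'   non-empty, names are unique.
#' @slot universe Character vector of the declared gene universe (may be
#'   empty when no universe is declared).
#' @slot metadata List of provenance information (e.g. planted enrichment
#'   targets for synthetic collections).
#' @export
setClass("GeneSetList",
         representation(sets = "list", universe = "character",
                        metadata = "list"),
         prototype(sets = list(), universe = character(), metadata = list()))

setValidity("GeneSetList", function(object) {
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || any(names(s) == "") || anyDuplicated(names(s)))
      return("sets must have unique non-empty names")
    if (!all(vapply(s, is.character, logical(1))))
      return("each set must be a character vector of gene ids")
    if (any(vapply(s, length, integer(1)) == 0L))
      return("empty gene sets are not allowed")
    if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
      return("gene ids within a set must be unique")
  }
  TRUE
})

#' Construct a GeneSetList
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Optional character vector declaring the gene universe.
#' @param metadata Optional list of provenance information.
#' @return A [GeneSetList-class].
#' @export
GeneSetList <- function(sets = list(), universe = character(),
                        metadata = list()) {
  methods::new("GeneSetList", sets = lapply(sets, as.character),
               universe = as.character(universe), metadata = metadata)
}

#' @describeIn GeneSetList Number of sets.
#' @param x A `GeneSetList`.
#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))

#' @describeIn GeneSetList Set names.
#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))

#' @describeIn GeneSetList Extract one set by name or index.
#' @param i Set name or index.
#' @export
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])

#' @describeIn GeneSetList All sets as a plain named list.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetList Declared gene universe.
#' @export
setUniverse <- function(x) x@universe

setMethod("show", "GeneSetList", function(object) {
  cat("GeneSetList with", length(object@sets), "set(s)")
  if (length(object@universe))
    cat(" over a universe of", length(object@universe), "genes")
  cat("\n")
  if (length(object@sets)) {
    sz <- vapply(object@sets, length, integer(1))
    cat("  set sizes:", paste(range(sz), collapse = "-"), "\n")
    nshow <- min(5L, length(object@sets))
    cat("  ", paste(utils::head(names(object@sets), nshow), collapse = ", "),
        if (length(object@sets) > nshow) ", ..." else "", "\n", sep = "")
  }
})

#' Ground truth of a synthetic compendium
#'
#' Ledger of everything planted by [generateCompendium()]: per-gene status
#' pair, effect and sex-bias parameters, the probe-to-gene map, and the
#' generating configuration.  Used as the reference in recovery tests.
#'
#' @slot genes `data.frame` with one row per gene: `gene_id`, `status_dmd`,
#'   `status_age`, `status_pair`, `mu` (baseline log2 level), `sd` (residual
#'   standard deviation), `delta_dmd`, `delta_age` (planted mean shifts,
#'   log2 units), `sex_biased` (logical), `sex_direction` (`M`/`F`/`NA`),
#'   `sex_delta` (log2 shift applied to male samples).
#' @slot probes `data.frame` with `probe_id`, `gene_id`.
#' @slot config The [syntheticConfig()] list that generated the compendium.
#' @export
setClass("SyntheticTruth",
         representation(genes = "data.frame", probes = "data.frame",
                        config = "list"))

setValidity("SyntheticTruth", function(object) {
  need <- c("gene_id", "status_dmd", "status_age", "status_pair",
            "mu", "sd", "delta_dmd", "delta_age",
            "sex_biased", "sex_direction", "sex_delta")
  if (!all(need %in% colnames(object@genes)))
    return("truth gene table lacks required columns")
  if (anyDuplicated(object@probes$probe_id))
    return("probe ids must be unique")
  if (!all(object@probes$gene_id %in% object@genes$gene_id))
    return("every probe must map to exactly one known gene")
  TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  g <- object@genes
  cat("SyntheticTruth:", nrow(g), "genes,", nrow(object@probes), "probes\n")
  cat("  planted effect genes:",
      sum(g$status_dmd != "0" | g$status_age != "0"),
      "| sex-biased:", sum(g$sex_biased), "\n")
  tab <- table(factor(g$status_pair, levels = metaClusterLabels()))
  cat("  status-pair counts:\n")
  print(tab)
})

#' @describeIn SyntheticTruth Per-gene truth table.
#' @param x A `SyntheticTruth`.
#' @export
truthGenes <- function(x) x@genes

#' @describeIn SyntheticTruth Probe-to-gene map.
#' @export
truthProbes <- function(x) x@probes

#' Empirical-Bayes moderated-t fit
#'
#' @slot table Per-gene results: `gene_id`, `mean_case`, `mean_control`,
#'   `log_ratio`, `s2` (pooled residual variance), `s2_posterior`,
#'   `t_moderated`, `p_moderated`, `df_residual`, `df_total`, `degenerate`.
#' @slot d0 Prior degrees of freedom (may be `Inf`).
#' @slot s0sq Prior variance.
#' @export
setClass("EBayesFit",
         representation(table = "data.frame", d0 = "numeric",
                        s0sq = "numeric"))

setMethod("show", "EBayesFit", function(object) {
  cat("EBayesFit on", nrow(object@table), "genes\n")
  cat(sprintf("  prior df d0 = %s, prior variance s0^2 = %.6g\n",
              format(object@d0, digits = 4), object@s0sq))
  cat("  genes at p < 0.01:", sum(object@table$p_moderated < 0.01), "\n")
})

#' @describeIn EBayesFit Per-gene result table.
#' @param x An `EBayesFit`.
#' @export
ebayesTable <- function(x) x@table

#' Permutation relative-difference (SAM-style) fit
#'
#' @slot table Per-gene results: `gene_id`, `mean_case`, `mean_control`,
#'   `log_ratio`, `se` (pooled standard error), `d` (relative difference),
#'   `q` (permutation FDR), `degenerate`.
#' @slot s0 Fudge constant added to the gene-wise standard error.
#' @slot s0Percentile Percentile of the standard-error distribution at which
#'   `s0` was taken (`NA` when `s0` was supplied by the caller).
#' @slot nPerm Number of label permutations actually used.
#' @export
setClass("SamFit",
         representation(table = "data.frame", s0 = "numeric",
                        s0Percentile = "numeric", nPerm = "integer"))

setMethod("show", "SamFit", function(object) {
  cat("SamFit on", nrow(object@table), "genes\n")
  cat(sprintf("  fudge constant s0 = %.6g (percentile %s), %d permutations\n",
              object@s0,
              format(object@s0Percentile, digits = 3), object@nPerm))
  cat("  genes at q < 0.02:", sum(object@table$q < 0.02), "\n")
})

#' @describeIn SamFit Per-gene result table.
#' @param x A `SamFit`.
#' @export
samTable <- function(x) x@table
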