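## Tab-delimited interchange: expression matrices with annotation tables,
## GMT gene-set collections, and TreeView-compatible CDT/GTR output.
## Missing values: "NA" on write; "NA", "NaN" and "" accepted on read.
## Numeric cells are written with 12 significant digits so a write -> read
## -> write cycle is byte-stable.

.NA_TOKENS <- c("NA", "NaN", "")
.NUM_FMT <- "%.12g"

.fmtNum <- function(x) {
  out <- sprintf(.NUM_FMT, x)
  out[is.na(x)] <- "NA"
  out
}

#' Read a sample-annotation table
#'
#' @param path TSV file with header columns `sample_id`, `condition`,
#'   `cohort`, `sex`, `dataset_id`, `subject_id`, `array_id`.
#' @return `data.frame` with those columns, in file order.
#' @export
readSampleAnnotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, quote = "")
  missing <- setdiff(.ANNOT_COLS, colnames(ann))
  if (length(missing))
    stop("annotation table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample_id in annotation: ",
         ann$sample_id[duplicated(ann$sample_id)][1L])
  ann[, .ANNOT_COLS]
}

#' Write a sample-annotation table
#'
#' @param annotation `data.frame` with the canonical annotation columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeSampleAnnotation <- function(annotation, path) {
  utils::write.table(annotation[, .ANNOT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with its annotations
#'
#' The first column of the matrix file holds probe/gene identifiers, the
#' header row holds sample ids, and cells are numeric or a missing-value
#' token (`NA`, `NaN` or empty).  The column set must coincide exactly with
#' the `sample_id` set of the annotation table.
#'
#' @param path Expression-matrix TSV.
#' @param annotationPath Sample-annotation TSV (see
#'   [readSampleAnnotation()]).
#' @param geneIds Optional probe-to-gene vector passed on to
#'   [MuscleExperiment()].
#' @return A [MuscleExperiment-class].
#' @export
readExpressionTsv <- function(path, annotationPath, geneIds = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", row.names = NULL)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicated row identifier: ", ids[duplicated(ids)][1L])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals %in% .NA_TOKENS] <- NA_character_
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- !is.na(vals) & is.na(storage)
  if (any(bad))
    stop("non-numeric cell(s) in expression matrix, e.g. '",
         vals[which(bad)[1L]], "'")
  dimnames(storage) <- list(ids, colnames(vals))
  ann <- readSampleAnnotation(annotationPath)
  MuscleExperiment(storage, ann, geneIds = geneIds)
}

#' Write an expression matrix (and optionally its annotations)
#'
#' @param x A [MuscleExperiment-class] or a numeric matrix with dimnames.
#' @param path Output TSV path.
#' @param annotationPath Optional path; when given and `x` is a
#'   `MuscleExperiment`, the sample annotations are written there too.
#' @param idColumn Header of the identifier column (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(x, path, annotationPath = NULL,
                               idColumn = "gene_id") {
  m <- if (methods::is(x, "SummarizedExperiment")) exprsMatrix(x) else x
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(idColumn, colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  if (!is.null(annotationPath) && methods::is(x, "MuscleExperiment"))
    writeSampleAnnotation(
      as.data.frame(SummarizedExperiment::colData(x)), annotationPath)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' @param path TSV with header columns `probe_id`, `gene_id`.
#' @return `data.frame` with unique `probe_id` rows.
#' @export
readProbeMap <- function(path) {
  pm <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, quote = "")
  if (!all(c("probe_id", "gene_id") %in% colnames(pm)))
    stop("probe map needs columns probe_id and gene_id")
  if (anyDuplicated(pm$probe_id))
    stop("duplicated probe_id in map: ",
         pm$probe_id[duplicated(pm$probe_id)][1L])
  pm[, c("probe_id", "gene_id")]
}

#' Read a GMT gene-set file
#'
#' Each line is `set-name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are removed (first occurrence kept);
#' a line without at least one gene token is rejected.
#'
#' @param path GMT file path.
#' @return A [GeneSetList-class]; set descriptions are kept in
#'   `metadata$descriptions`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(f) < 3L || !length(genes))
      stop("malformed GMT line ", i, ": need a set name, a description ",
           "and at least one gene")
    if (f[1L] %in% names(sets))
      stop("duplicated set name '", f[1L], "' at GMT line ", i)
    sets[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  GeneSetList(sets, metadata = list(descriptions = desc))
}

#' Write a GMT gene-set file
#'
#' @param sets A [GeneSetList-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  desc <- sets@metadata$descriptions
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write clustered expression data as TreeView CDT/GTR files
#'
#' Produces the tab-delimited clustered-data-table (`.cdt`) and gene-tree
#' (`.gtr`) pair consumed by Java TreeView and compatible heatmap viewers.
#' Rows are emitted in gene-tree leaf order; node heights are stored as
#' Pearson similarity (1 - merge distance), the TreeView convention.
#'
#' @param x A [MuscleExperiment-class] or numeric matrix.
#' @param geneTree An `hclust` object whose labels are exactly the row
#'   names of `x` (e.g. from [hierarchicalCluster()]).
#' @param arrayOrder Optional character vector giving the output column
#'   order (default: current column order).
#' @param pathPrefix Output files are `<pathPrefix>.cdt` and
#'   `<pathPrefix>.gtr`.
#' @return Named character vector with the two paths, invisibly.
#' @export
writeCdtGtr <- function(x, geneTree, arrayOrder = NULL, pathPrefix) {
  m <- if (methods::is(x, "SummarizedExperiment")) exprsMatrix(x) else x
  if (!inherits(geneTree, "hclust"))
    stop("geneTree must be an hclust object")
  if (!setequal(geneTree$labels, rownames(m)) ||
      length(geneTree$labels) != nrow(m))
    stop("gene-tree leaves do not match matrix rows")
  if (is.null(arrayOrder)) arrayOrder <- colnames(m)
  if (!setequal(arrayOrder, colnames(m)))
    stop("arrayOrder does not match matrix columns")
  m <- m[, arrayOrder, drop = FALSE]

  nGenes <- nrow(m)
  gid <- paste0("GENE", seq_len(nGenes), "X")   # in original row order
  names(gid) <- rownames(m)

  ## GTR: one line per merge, heights as similarity = 1 - distance
  nid <- paste0("NODE", seq_len(nGenes - 1L), "X")
  ref <- function(j) if (j < 0) gid[[geneTree$labels[-j]]] else nid[j]
  gtr <- vapply(seq_len(nGenes - 1L), function(k) {
    a <- ref(geneTree$merge[k, 1L])
    b <- ref(geneTree$merge[k, 2L])
    paste(nid[k], a, b, .fmtNum(1 - geneTree$height[k]), sep = "\t")
  }, character(1))
  writeLines(gtr, paste0(pathPrefix, ".gtr"))

  leafOrder <- geneTree$labels[geneTree$order]
  header <- paste(c("GID", "UNIQID", "NAME", arrayOrder), collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "",
                     rep("1", length(arrayOrder))), collapse = "\t")
  rowsTxt <- vapply(leafOrder, function(g)
    paste(c(gid[g], g, g, .fmtNum(m[g, ])), collapse = "\t"), character(1))
  writeLines(c(header, eweight, rowsTxt), paste0(pathPrefix, ".cdt"))
  invisible(c(cdt = paste0(pathPrefix, ".cdt"),
              gtr = paste0(pathPrefix, ".gtr")))
}

#' Read back the numeric block of a CDT file
#'
#' Convenience reader used to verify CDT output; returns the expression
#' block with genes in file (leaf) order.
#'
#' @param path CDT file path.
#' @return Numeric matrix with gene ids as row names.
#' @export
readCdt <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           colClasses = "character")
  raw <- raw[raw$GID != "EWEIGHT" & raw$UNIQID != "", , drop = FALSE]
  dataCols <- setdiff(colnames(raw), c("GID", "UNIQID", "NAME"))
  m <- matrix(as.numeric(as.matrix(raw[, dataCols, drop = FALSE])),
              nrow = nrow(raw),
              dimnames = list(raw$UNIQID, dataCols))
  m
}
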