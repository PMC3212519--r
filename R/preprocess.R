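## Per-array normalisation, replicate consolidation and validity filtering.

#' Intensity-dependent LOWESS normalisation of a two-channel array
#'
#' Removes the intensity-dependent dye trend from the log-ratios of one
#' two-colour array: M is replaced by M - f(A), where f is a locally
#' weighted degree-1 regression of M on A (tricube weights, robustness
#' iterations), the standard MA-plot correction for two-colour data.
#' Invalid spots are left untouched and do not influence the fit.
#'
#' @param array `data.frame` with columns `probe_id`, `M` (log2 ratio),
#'   `A` (mean log2 intensity) and logical `flag` (`TRUE` = valid spot).
#' @param span Fraction of spots in each local window, in (0, 1].
#' @param iterations Robustness iterations of the local fit.
#' @return The input `data.frame` with normalised `M`; the fitted trend is
#'   attached as attribute `"trend"`.
#' @export
lowessNormalize <- function(array, span = 0.3, iterations = 3L) {
  stopifnot(all(c("probe_id", "M", "A", "flag") %in% colnames(array)),
            span > 0, span <= 1)
  valid <- array$flag & is.finite(array$M) & is.finite(array$A)
  if (sum(valid) < 20L)
    stop("need at least 20 valid spots for LOWESS normalisation (got ",
         sum(valid), ")")
  fit <- stats::lowess(array$A[valid], array$M[valid], f = span,
                       iter = iterations)
  trend <- stats::approx(fit$x, fit$y, xout = array$A[valid], rule = 2,
                         ties = mean)$y
  out <- array
  out$M[valid] <- array$M[valid] - trend
  full <- rep(NA_real_, nrow(array))
  full[valid] <- trend
  attr(out, "trend") <- full
  out
}

#' Consolidate replicate spots to one value per gene per array
#'
#' On each array, a gene's replicate spots are reduced to their median
#' (robust to single aberrant spots, which is why the median rather than
#' the mean is used); missing spots are ignored, and a gene with no valid
#' spot on an array becomes missing there.  The result is invariant to
#' the order of the replicate spots.
#'
#' @param x Probe/spot-level [MuscleExperiment-class].
#' @param probeMap Optional `data.frame` (`probe_id`, `gene_id`)
#'   overriding the object's `rowData(x)$gene_id` mapping.
#' @return Gene-level [MuscleExperiment-class] with genes in first-seen
#'   order.
#' @export
consolidateReplicates <- function(x, probeMap = NULL) {
  m <- exprsMatrix(x)
  gene <- if (is.null(probeMap)) geneIds(x)
  else {
    hit <- match(rownames(m), probeMap$probe_id)
    if (anyNA(hit))
      stop("probe(s) absent from probe map: ",
           rownames(m)[is.na(hit)][1L])
    probeMap$gene_id[hit]
  }
  idx <- split(seq_len(nrow(m)), factor(gene, levels = unique(gene)))
  med <- matrix(NA_real_, nrow = length(idx), ncol = ncol(m),
                dimnames = list(names(idx), colnames(m)))
  for (j in seq_along(idx)) {
    sub <- m[idx[[j]], , drop = FALSE]
    med[j, ] <- apply(sub, 2L, function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  }
  MuscleExperiment(med,
                   as.data.frame(SummarizedExperiment::colData(x)))
}

#' Keep only genes with valid values in every sample
#'
#' Complete-case validity filter: genes carrying a missing value in any
#' sample are dropped.  Kept and dropped counts are reported via
#' `message()` and stored in `metadata(x)$filter_report`; the operation is
#' idempotent.
#'
#' @param x Gene-level [MuscleExperiment-class].
#' @return Filtered [MuscleExperiment-class].
#' @export
filterValid <- function(x) {
  m <- exprsMatrix(x)
  keep <- stats::complete.cases(m)
  if (!any(keep))
    warning("no gene has complete valid values; result is empty")
  out <- x[keep, ]
  report <- list(kept = sum(keep), dropped = sum(!keep),
                 dropped_genes = rownames(m)[!keep])
  S4Vectors::metadata(out)$filter_report <- report
  message("filterValid: kept ", report$kept, " gene(s), dropped ",
          report$dropped)
  out
}

#' Log2 transformation and per-gene median centering
#'
#' Reduces intensity- or ratio-scale data to row-centered log2 values so
#' relative variation, not absolute level, drives all cross-dataset
#' comparisons: values are log2-transformed (skipped when already on log
#' scale) and each gene's median is subtracted, leaving every row with
#' median exactly zero.
#'
#' @param x A [MuscleExperiment-class].
#' @param alreadyLog `TRUE` when values are already log2 (the default for
#'   ratio data); `FALSE` for positive intensity-scale data.
#' @return Centered [MuscleExperiment-class].
#' @export
log2MedianCenter <- function(x, alreadyLog = TRUE) {
  m <- exprsMatrix(x)
  if (!alreadyLog) {
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("nonpositive intensity for gene ", rownames(m)[bad[1L, 1L]],
           "; cannot log-transform")
    m <- log2(m)
  }
  ctr <- apply(m, 1L, stats::median, na.rm = TRUE)
  m <- m - ctr
  SummarizedExperiment::assay(x, "exprs") <- m
  x
}

#' Collapse replicate arrays to per-subject means
#'
#' Sensitivity-analysis helper: replicate hybridisations of one subject
#' (same `subject_id`) are averaged into a single column.  The default
#' pipeline keeps replicate arrays as separate columns through the
#' differential tests.
#'
#' @param x A [MuscleExperiment-class].
#' @return [MuscleExperiment-class] with one column per subject.
#' @export
collapseToSubjects <- function(x) {
  m <- exprsMatrix(x)
  ann <- as.data.frame(SummarizedExperiment::colData(x))
  idx <- split(seq_len(ncol(m)),
               factor(ann$subject_id, levels = unique(ann$subject_id)))
  mm <- vapply(idx, function(i) rowMeans(m[, i, drop = FALSE], na.rm = TRUE),
               numeric(nrow(m)))
  firsts <- vapply(idx, `[`, integer(1), 1L)
  ann2 <- ann[firsts, , drop = FALSE]
  ann2$sample_id <- ann2$subject_id
  ann2$array_id <- ann2$subject_id
  colnames(mm) <- ann2$sample_id
  MuscleExperiment(mm, ann2, geneIds = geneIds(x))
}
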