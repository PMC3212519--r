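## Display computations: average-linkage Pearson clustering and paired
## concordance summaries.

#' Average-linkage hierarchical clustering with Pearson distance
#'
#' Agglomerative clustering of genes or samples with distance
#' `1 - r` (centered Pearson correlation) and average linkage — the
#' Cluster/TreeView convention for expression heatmaps.  Items with zero
#' variance (for which the correlation is undefined) are dropped and
#' reported; duplicate items merge first at height 0.
#'
#' @param x A [MuscleExperiment-class] or numeric matrix.
#' @param axis `"genes"` (cluster rows) or `"samples"` (cluster columns).
#' @return An `hclust` object whose heights are `1 - r` at each merge;
#'   attribute `"dropped"` lists constant items removed beforehand.
#' @export
hierarchicalCluster <- function(x, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  m <- if (methods::is(x, "SummarizedExperiment")) exprsMatrix(x) else x
  if (axis == "samples") m <- t(m)
  keep <- apply(m, 1L, function(v) stats::sd(v, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  dropped <- rownames(m)[!keep]
  if (length(dropped))
    message("hierarchicalCluster: dropping ", length(dropped),
            " constant item(s)")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2L)
    stop("need at least 2 non-constant items to cluster")
  d <- stats::as.dist(1 - stats::cor(t(m), use = "pairwise.complete.obs"))
  hc <- stats::hclust(d, method = "average")
  attr(hc, "dropped") <- dropped
  hc
}

#' Paired concordance between two measurement vectors
#'
#' Standard Pearson correlation of paired measurements (e.g. microarray
#' log-ratios vs quantitative RT-PCR log-ratios for a panel of genes),
#' with the paired table returned for scatter plotting.
#'
#' @param x,y Numeric vectors of equal length >= 3; all values finite.
#' @param labels Optional point labels (e.g. gene ids).
#' @return List with `r` (Pearson correlation; `NA` with a warning when
#'   either vector has zero variance) and `table`
#'   (`data.frame` of `label`, `x`, `y`).
#' @export
concordance <- function(x, y, labels = NULL) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need paired vectors of equal length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("concordance requires finite values")
  if (is.null(labels)) labels <- as.character(seq_along(x))
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    NA_real_
  } else stats::cor(x, y)
  list(r = r,
       table = data.frame(label = labels, x = x, y = y,
                          stringsAsFactors = FALSE))
}
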