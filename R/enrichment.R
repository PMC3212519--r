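## Direction-aware Fisher's-exact bias testing of gene sets within
## meta-clusters, and candidate transcription-factor selection.

#' Hypergeometric bias test of one 2x2 table
#'
#' Both one-sided tails of the Fisher's exact test for an overlap of `k`
#' genes between a set of size `K` and a cluster of size `n` in a
#' universe of size `N`: `p_over = P(X >= k)` (over-representation) and
#' `p_under = P(X <= k)` (under-representation) for
#' `X ~ hypergeometric(N, K, n)`.  Both tails include `P(X = k)`, so
#' `p_over + p_under >= 1` always.  The odds ratio comes from the 2x2
#' table with the Haldane 0.5 correction when any cell is zero.
#'
#' @param k Overlap count.
#' @param K Set size within the universe.
#' @param n Cluster size.
#' @param N Universe size.
#' @return List with `p_over`, `p_under`, `odds_ratio`.
#' @export
fisherBias <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N ||
      k > min(K, n) || k < max(0, K + n - N))
    stop("inconsistent 2x2 counts (k=", k, ", K=", K,
         ", n=", n, ", N=", N, ")")
  pOver <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pUnder <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  a <- k; b <- K - k; cc <- n - k; d <- N - K - n + k
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  list(p_over = pOver, p_under = pUnder, odds_ratio = (a * d) / (b * cc))
}

#' Gene-set bias across meta-clusters
#'
#' Tests every (meta-cluster, gene set) pair for over- or
#' under-representation against the expressed-gene reference population:
#' the universe is the filtered expressed-gene list, never the whole
#' annotation universe, and sets are intersected with it before testing.
#' Verdicts use the raw two-tail rule at `alpha` (no multiple-testing
#' correction, matching the 5%-risk convention); a Benjamini-Hochberg
#' column is reported alongside for transparency.  The `score` column is
#' the signed enrichment score `-log10(min tail p)`, positive for
#' enrichment and negative for depletion — the quantity heatmap displays
#' encode as colour intensity.
#'
#' @param clusters Meta-cluster table from [assignMetaClusters()] (or any
#'   `data.frame` with `gene_id` and `meta_cluster`).
#' @param sets A [GeneSetList-class].
#' @param universe Character vector of expressed gene ids (defaults to
#'   the cluster table's genes).
#' @param alpha Significance level for the verdicts.
#' @return `data.frame` with one row per (cluster, set) pair: `set_name`,
#'   `cluster`, `k`, `K`, `n`, `N`, `p_over`, `p_under`, `odds_ratio`,
#'   `score`, `p_bh` (BH on the min tail), `verdict`
#'   (`ENRICHED`/`DEPLETED`/`NONE`).  Sets disjoint from the universe are
#'   skipped and listed in attribute `"skipped_sets"`.
#' @export
enrichClusters <- function(clusters, sets, universe = NULL, alpha = 0.05) {
  if (is.null(universe)) universe <- unique(clusters$gene_id)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  N <- length(universe)
  clusters <- clusters[clusters$gene_id %in% universe, , drop = FALSE]
  members <- split(clusters$gene_id, clusters$meta_cluster)

  trimmed <- lapply(geneSets(sets), intersect, y = universe)
  skipped <- names(trimmed)[vapply(trimmed, length, integer(1)) == 0L]
  trimmed <- trimmed[setdiff(names(trimmed), skipped)]
  if (length(skipped))
    message("enrichClusters: skipping ", length(skipped),
            " set(s) disjoint from the universe")

  rows <- list()
  for (cl in names(members)) {
    n <- length(members[[cl]])
    for (nm in names(trimmed)) {
      K <- length(trimmed[[nm]])
      k <- length(intersect(trimmed[[nm]], members[[cl]]))
      fb <- fisherBias(k, K, n, N)
      rows[[length(rows) + 1L]] <- data.frame(
        set_name = nm, cluster = cl, k = k, K = K, n = n, N = N,
        p_over = fb$p_over, p_under = fb$p_under,
        odds_ratio = fb$odds_ratio,
        score = if (fb$p_over <= fb$p_under)
          -log10(fb$p_over) else log10(fb$p_under),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bh <- stats::p.adjust(pmin(out$p_over, out$p_under), "BH")
  out$verdict <- ifelse(out$p_over < alpha, "ENRICHED",
                        ifelse(out$p_under < alpha, "DEPLETED", "NONE"))
  attr(out, "skipped_sets") <- skipped
  out
}

#' Signed enrichment-score matrix for heatmap display
#'
#' @param enrichments Result of [enrichClusters()].
#' @return Numeric matrix, clusters x sets, of signed `-log10 p` scores.
#' @export
enrichmentScoreMatrix <- function(enrichments) {
  cl <- sort(unique(enrichments$cluster))
  st <- sort(unique(enrichments$set_name))
  m <- matrix(0, length(cl), length(st), dimnames = list(cl, st))
  m[cbind(match(enrichments$cluster, cl),
          match(enrichments$set_name, st))] <- enrichments$score
  m
}

#' Select candidate transcription factors
#'
#' A transcription factor is a candidate regulator of the observed
#' meta-signatures when (1) the set of genes carrying its binding site is
#' significantly enriched in at least one meta-cluster and (2) the TF
#' gene itself is differentially expressed (non-zero status) in at least
#' one condition.  Binding-site sets without a mapped TF gene in the
#' status universe are reported, not tested.
#'
#' @param enrichments Result of [enrichClusters()] on the TFBS target
#'   sets.
#' @param tfbsToTf `data.frame` mapping `set_name` to `tf_gene_id`.
#' @param dmdCalls,ageCalls Status tables from [callStatus()].
#' @return `data.frame` with one row per selected TF: `tf_gene_id`,
#'   `enriched_clusters` (comma-separated), `status_dmd`, `status_age`,
#'   `conditions` (which conditions are non-zero).  Attribute
#'   `"unmapped_sets"` lists binding-site sets with no usable TF gene.
#' @export
selectCandidateTfs <- function(enrichments, tfbsToTf, dmdCalls, ageCalls) {
  enr <- enrichments[enrichments$verdict == "ENRICHED", , drop = FALSE]
  tf <- tfbsToTf$tf_gene_id[match(enr$set_name, tfbsToTf$set_name)]
  known <- tf %in% dmdCalls$gene_id | tf %in% ageCalls$gene_id
  unmapped <- unique(enr$set_name[is.na(tf) | !known])
  enr <- enr[!is.na(tf) & known, , drop = FALSE]
  tf <- tf[!is.na(tf) & known]

  out <- list()
  for (g in unique(tf)) {
    sDmd <- dmdCalls$status[match(g, dmdCalls$gene_id)]
    sAge <- ageCalls$status[match(g, ageCalls$gene_id)]
    conds <- c(if (!is.na(sDmd) && sDmd != "0") "DMD",
               if (!is.na(sAge) && sAge != "0") "AGE")
    if (!length(conds)) next
    out[[g]] <- data.frame(
      tf_gene_id = g,
      enriched_clusters = paste(sort(unique(enr$cluster[tf == g])),
                                collapse = ","),
      status_dmd = ifelse(is.na(sDmd), "0", sDmd),
      status_age = ifelse(is.na(sAge), "0", sAge),
      conditions = paste(conds, collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(tf_gene_id = character(),
                  enriched_clusters = character(),
                  status_dmd = character(), status_age = character(),
                  conditions = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "unmapped_sets") <- unmapped
  res
}
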