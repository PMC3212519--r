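## Dual-statistic differential-expression calling:
##   * pooled-variance Student t,
##   * SAM-style relative difference d with fudge constant s0 and
##     permutation-estimated FDR,
##   * empirical-Bayes moderated t with (d0, s0^2) fitted by moment
##     matching on log sample variances,
## plus the intersection rule (FDR < 0.02 AND moderated p < 0.01) and the
## partition of the DMD/AGE call lists into the seven overlap classes.

.resolveGrouping <- function(x, grouping = NULL) {
  if (is.null(grouping)) {
    if (!methods::is(x, "MuscleExperiment"))
      stop("grouping is required when x is a plain matrix")
    grouping <- sampleCondition(x)
  }
  if (is.logical(grouping)) return(grouping)
  if (!all(grouping %in% c("CASE", "CONTROL")))
    stop("grouping must be CASE/CONTROL labels or a logical vector")
  grouping == "CASE"
}

## NA-aware per-gene two-group summary statistics
.groupStats <- function(m, isCase) {
  stopifnot(ncol(m) == length(isCase))
  ok <- !is.na(m)
  m0 <- m; m0[!ok] <- 0
  c1 <- as.numeric(isCase); c2 <- 1 - c1
  n1 <- as.vector(ok %*% c1); n2 <- as.vector(ok %*% c2)
  s1 <- as.vector(m0 %*% c1); s2c <- as.vector(m0 %*% c2)
  m1 <- s1 / n1; m2 <- s2c / n2
  q1 <- as.vector((m0 * m0) %*% c1); q2 <- as.vector((m0 * m0) %*% c2)
  ss1 <- pmax(q1 - n1 * m1^2, 0); ss2 <- pmax(q2 - n2 * m2^2, 0)
  df <- n1 + n2 - 2
  sp2 <- ifelse(df > 0, (ss1 + ss2) / df, NA_real_)
  list(n1 = n1, n2 = n2, mean_case = m1, mean_control = m2,
       diff = m1 - m2, sp2 = sp2, df = df,
       se = sqrt(sp2 * (1 / n1 + 1 / n2)))
}

#' Per-gene two-sample pooled-variance Student t-test
#'
#' @param x [MuscleExperiment-class] or numeric matrix (genes x samples).
#' @param grouping `CASE`/`CONTROL` labels or logical (`TRUE` = CASE);
#'   defaults to the object's sample conditions.
#' @return `data.frame` with `gene_id`, `mean_case`, `mean_control`,
#'   `log_ratio` (case - control), `t`, `p` (two-sided, `n1+n2-2` df),
#'   `df`, `degenerate`.  Zero pooled variance gives `t = 0`, `p = 1` and
#'   a degenerate flag.
#' @export
studentT <- function(x, grouping = NULL) {
  isCase <- .resolveGrouping(x, grouping)
  m <- if (methods::is(x, "SummarizedExperiment")) exprsMatrix(x) else x
  if (sum(isCase) < 2 || sum(!isCase) < 2)
    stop("need at least 2 samples per group")
  g <- .groupStats(m, isCase)
  degen <- !is.na(g$sp2) & g$sp2 == 0
  t <- g$diff / g$se
  t[degen] <- 0
  p <- 2 * stats::pt(-abs(t), df = g$df)
  p[degen] <- 1
  data.frame(gene_id = rownames(m),
             mean_case = g$mean_case, mean_control = g$mean_control,
             log_ratio = g$diff, t = t, p = p, df = g$df,
             degenerate = degen, stringsAsFactors = FALSE,
             row.names = NULL)
}

## Fudge-constant selection: s0 is the percentile of the gene-wise
## standard errors that minimises the coefficient of variation of the
## median absolute d across standard-error quantile bins.
.chooseS0 <- function(r, se, nBins = 100L,
                      alphas = seq(0, 1, by = 0.05)) {
  qs <- stats::quantile(se, alphas, names = FALSE)
  breaks <- unique(stats::quantile(
    se, seq(0, 1, length.out = nBins + 1L), names = FALSE))
  if (length(breaks) < 3L)  # (near-)constant standard errors
    return(list(s0 = stats::median(se), percentile = 0.5))
  bin <- cut(se, breaks, include.lowest = TRUE)
  cv <- vapply(qs, function(s0a) {
    d <- r / (se + s0a)
    v <- tapply(abs(d), bin, stats::mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  best <- which.min(cv)
  list(s0 = qs[best], percentile = alphas[best])
}

## matrix of case-indicator columns for the permutation null;
## "balanced" keeps only relabelings drawing the expected number of
## original CASE samples into the permuted CASE group
.permutationIndicators <- function(isCase, nPerm, balanced = TRUE) {
  n <- length(isCase); n1 <- sum(isCase)
  nDistinct <- choose(n, n1)
  balTarget <- round(n1 * n1 / n)
  if (nDistinct <= nPerm * 5 && n <= 25) {
    sets <- utils::combn(n, n1)
    ind <- matrix(0, n, ncol(sets))
    ind[cbind(as.vector(sets),
              rep(seq_len(ncol(sets)), each = n1))] <- 1
    if (balanced) {
      keep <- as.vector(crossprod(ind, as.numeric(isCase))) == balTarget
      if (sum(keep) >= 10L) ind <- ind[, keep, drop = FALSE]
    }
    if (ncol(ind) > nPerm)
      ind <- ind[, sample.int(ncol(ind), nPerm), drop = FALSE]
    else if (ncol(ind) < nPerm)
      warning("only ", ncol(ind), " distinct permutations available; ",
              "using all of them")
    return(ind)
  }
  ind <- matrix(0, n, nPerm)
  for (b in seq_len(nPerm)) {
    repeat {
      cases <- sample.int(n, n1)
      if (!balanced ||
          sum(isCase[cases]) == balTarget) break
    }
    ind[cases, b] <- 1
  }
  ind
}

#' SAM-style relative-difference analysis with permutation FDR
#'
#' Computes, per gene, the relative difference
#' `d = (mean_case - mean_control) / (se + s0)`, where `se` is the pooled
#' two-sample standard error and the fudge constant `s0` regularises
#' low-variance genes (chosen automatically as the standard-error
#' percentile minimising the coefficient of variation of the median
#' absolute `d` across standard-error bins, unless supplied).  The null
#' distribution comes from balanced relabelings of the samples (all
#' distinct relabelings when few enough exist); a gene's `q` is the
#' estimated false discovery rate at the |d| threshold that first calls
#' it: the median, across permutations, of the number of permuted |d*|
#' exceeding the threshold, divided by the observed number of calls,
#' taken as a running minimum over more lenient thresholds and capped
#' at 1.
#'
#' @inheritParams studentT
#' @param s0 Fudge constant; `NULL` (default) for automatic selection.
#' @param nPerm Requested number of permutations.
#' @param seed Integer seed for the permutation draws.
#' @param balanced Keep only relabelings balanced across the original
#'   groups.
#' @return A [SamFit-class].
#' @export
samAnalyze <- function(x, grouping = NULL, s0 = NULL, nPerm = 1000L,
                       seed = 1L, balanced = TRUE) {
  isCase <- .resolveGrouping(x, grouping)
  m <- if (methods::is(x, "SummarizedExperiment")) exprsMatrix(x) else x
  if (sum(isCase) < 2 || sum(!isCase) < 2)
    stop("need at least 2 samples per group")
  if (anyNA(m))
    stop("samAnalyze requires a complete matrix; run filterValid() first")
  g <- .groupStats(m, isCase)
  degen <- g$se == 0
  s0pct <- NA_real_
  if (is.null(s0)) {
    ch <- .chooseS0(g$diff, g$se)
    s0 <- ch$s0; s0pct <- ch$percentile
  }
  denom <- g$se + s0
  d <- ifelse(denom > 0, g$diff / denom, 0)

  set.seed(seed)
  ind <- .permutationIndicators(isCase, nPerm, balanced)
  B <- ncol(ind)
  n1p <- colSums(ind); n2p <- length(isCase) - n1p
  S1 <- m %*% ind                       # genes x perms sums, CASE side
  Stot <- rowSums(m)
  M1 <- sweep(S1, 2L, n1p, "/")
  M2 <- sweep(Stot - S1, 2L, n2p, "/")
  Q1 <- (m * m) %*% ind
  Qtot <- rowSums(m * m)
  SS1 <- pmax(Q1 - sweep(M1^2, 2L, n1p, "*"), 0)
  SS2 <- pmax((Qtot - Q1) - sweep(M2^2, 2L, n2p, "*"), 0)
  dfp <- length(isCase) - 2
  SEp <- sqrt(sweep(SS1 + SS2, 2L, (1 / n1p + 1 / n2p) / dfp, "*"))
  Dp <- abs((M1 - M2) / (SEp + s0))
  Dp[!is.finite(Dp)] <- 0

  ## median permutation exceedance count at each observed |d| threshold
  absd <- abs(d)
  ord <- order(absd, decreasing = TRUE)
  thr <- absd[ord]
  counts <- matrix(0, length(thr), B)
  for (b in seq_len(B)) {
    sb <- sort(Dp[, b])
    counts[, b] <- length(sb) - findInterval(thr, sb, left.open = TRUE)
  }
  medFalse <- apply(counts, 1L, stats::median)
  fdr <- medFalse / seq_along(thr)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  qOut <- numeric(length(d))
  qOut[ord] <- q
  qOut[degen] <- 1

  tab <- data.frame(gene_id = rownames(m),
                    mean_case = g$mean_case, mean_control = g$mean_control,
                    log_ratio = g$diff, se = g$se, d = d, q = qOut,
                    degenerate = degen, stringsAsFactors = FALSE,
                    row.names = NULL)
  methods::new("SamFit", table = tab, s0 = unname(s0),
               s0Percentile = s0pct, nPerm = B)
}

## Newton inversion of the trigamma function (vectorised)
.trigammaInverse <- function(y) {
  out <- y
  lo <- y < 1e-6; hi <- y > 1e7
  out[lo] <- 1 / y[lo]
  out[hi] <- 1 / sqrt(y[hi])
  mid <- which(!lo & !hi)
  if (length(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(abs(dif) / x) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderated t-statistic
#'
#' Fits the per-gene CASE - CONTROL contrast and shrinks the gene-wise
#' residual variances toward a prior: assuming
#' `s_g^2 ~ s0^2 * chi^2_{d_g} / d_g` scaled by a gene variance with an
#' inverse-chi-square prior (`d0`, `s0^2`), the hyperparameters are
#' estimated by moment matching of `log s_g^2` using digamma/trigamma
#' identities, and the posterior variance
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` replaces `s_g^2` in the
#' t-statistic, which then has `d0 + d_g` degrees of freedom.  When all
#' sample variances are equal the prior degrees of freedom are infinite
#' and normal-reference p-values are used.
#'
#' @inheritParams studentT
#' @param priorDf Optional fixed prior degrees of freedom (`0` recovers
#'   the ordinary t-test exactly; `NULL` estimates it from the data).
#' @return An [EBayesFit-class].
#' @export
eBayesModeratedT <- function(x, grouping = NULL, priorDf = NULL) {
  isCase <- .resolveGrouping(x, grouping)
  m <- if (methods::is(x, "SummarizedExperiment")) exprsMatrix(x) else x
  if (sum(isCase) < 2 || sum(!isCase) < 2)
    stop("need at least 2 samples per group")
  g <- .groupStats(m, isCase)
  s2 <- g$sp2
  dg <- g$df
  ok <- is.finite(s2) & s2 > 0 & dg > 0

  if (!is.null(priorDf)) {
    d0 <- priorDf
    s0sq <- if (any(ok)) exp(mean(log(s2[ok]))) else 1
  } else {
    if (!any(ok)) stop("no gene with positive residual variance")
    z <- log(s2[ok])
    e <- z - digamma(dg[ok] / 2) + log(dg[ok] / 2)
    emean <- mean(e)
    n <- length(e)
    evar <- sum((e - emean)^2) / (n - 1)
    rhs <- evar - mean(trigamma(dg[ok] / 2))
    if (is.finite(rhs) && rhs > 0) {
      d0 <- 2 * .trigammaInverse(rhs)
      s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0sq <- exp(emean)
    }
  }

  if (is.infinite(d0)) {
    st2 <- rep(s0sq, length(s2))
  } else if (d0 == 0) {
    st2 <- s2
  } else {
    st2 <- (d0 * s0sq + dg * s2) / (d0 + dg)
  }
  c2 <- (1 / g$n1 + 1 / g$n2)
  se <- sqrt(st2 * c2)
  degen <- se == 0
  t <- ifelse(degen, 0, g$diff / se)
  dfTotal <- d0 + dg
  p <- 2 * stats::pt(-abs(t), df = dfTotal)
  p[degen] <- 1

  tab <- data.frame(gene_id = rownames(m),
                    mean_case = g$mean_case, mean_control = g$mean_control,
                    log_ratio = g$diff, s2 = s2, s2_posterior = st2,
                    t_moderated = t, p_moderated = p,
                    df_residual = dg, df_total = dfTotal,
                    degenerate = degen, stringsAsFactors = FALSE,
                    row.names = NULL)
  methods::new("EBayesFit", table = tab, d0 = unname(d0),
               s0sq = unname(s0sq))
}

#' Intersect the two differential-expression calls
#'
#' A gene enters the final DEG list iff its permutation FDR is below
#' `qMax` AND its moderated-t p-value is below `pMax` (the two-method
#' intersection rule, FDR < 0.02 and p < 0.01 by default).  As an added
#' safeguard the two statistics must agree in sign; conflicting genes are
#' excluded and reported (attribute `"sign_conflicts"`), and the check
#' can be disabled.
#'
#' @param sam A [SamFit-class] (or its table).
#' @param ebayes An [EBayesFit-class] (or its table).
#' @param qMax FDR threshold applied to the SAM-style statistic.
#' @param pMax p-value threshold applied to the moderated t.
#' @param requireSignAgreement Exclude genes whose two statistics
#'   disagree in sign.
#' @return `data.frame` of called genes: `gene_id`,
#'   `direction` (`up`/`down`), `log_ratio`, `q_sam`, `p_moderated`.
#'   Attribute `"n_tested"` holds the universe size.
#' @export
intersectDegs <- function(sam, ebayes, qMax = 0.02, pMax = 0.01,
                          requireSignAgreement = TRUE) {
  st <- if (methods::is(sam, "SamFit")) sam@table else sam
  et <- if (methods::is(ebayes, "EBayesFit")) ebayes@table else ebayes
  if (!identical(st$gene_id, et$gene_id)) {
    if (!setequal(st$gene_id, et$gene_id))
      stop("the two statistics were computed on different gene universes")
    et <- et[match(st$gene_id, et$gene_id), , drop = FALSE]
  }
  called <- st$q < qMax & et$p_moderated < pMax &
    !st$degenerate & !et$degenerate
  conflict <- called & sign(st$d) != sign(et$t_moderated)
  if (requireSignAgreement && any(conflict)) {
    message("intersectDegs: excluding ", sum(conflict),
            " gene(s) with conflicting statistic signs")
    called <- called & !conflict
  }
  out <- data.frame(gene_id = st$gene_id[called],
                    direction = ifelse(st$log_ratio[called] > 0,
                                       "up", "down"),
                    log_ratio = st$log_ratio[called],
                    q_sam = st$q[called],
                    p_moderated = et$p_moderated[called],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_tested") <- nrow(st)
  attr(out, "sign_conflicts") <-
    if (requireSignAgreement) st$gene_id[conflict] else character()
  out
}

.PARTITION_CLASSES <- c("DMD_only_up", "DMD_only_down",
                        "AGE_only_up", "AGE_only_down",
                        "shared_consistent_up", "shared_consistent_down",
                        "shared_inconsistent")

#' Partition DMD and AGE DEG lists into overlap classes
#'
#' Splits the union of the two condition-wise DEG lists into
#' condition-specific up/down classes, shared consistently deregulated
#' classes, and a shared class deregulated in the opposite sense — the
#' three-set structure (DMD set, AGE set, common set) used to summarise
#' the in-lab calls.
#'
#' @param degDmd,degAge `data.frame`s from [intersectDegs()] (columns
#'   `gene_id`, `direction`).
#' @return `data.frame` over the union of called genes: `gene_id`,
#'   `dir_dmd`, `dir_age` (`up`/`down`/`NA`) and `class` (one of the
#'   seven partition labels).  Attribute `"counts"` holds the per-class
#'   table; the classes are exhaustive and disjoint, so
#'   `|DMD calls| = DMD_only + shared` and likewise for AGE.
#' @export
partitionSets <- function(degDmd, degAge) {
  genes <- union(degDmd$gene_id, degAge$gene_id)
  dDmd <- degDmd$direction[match(genes, degDmd$gene_id)]
  dAge <- degAge$direction[match(genes, degAge$gene_id)]
  cls <- character(length(genes))
  inD <- !is.na(dDmd); inA <- !is.na(dAge)
  cls[inD & !inA] <- paste0("DMD_only_", dDmd[inD & !inA])
  cls[!inD & inA] <- paste0("AGE_only_", dAge[!inD & inA])
  both <- inD & inA
  cls[both & dDmd == dAge] <-
    paste0("shared_consistent_", dDmd[both & dDmd == dAge])
  cls[both & dDmd != dAge] <- "shared_inconsistent"
  out <- data.frame(gene_id = genes, dir_dmd = dDmd, dir_age = dAge,
                    class = cls, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "counts") <- table(factor(cls, levels = .PARTITION_CLASSES))
  out
}
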