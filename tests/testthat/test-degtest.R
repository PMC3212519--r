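test_that("pooled t matches the closed-form oracle and flags degeneracy", {
  ids <- paste0("s", 1:6)
  ann <- makeAnnotation(ids, 3)
  m <- rbind(g1 = c(4, 5, 6, 1, 2, 3),    # hand-derivable case
             g2 = c(1, 2, 3, 1, 2, 3),    # identical groups
             g3 = c(2, 2, 2, 2, 2, 2))    # zero variance everywhere
  colnames(m) <- ids
  tt <- studentT(MuscleExperiment(m, ann))

  ## hand computation: diff = 3, pooled var = (2+2)/4 = 1,
  ## se = sqrt(1 * (1/3 + 1/3)), t = 3/sqrt(2/3) = 3*sqrt(3/2), df = 4
  expect_equal(tt$t[1], 3 * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(tt$p[1], 2 * pt(-3 * sqrt(3 / 2), df = 4),
               tolerance = 1e-12)
  expect_identical(tt$df[1], 4)

  expect_identical(tt$t[2], 0)
  expect_identical(tt$p[2], 1)
  expect_false(tt$degenerate[2])
  expect_true(tt$degenerate[3])
  expect_identical(tt$p[3], 1)

  ## random matrix agrees with t.test(var.equal = TRUE) gene by gene
  set.seed(9)
  x <- makeExperiment(nGenes = 25, nCase = 5, nControl = 4)
  tt2 <- studentT(x)
  ref <- apply(exprsMatrix(x), 1, function(v)
    t.test(v[1:5], v[6:9], var.equal = TRUE)$p.value)
  expect_equal(tt2$p, unname(ref), tolerance = 1e-12)

  expect_error(studentT(exprsMatrix(x), rep(c("CASE", "CONTROL"), c(1, 8))),
               "2 samples")
})

test_that("relative difference reduces to t and respects label symmetry", {
  set.seed(10)
  x <- makeExperiment(nGenes = 60, nCase = 5, nControl = 5)

  ## s0 = 0: d is exactly the pooled t (same standard-error convention)
  sam0 <- samAnalyze(x, s0 = 0, nPerm = 50, seed = 2)
  expect_equal(samTable(sam0)$d, studentT(x)$t, tolerance = 1e-12)

  ## flipping all CASE/CONTROL labels negates d and leaves q unchanged
  grp <- sampleCondition(x)
  flip <- ifelse(grp == "CASE", "CONTROL", "CASE")
  samA <- samAnalyze(exprsMatrix(x), grp, s0 = 0.1, nPerm = 100, seed = 3)
  samB <- samAnalyze(exprsMatrix(x), flip, s0 = 0.1, nPerm = 100, seed = 3)
  expect_equal(samTable(samA)$d, -samTable(samB)$d, tolerance = 1e-12)
  expect_identical(samTable(samA)$q, samTable(samB)$q)
})

test_that("permutation FDR is calibrated under the null", {
  for (s in 1:3) {
    set.seed(100 + s)
    m <- matrix(rnorm(1000 * 16), 1000,
                dimnames = list(sprintf("g%04d", 1:1000), paste0("a", 1:16)))
    sam <- samAnalyze(m, rep(c("CASE", "CONTROL"), each = 8),
                      nPerm = 150, seed = s)
    expect_lte(sum(samTable(sam)$q <= 0.02), 0.05 * 1000)
  }
})

test_that("dual statistics are equivariant to gene row order", {
  set.seed(12)
  x <- exprsMatrix(makeExperiment(nGenes = 40, nCase = 4, nControl = 4))
  grp <- rep(c("CASE", "CONTROL"), each = 4)
  perm <- sample(nrow(x))
  ## 4v4 balanced relabelings: only 36 distinct, so the request for 80
  ## must fall back to all of them with a warning
  expect_warning(sam1 <- samTable(samAnalyze(x, grp, nPerm = 80, seed = 5)),
                 "distinct")
  expect_warning(sam2 <- samTable(samAnalyze(x[perm, ], grp,
                                             nPerm = 80, seed = 5)),
                 "distinct")
  expect_equal(sam2[match(sam1$gene_id, sam2$gene_id), ]$q, sam1$q,
               tolerance = 1e-12)
  eb1 <- ebayesTable(eBayesModeratedT(x, grp))
  eb2 <- ebayesTable(eBayesModeratedT(x[perm, ], grp))
  expect_equal(eb2[match(eb1$gene_id, eb2$gene_id), ]$t_moderated,
               eb1$t_moderated, tolerance = 1e-12)
})

test_that("moderated t shrinks correctly and matches limma", {
  set.seed(13)
  n <- 600
  s2 <- 4 * 0.05 / rchisq(n, 4)
  m <- matrix(rnorm(n * 12, 0, sqrt(s2)), n,
              dimnames = list(sprintf("g%04d", 1:n), paste0("a", 1:12)))
  grp <- rep(c("CASE", "CONTROL"), each = 6)
  fit <- eBayesModeratedT(m, grp)

  ## independent route: limma's empirical-Bayes machinery
  lf <- limma::eBayes(limma::lmFit(m, cbind(1, grp == "CASE")))
  expect_equal(fit@d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit@s0sq, lf$s2.prior, tolerance = 1e-6)
  expect_equal(ebayesTable(fit)$t_moderated, unname(lf$t[, 2]),
               tolerance = 1e-10)
  expect_equal(ebayesTable(fit)$p_moderated, unname(lf$p.value[, 2]),
               tolerance = 1e-10)

  ## posterior variance lies strictly between s_g^2 and s0^2
  tab <- ebayesTable(fit)
  low <- tab$s2 < fit@s0sq
  expect_true(all(tab$s2_posterior[low] > tab$s2[low]))
  expect_true(all(tab$s2_posterior[low] < fit@s0sq))
  expect_true(all(tab$s2_posterior[!low] <= tab$s2[!low]))

  ## no-shrinkage limit recovers the ordinary t exactly
  f0 <- eBayesModeratedT(m, grp, priorDf = 0)
  st <- studentT(m, grp)
  expect_identical(ebayesTable(f0)$t_moderated, st$t)
  expect_identical(ebayesTable(f0)$p_moderated, st$p)

  ## all variances equal -> infinite prior df, normal-reference p-values
  mEq <- matrix(rep(c(1, 2, 3, 4, 1, 2, 3, 4), each = 5), 5, byrow = FALSE)
  dimnames(mEq) <- list(paste0("e", 1:5), paste0("a", 1:8))
  fEq <- eBayesModeratedT(mEq, rep(c("CASE", "CONTROL"), each = 4))
  expect_true(is.infinite(fEq@d0))
})

test_that("the intersection rule applies both thresholds and sign logic", {
  samTab <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                       mean_case = c(1, 1, 1, 0), mean_control = 0,
                       log_ratio = c(0.8, 0.8, -0.5, 0.4),
                       se = 0.1, d = c(2, 2, -2, 2),
                       q = c(0.01, 0.01, 0.001, 0.5),
                       degenerate = FALSE, stringsAsFactors = FALSE)
  ebTab <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      t_moderated = c(3, 3, -3, 3),
                      p_moderated = c(0.005, 0.02, 0.002, 0.001),
                      degenerate = FALSE, stringsAsFactors = FALSE)
  deg <- intersectDegs(samTab, ebTab)
  expect_identical(deg$gene_id, c("g1", "g3"))     # g2 fails p, g4 fails q
  expect_identical(deg$direction, c("up", "down"))
  expect_identical(attr(deg, "n_tested"), 4L)

  ## conflicting signs are excluded and reported
  ebTab$t_moderated[1] <- -3
  deg2 <- suppressMessages(intersectDegs(samTab, ebTab))
  expect_identical(deg2$gene_id, "g3")
  expect_identical(attr(deg2, "sign_conflicts"), "g1")
  deg3 <- intersectDegs(samTab, ebTab, requireSignAgreement = FALSE)
  expect_identical(deg3$gene_id, c("g1", "g3"))

  ebBad <- ebTab; ebBad$gene_id[1] <- "other"
  expect_error(intersectDegs(samTab, ebBad), "universes")
})

test_that("partition classes are exhaustive, disjoint and audited", {
  dmd <- data.frame(gene_id = c("a", "b", "c", "d"),
                    direction = c("up", "down", "up", "down"),
                    stringsAsFactors = FALSE)
  age <- data.frame(gene_id = c("c", "d", "e"),
                    direction = c("up", "up", "down"),
                    stringsAsFactors = FALSE)
  p <- partitionSets(dmd, age)
  cls <- setNames(p$class, p$gene_id)
  expect_identical(cls[["a"]], "DMD_only_up")
  expect_identical(cls[["b"]], "DMD_only_down")
  expect_identical(cls[["c"]], "shared_consistent_up")
  expect_identical(cls[["d"]], "shared_inconsistent")
  expect_identical(cls[["e"]], "AGE_only_down")

  ## conservation arithmetic: |DMD| = DMD_only + shared (and same for AGE)
  cnt <- attr(p, "counts")
  shared <- sum(cnt[c("shared_consistent_up", "shared_consistent_down",
                      "shared_inconsistent")])
  expect_identical(nrow(dmd),
                   as.integer(cnt[["DMD_only_up"]] +
                              cnt[["DMD_only_down"]] + shared))
  expect_identical(nrow(age),
                   as.integer(cnt[["AGE_only_up"]] +
                              cnt[["AGE_only_down"]] + shared))
  expect_identical(sum(cnt), length(union(dmd$gene_id, age$gene_id)))

  ## degenerate input: no AGE calls at all
  p0 <- partitionSets(dmd, age[0, ])
  expect_true(all(grepl("^DMD_only", p0$class)))
})
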