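test_that("probe collapse keeps the most discriminating probe", {
  ids <- paste0("s", 1:8)
  ann <- makeAnnotation(ids, 4)
  set.seed(21)
  noise <- matrix(rnorm(4 * 8, 0, 0.2), 4,
                  dimnames = list(c("pStrong", "pWeak", "qOnly", "rFlat"),
                                  ids))
  noise["pStrong", 1:4] <- noise["pStrong", 1:4] + 3   # tiny p
  noise["pWeak", 1:4] <- noise["pWeak", 1:4] + 0.25    # larger p
  x <- MuscleExperiment(noise, ann,
                        geneIds = c("G1", "G1", "G2", "G3"))
  out <- collapseProbes(x)
  expect_identical(rownames(out), c("G1", "G2", "G3"))
  kept <- S4Vectors::metadata(out)$kept_probes
  expect_identical(unname(kept["G1"]), "pStrong")
  expect_identical(exprsMatrix(out)["G1", ], noise["pStrong", ])
  ## single-probe gene passes through unchanged
  expect_identical(exprsMatrix(out)["G2", ], noise["qOnly", ])

  ## exact tie: identical probes -> lexicographically smallest id kept
  dup <- noise[c(1, 1, 3), ]
  rownames(dup) <- c("pB", "pA", "qOnly")
  xt <- MuscleExperiment(dup, ann, geneIds = c("G1", "G1", "G2"))
  expect_identical(
    unname(S4Vectors::metadata(collapseProbes(xt))$kept_probes["G1"]),
    "pA")

  ## gene with no valid (all-degenerate) probe is dropped and reported
  flat <- rbind(noise[1:3, ], rFlat = rep(1, 8))
  xf <- MuscleExperiment(flat, ann, geneIds = c("G1", "G1", "G2", "G4"))
  outF <- suppressMessages(collapseProbes(xf))
  expect_false("G4" %in% rownames(outF))
  expect_identical(S4Vectors::metadata(outF)$dropped_genes, "G4")
})

test_that("meta-matrix merge intersects universes and keeps annotations", {
  a <- makeExperiment(nGenes = 100, nCase = 3, nControl = 3,
                      seed = 1, dataset = "dA")
  b <- makeExperiment(nGenes = 100, nCase = 4, nControl = 4,
                      seed = 2, dataset = "dB")
  bSub <- b[11:100, ]                       # share 90 of 100 genes
  meta <- buildMetaMatrix(list(a, bSub), condition = "DMD")
  expect_identical(nrow(meta), 90L)
  expect_identical(ncol(meta), 6L + 8L)
  expect_identical(unique(datasetId(meta)), c("dA", "dB"))
  expect_identical(S4Vectors::metadata(meta)$condition, "DMD")

  ## single dataset: identity up to median centering
  one <- buildMetaMatrix(list(a), condition = "DMD")
  expect_equal(exprsMatrix(one),
               exprsMatrix(log2MedianCenter(a)), tolerance = 1e-12)

  ## union mode keeps all genes with explicit missingness
  metaU <- buildMetaMatrix(list(a, bSub), merge = "union")
  expect_identical(nrow(metaU), 100L)
  expect_identical(sum(is.na(exprsMatrix(metaU))), 10L * 8L)

  ## disjoint universes are an error
  a2 <- a; rownames(a2) <- paste0("other_", rownames(a))
  expect_error(buildMetaMatrix(list(a2, bSub)), "no genes")
})

test_that("status calls follow the ternary definition", {
  ids <- paste0("s", 1:12)
  ann <- makeAnnotation(ids, 6)
  set.seed(30)
  m <- matrix(rnorm(3 * 12, 0, 0.3), 3,
              dimnames = list(c("up", "down", "flat"), ids))
  m["up", 1:6] <- m["up", 1:6] + 2
  m["down", 1:6] <- m["down", 1:6] - 2
  st <- callStatus(MuscleExperiment(m, ann), condition = "DMD")
  expect_identical(st$status, c("+", "-", "0"))
  expect_true(all(st$p_value[1:2] < 0.01))
  expect_identical(st$condition, rep("DMD", 3))

  ## degenerate variance is never a call
  mC <- rbind(m, const = rep(5, 12))
  stC <- callStatus(MuscleExperiment(mC, ann))
  expect_identical(stC$status[4], "0")
  expect_true(stC$degenerate[4])
})

test_that("status calls are immune to dataset-level offsets", {
  sets <- lapply(1:3, function(i)
    makeExperiment(nGenes = 60, nCase = 4, nControl = 4, seed = i,
                   shift = c(rep(1.5, 10), rep(0, 50)),
                   dataset = paste0("d", i)))
  base <- callStatus(buildMetaMatrix(sets, "DMD"))
  shifted <- sets
  SummarizedExperiment::assay(shifted[[2]], "exprs") <-
    exprsMatrix(shifted[[2]]) + 7.3
  after <- callStatus(buildMetaMatrix(shifted, "DMD"))
  expect_identical(base$status, after$status)
  expect_equal(base$p_value, after$p_value, tolerance = 1e-12)
})

test_that("meta-cluster assignment partitions the universe", {
  mkCalls <- function(status, cond)
    data.frame(gene_id = paste0("g", seq_along(status)),
               condition = cond, status = status,
               stringsAsFactors = FALSE)
  dmd <- mkCalls(c("+", "+", "0", "-", "0"), "DMD")
  age <- mkCalls(c("+", "-", "0", "+", "-"), "AGE")
  mc <- assignMetaClusters(dmd, age)
  expect_identical(mc$meta_cluster,
                   c("DMD+AGE+", "DMD+AGE-", "DMD0AGE0",
                     "DMD-AGE+", "DMD0AGE-"))
  cnt <- attr(mc, "counts")
  expect_identical(length(cnt), 9L)
  expect_identical(sum(cnt), nrow(mc))

  expect_error(assignMetaClusters(dmd, age[1:4, ]), "universes")
})

test_that("cross-validation verdicts follow the concordance rules", {
  part <- data.frame(gene_id = c("a", "b", "c", "d"),
                     dir_dmd = c("up", "up", "down", NA),
                     dir_age = c(NA, "down", "down", "up"),
                     class = "x", stringsAsFactors = FALSE)
  dmd <- data.frame(gene_id = c("a", "b", "c"),
                    status = c("+", "-", "0"), stringsAsFactors = FALSE)
  age <- data.frame(gene_id = c("b", "c", "d"),
                    status = c("-", "+", "0"), stringsAsFactors = FALSE)
  v <- crossValidate(part, dmd, age)
  expect_identical(v$verdict_dmd, c("VALIDATED", "DISCORDANT",
                                    "UNCONFIRMED", NA))
  expect_identical(v$verdict_age, c(NA, "VALIDATED", "DISCORDANT",
                                    "UNCONFIRMED"))
  ## gene absent from the compendium is unvalidatable
  part2 <- data.frame(gene_id = "zz", dir_dmd = "up", dir_age = NA,
                      class = "x", stringsAsFactors = FALSE)
  expect_identical(crossValidate(part2, dmd, age)$verdict_dmd,
                   "UNVALIDATABLE")
  expect_identical(v$validated_any, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("verdicts are stable under dataset-order permutation", {
  sets <- lapply(1:4, function(i)
    makeExperiment(nGenes = 50, nCase = 4, nControl = 4, seed = i,
                   shift = c(rep(2, 8), rep(0, 42)),
                   dataset = paste0("d", i)))
  part <- data.frame(gene_id = sprintf("g%03d", 1:10),
                     dir_dmd = rep("up", 10), dir_age = NA,
                     class = "DMD_only_up", stringsAsFactors = FALSE)
  call1 <- callStatus(buildMetaMatrix(sets, "DMD"))
  call2 <- callStatus(buildMetaMatrix(rev(sets), "DMD"))
  age0 <- data.frame(gene_id = call1$gene_id, status = "0",
                     stringsAsFactors = FALSE)
  v1 <- crossValidate(part, call1, age0)
  v2 <- crossValidate(part, call2, age0)
  expect_identical(v1$verdict_dmd, v2$verdict_dmd)

  conc <- perDatasetConcordance(part, setNames(sets, paste0("d", 1:4)))
  expect_identical(nrow(conc), 40L)
  expect_gt(mean(conc$concordant), 0.9)   # planted 2-SD effects agree
})

test_that("sex-bias screen detects planted effects at the right level", {
  ## controls only, both sexes present by construction
  cfg <- syntheticConfig(nGenes = 400, nDatasets = 4,
                         sexBiasFraction = 0.05, sexEffect = 2,
                         statusFractions = statusFracs(), seed = 77)
  comp <- generateCompendium(cfg)
  nms <- grep("DMD", names(comp$datasets), value = TRUE)
  meta <- buildMetaMatrix(lapply(comp$datasets[nms], log2MedianCenter),
                          "DMD")
  sb <- detectSexBias(meta)
  tg <- truthGenes(comp$truth)
  planted <- tg$gene_id[tg$sex_biased]
  hit <- sb$sex_biased[match(planted, sb$gene_id)]
  expect_gt(mean(hit), 0.9)
  dirOk <- sb$direction[match(planted, sb$gene_id)] ==
    tg$sex_direction[match(planted, tg$gene_id)]
  expect_true(all(dirOk[hit]))
  ## null genes flagged at about the nominal rate
  nullRate <- mean(sb$sex_biased[!(sb$gene_id %in% planted)])
  expect_lt(nullRate, 0.04)

  ## single-sex compendium gives an empty result with a warning
  ids <- paste0("s", 1:8)
  ann <- makeAnnotation(ids, 4, sex = rep("M", 8))
  xm <- MuscleExperiment(matrix(rnorm(80), 10,
                                dimnames = list(paste0("g", 1:10), ids)),
                         ann)
  expect_warning(res <- detectSexBias(xm), "each sex")
  expect_identical(nrow(res), 0L)
})
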