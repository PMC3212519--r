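test_that("generator is deterministic and validates its configuration", {
  cfg <- syntheticConfig(nGenes = 100, nDatasets = 2, nSets = 4, seed = 42)
  a <- generateCompendium(cfg)
  b <- generateCompendium(cfg)
  expect_identical(names(a$datasets), names(b$datasets))
  for (nm in names(a$datasets))
    expect_identical(exprsMatrix(a$datasets[[nm]]),
                     exprsMatrix(b$datasets[[nm]]))
  expect_identical(truthGenes(a$truth), truthGenes(b$truth))

  il1 <- generateInLabStudy(cfg)
  il2 <- generateInLabStudy(cfg)
  expect_identical(exprsMatrix(il1$experiment), exprsMatrix(il2$experiment))

  bad <- statusFracs("DMD+AGE+" = 0.1)
  bad["DMD0AGE0"] <- 0.5
  expect_error(syntheticConfig(statusFractions = bad), "sum to 1")
  expect_error(generateGeneSets(a$truth,
                                syntheticConfig(nGenes = 100, setSize = 101)),
               "setSize")
  expect_identical(length(generateGeneSets(
    a$truth, syntheticConfig(nGenes = 100, nSets = 0, seed = 1))), 0L)
})

test_that("all-null configuration yields central t-statistics", {
  cfg <- syntheticConfig(nGenes = 800, nDatasets = 1,
                         statusFractions = statusFracs(),
                         sexBiasFraction = 0, datasetOffsetSd = 0,
                         seed = 5)
  comp <- generateCompendium(cfg)
  tg <- truthGenes(comp$truth)
  expect_true(all(tg$delta_dmd == 0) && all(tg$delta_age == 0))
  expect_true(all(tg$sex_delta == 0))

  tt <- studentT(comp$datasets[["DMD01"]])
  ks <- ks.test(tt$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planted effects realise the stated generative law", {
  ## (+,+) genes at 2 SD: standardised empirical case-control differences
  ## are N(0,1) around the planted shift, so their mean over G genes must
  ## sit within 3/sqrt(G) of zero
  cfg <- syntheticConfig(nGenes = 1000, nDatasets = 1,
                         statusFractions = statusFracs("DMD+AGE+" = 0.1),
                         effectSize = 2, sexBiasFraction = 0,
                         seed = 17)
  comp <- generateCompendium(cfg)
  tg <- truthGenes(comp$truth)
  planted <- tg$status_pair == "DMD+AGE+"
  expect_equal(sum(planted), 100)

  tt <- studentT(comp$datasets[["DMD01"]])
  zs <- (tt$log_ratio[planted] - 2 * tg$sd[planted]) /
    (tg$sd[planted] * sqrt(1 / cfg$nCase + 1 / cfg$nControl))
  expect_lt(abs(mean(zs)), 3 / sqrt(sum(planted)))
  ## and the minus arm mirrors it in the AGE condition
  cfg2 <- syntheticConfig(nGenes = 1000, nDatasets = 1,
                          statusFractions = statusFracs("DMD0AGE-" = 0.1),
                          effectSize = 2, sexBiasFraction = 0, seed = 18)
  comp2 <- generateCompendium(cfg2)
  tg2 <- truthGenes(comp2$truth)
  pl2 <- tg2$status_pair == "DMD0AGE-"
  tt2 <- studentT(comp2$datasets[["AGE01"]])
  zs2 <- (tt2$log_ratio[pl2] + 2 * tg2$sd[pl2]) /
    (tg2$sd[pl2] * sqrt(1 / cfg2$nCase + 1 / cfg2$nControl))
  expect_lt(abs(mean(zs2)), 3 / sqrt(sum(pl2)))
})

test_that("variance prior is recovered by moment matching", {
  cfg <- syntheticConfig(nGenes = 2000, nDatasets = 1,
                         statusFractions = statusFracs(),
                         sexBiasFraction = 0, varPriorDf = 4,
                         varPriorScale = 0.05, seed = 23)
  comp <- generateCompendium(cfg)
  fit <- eBayesModeratedT(comp$datasets[["DMD01"]])
  expect_lt(abs(fit@d0 - 4) / 4, 0.15)
  expect_lt(abs(fit@s0sq - 0.05) / 0.05, 0.15)
})

test_that("probe multiplicity and replicate spots follow the law", {
  cfg <- syntheticConfig(nGenes = 200, nDatasets = 1,
                         probeMultiplicity = c("1" = 0.5, "4" = 0.5),
                         seed = 31)
  comp <- generateCompendium(cfg)
  pr <- truthProbes(comp$truth)
  perGene <- table(pr$gene_id)
  expect_true(all(perGene %in% c(1L, 4L)))
  expect_gt(sum(perGene == 4), 50)   # about half the genes
  expect_false(anyDuplicated(pr$probe_id) > 0)
  ds <- comp$datasets[["DMD01"]]
  expect_identical(rownames(ds), pr$probe_id)
  expect_identical(geneIds(ds), pr$gene_id)
})

test_that("planted gene-set enrichment is realised and null sets are flat", {
  cfg <- syntheticConfig(nGenes = 1000, nSets = 20, setSize = 50,
                         enrichmentOdds = 20,
                         plantedSetClasses = rep("DMD+AGE+", 4),
                         statusFractions = statusFracs("DMD+AGE+" = 0.1),
                         seed = 41)
  truth <- generateTruth(cfg)
  sets <- generateGeneSets(truth, cfg)
  expect_identical(length(sets), 20L)
  tg <- truthGenes(truth)
  classGenes <- tg$gene_id[tg$status_pair == "DMD+AGE+"]
  planted <- sets@metadata$planted
  expect_identical(nrow(planted), 4L)
  backgroundRate <- length(classGenes) / cfg$nGenes
  for (nm in planted$set) {
    inClass <- mean(sets[[nm]] %in% classGenes)
    expect_gt(inClass, backgroundRate)
  }
  ## with odds 1 every set is a uniform draw: in-class rate stays near 0.1
  cfg1 <- syntheticConfig(nGenes = 1000, nSets = 30, setSize = 50,
                          enrichmentOdds = 1,
                          statusFractions = statusFracs("DMD+AGE+" = 0.1),
                          seed = 43)
  sets1 <- generateGeneSets(generateTruth(cfg1), cfg1)
  expect_identical(nrow(sets1@metadata$planted), 0L)
  rates <- vapply(geneSets(sets1), function(s)
    mean(s %in% truthGenes(generateTruth(cfg1))$gene_id[
      truthGenes(generateTruth(cfg1))$status_pair == "DMD+AGE+"]),
    numeric(1))
  expect_lt(abs(mean(rates) - 0.1), 0.05)
})
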