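## Synthetic multi-dataset compendium generator.
##
## Emulates the statistical structure of a two-condition (DMD, AGE)
## case/control muscle compendium: per-gene baseline levels, residual
## variances drawn from a scaled inverse-chi-square prior (so the
## empirical-Bayes moderated-t assumption holds by construction),
## dataset-specific additive offsets, planted status pairs on the 3x3
## grid, additive sex effects, replicate probes per gene, and gene sets
## enriched toward chosen status classes.
##
## The value for probe p of gene g in sample s of dataset d is
##   x = mu_g + delta_{g,c} * [s is CASE of condition c]
##            + sexdelta_g * [s is male] + off_d + e,
## e ~ N(0, sd_g), sd_g^2 ~ scaled-inv-chi2(varPriorDf, varPriorScale),
## off_d ~ N(0, datasetOffsetSd).  Status-0 genes get exactly zero
## planted effect so ground truth is unambiguous.

#' Configuration of the synthetic compendium
#'
#' Defaults reproduce the design of the emulated study: 2,745 expressed
#' genes, two case conditions (DMD, AGE) each observed in 6 independent
#' datasets with 8 CASE and 8 CONTROL arrays, planted effects of 2
#' within-group standard deviations, and gene variances from a scaled
#' inverse-chi-square law.
#'
#' @param nGenes Number of genes.
#' @param statusFractions Named numeric vector over [metaClusterLabels()]
#'   giving the fraction of genes planted in each status-pair cell; must
#'   sum to 1.  Default: 80% null (`DMD0AGE0`), 2.5% in each other cell.
#' @param effectSize Planted |mean shift| in units of the gene's residual
#'   standard deviation.
#' @param nDatasets Independent datasets per case condition.
#' @param nCase,nControl CASE / CONTROL arrays (columns) per dataset.
#' @param arraysPerSubject Replicate hybridisations per subject in the
#'   in-lab study (the emulated design hybridised every subject twice);
#'   arrays of one subject share the subject label and differ only in
#'   noise.  Compendium datasets always use one array per subject.
#' @param varPriorDf,varPriorScale Degrees of freedom and scale of the
#'   scaled inverse-chi-square law generating per-gene variances.
#' @param datasetOffsetSd SD of the per-dataset additive offset.
#' @param probeMultiplicity Named probability vector: probe copies per gene
#'   in compendium datasets (names = copy counts).
#' @param inLabSpotReplicates Replicate spots per gene on the in-lab array
#'   (the emulated design printed quadruplicate oligonucleotides).
#' @param sexBiasFraction Fraction of genes with an additive sex effect.
#' @param sexEffect |sex shift| in residual-SD units.
#' @param maleFractionCase,maleFractionControl Male fraction among CASE /
#'   CONTROL subjects (the emulated control population was a roughly
#'   60/40 male/female mix).
#' @param nSets,setSize Number and size of generated gene sets.
#' @param enrichmentOdds Sampling-odds multiplier toward the target status
#'   class for planted sets.
#' @param plantedSetClasses Character vector of status-pair labels, one per
#'   planted set; remaining sets are uniform background.  Default: one
#'   planted set per non-null cell when `enrichmentOdds > 1`.
#' @param seed Integer seed; the generator derives an independent stream
#'   per dataset from it, so identical seeds give bit-identical output.
#'
#' @return A validated configuration list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 2745,
                            statusFractions = NULL,
                            effectSize = 2,
                            nDatasets = 6,
                            nCase = 8, nControl = 8,
                            arraysPerSubject = 2,
                            varPriorDf = 4, varPriorScale = 0.05,
                            datasetOffsetSd = 0.3,
                            probeMultiplicity = c("1" = 1),
                            inLabSpotReplicates = 4,
                            sexBiasFraction = 0.011,
                            sexEffect = 2,
                            maleFractionCase = 0.5,
                            maleFractionControl = 0.6,
                            nSets = 40, setSize = 40,
                            enrichmentOdds = 20,
                            plantedSetClasses = NULL,
                            seed = 1L) {
  labels <- metaClusterLabels()
  if (is.null(statusFractions)) {
    statusFractions <- stats::setNames(rep(0.025, 9), labels)
    statusFractions["DMD0AGE0"] <- 0.8
  }
  if (!setequal(names(statusFractions), labels))
    stop("statusFractions must be named by metaClusterLabels()")
  statusFractions <- statusFractions[labels]
  if (abs(sum(statusFractions) - 1) > 1e-8)
    stop("statusFractions must sum to 1 (got ", sum(statusFractions), ")")
  if (nCase < 2 || nControl < 2)
    stop("at least 2 CASE and 2 CONTROL arrays per dataset are required")
  if (nCase %% arraysPerSubject || nControl %% arraysPerSubject)
    stop("group sizes must be multiples of arraysPerSubject")
  stopifnot(nGenes >= 2, nDatasets >= 1, effectSize > 0,
            varPriorDf > 0, varPriorScale > 0, datasetOffsetSd >= 0,
            sexBiasFraction >= 0, sexBiasFraction <= 1, sexEffect > 0,
            abs(sum(probeMultiplicity) - 1) < 1e-8)
  if (is.null(plantedSetClasses))
    plantedSetClasses <- if (enrichmentOdds > 1 && nSets > 0)
      utils::head(setdiff(labels, "DMD0AGE0"), min(8L, nSets))
    else character()
  if (!all(plantedSetClasses %in% labels))
    stop("plantedSetClasses must be status-pair labels")
  cfg <- list(nGenes = as.integer(nGenes),
              statusFractions = statusFractions,
              effectSize = effectSize,
              nDatasets = as.integer(nDatasets),
              nCase = as.integer(nCase), nControl = as.integer(nControl),
              arraysPerSubject = as.integer(arraysPerSubject),
              varPriorDf = varPriorDf, varPriorScale = varPriorScale,
              datasetOffsetSd = datasetOffsetSd,
              probeMultiplicity = probeMultiplicity,
              inLabSpotReplicates = as.integer(inLabSpotReplicates),
              sexBiasFraction = sexBiasFraction, sexEffect = sexEffect,
              maleFractionCase = maleFractionCase,
              maleFractionControl = maleFractionControl,
              nSets = as.integer(nSets), setSize = as.integer(setSize),
              enrichmentOdds = enrichmentOdds,
              plantedSetClasses = plantedSetClasses,
              seed = as.integer(seed))
  class(cfg) <- "syntheticConfig"
  cfg
}

## derive an independent, reproducible sub-seed (kept under 2^31)
.subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

.statusSign <- function(status) c("+" = 1, "-" = -1, "0" = 0)[status]

#' Draw the ground-truth gene table of a synthetic compendium
#'
#' Assigns status pairs by rounded deterministic counts (so realised
#' fractions match the configuration within rounding), draws baseline
#' levels, residual SDs from the inverse-chi-square prior, sex-bias flags
#' and the probe-to-gene map.
#'
#' @param config A [syntheticConfig()].
#' @return A [SyntheticTruth-class].
#' @export
generateTruth <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(.subSeed(config$seed, 1L))
  n <- config$nGenes
  geneId <- sprintf("G%05d", seq_len(n))

  counts <- round(config$statusFractions * n)
  counts["DMD0AGE0"] <- counts["DMD0AGE0"] + (n - sum(counts))
  if (any(counts < 0)) stop("status fractions incompatible with nGenes")
  pair <- sample(rep(names(counts), counts))
  statusDmd <- substr(pair, 4, 4)
  statusAge <- substr(pair, 8, 8)

  mu <- stats::rnorm(n, 0, 1)
  sd2 <- config$varPriorDf * config$varPriorScale /
    stats::rchisq(n, df = config$varPriorDf)
  sdg <- sqrt(sd2)
  deltaDmd <- .statusSign(statusDmd) * config$effectSize * sdg
  deltaAge <- .statusSign(statusAge) * config$effectSize * sdg

  nSex <- round(config$sexBiasFraction * n)
  sexBiased <- rep(FALSE, n)
  sexBiased[sample.int(n, nSex)] <- TRUE
  sexDirection <- rep(NA_character_, n)
  sexDirection[sexBiased] <- sample(c("M", "F"), nSex, replace = TRUE)
  sexDelta <- ifelse(sexBiased,
                     ifelse(sexDirection == "M", 1, -1) *
                       config$sexEffect * sdg, 0)

  copies <- as.integer(sample(names(config$probeMultiplicity), n,
                              replace = TRUE,
                              prob = config$probeMultiplicity))
  probes <- data.frame(
    probe_id = unlist(lapply(seq_len(n), function(i)
      if (copies[i] == 1L) geneId[i]
      else paste0(geneId[i], ".p", seq_len(copies[i])))),
    gene_id = rep(geneId, copies),
    stringsAsFactors = FALSE)

  genes <- data.frame(gene_id = geneId,
                      status_dmd = statusDmd, status_age = statusAge,
                      status_pair = pair,
                      mu = mu, sd = sdg,
                      delta_dmd = deltaDmd, delta_age = deltaAge,
                      sex_biased = sexBiased,
                      sex_direction = sexDirection,
                      sex_delta = sexDelta,
                      stringsAsFactors = FALSE)
  methods::new("SyntheticTruth", genes = genes, probes = probes,
               config = unclass(config))
}

## deterministic male/female assignment per subject: rounded counts,
## shuffled within the current RNG stream
.assignSex <- function(nSubjects, maleFraction) {
  nM <- round(maleFraction * nSubjects)
  sample(c(rep("M", nM), rep("F", nSubjects - nM)))
}

## simulate one dataset: probe-level matrix + annotation
.simulateDataset <- function(truth, config, cohort, datasetIndex,
                             nCase, nControl, arraysPerSubject,
                             probes, seedIndex) {
  set.seed(.subSeed(config$seed, seedIndex))
  g <- truth@genes
  rowGene <- match(probes$gene_id, g$gene_id)
  nProbes <- nrow(probes)
  dsId <- sprintf("%s%02d", cohort, datasetIndex)

  nCaseSub <- nCase / arraysPerSubject
  nCtrlSub <- nControl / arraysPerSubject
  sexCase <- rep(.assignSex(nCaseSub, config$maleFractionCase),
                 each = arraysPerSubject)
  sexCtrl <- rep(.assignSex(nCtrlSub, config$maleFractionControl),
                 each = arraysPerSubject)
  ann <- data.frame(
    sample_id = c(sprintf("%s_case_s%02da%d", dsId,
                          rep(seq_len(nCaseSub), each = arraysPerSubject),
                          rep(seq_len(arraysPerSubject), nCaseSub)),
                  sprintf("%s_ctrl_s%02da%d", dsId,
                          rep(seq_len(nCtrlSub), each = arraysPerSubject),
                          rep(seq_len(arraysPerSubject), nCtrlSub))),
    condition = c(rep("CASE", nCase), rep("CONTROL", nControl)),
    cohort = c(rep(cohort, nCase), rep("NONE", nControl)),
    sex = c(sexCase, sexCtrl),
    dataset_id = dsId,
    subject_id = c(sprintf("%s_case_s%02d", dsId,
                           rep(seq_len(nCaseSub), each = arraysPerSubject)),
                   sprintf("%s_ctrl_s%02d", dsId,
                           rep(seq_len(nCtrlSub), each = arraysPerSubject))),
    array_id = NA_character_,
    stringsAsFactors = FALSE)
  ann$array_id <- ann$sample_id

  off <- stats::rnorm(1, 0, config$datasetOffsetSd)
  delta <- if (cohort == "DMD") g$delta_dmd else g$delta_age
  caseInd <- as.numeric(ann$condition == "CASE")
  maleInd <- as.numeric(ann$sex == "M")
  m <- g$mu[rowGene] + off +
    outer(delta[rowGene], caseInd) +
    outer(g$sex_delta[rowGene], maleInd) +
    matrix(stats::rnorm(nProbes * nrow(ann), 0, g$sd[rowGene]),
           nrow = nProbes)
  dimnames(m) <- list(probes$probe_id, ann$sample_id)
  MuscleExperiment(m, ann, geneIds = probes$gene_id)
}

#' Generate a synthetic multi-dataset compendium
#'
#' Produces `nDatasets` independent case/control datasets for each of the
#' two conditions (DMD, AGE), sharing one gene-level ground truth, plus
#' that truth ledger.  Each dataset has its own additive offset, noise
#' stream and control group; probe multiplicity follows
#' `config$probeMultiplicity`.
#'
#' @param config A [syntheticConfig()].
#' @param truth Optional pre-generated [SyntheticTruth-class] (so an
#'   in-lab study and a compendium can share planted effects).
#' @return List with elements `datasets` (named list of
#'   [MuscleExperiment-class], names like `"DMD01"`, `"AGE03"`) and
#'   `truth`.
#' @export
generateCompendium <- function(config, truth = NULL) {
  stopifnot(inherits(config, "syntheticConfig"))
  if (is.null(truth)) truth <- generateTruth(config)
  datasets <- list()
  idx <- 10L
  for (cohort in c("DMD", "AGE")) {
    for (d in seq_len(config$nDatasets)) {
      idx <- idx + 1L
      ds <- .simulateDataset(truth, config, cohort, d,
                             config$nCase, config$nControl,
                             1L, truth@probes, idx)
      datasets[[sprintf("%s%02d", cohort, d)]] <- ds
    }
  }
  list(datasets = datasets, truth = truth)
}

#' Generate a synthetic in-lab study
#'
#' Emulates the in-lab two-channel design: one dataset in which DMD and
#' AGE cases are compared against one shared control group, every gene is
#' printed as `inLabSpotReplicates` replicate spots (independent noise,
#' shared gene mean), and each subject is hybridised on
#' `arraysPerSubject` replicate arrays.
#'
#' @param config A [syntheticConfig()].
#' @param truth Optional shared [SyntheticTruth-class].
#' @return List with elements `experiment` (spot-level
#'   [MuscleExperiment-class]; DMD cases, AGE cases, then controls),
#'   `spotMap` (`data.frame` of `probe_id`, `gene_id` for the replicate
#'   spots) and `truth`.
#' @export
generateInLabStudy <- function(config, truth = NULL) {
  stopifnot(inherits(config, "syntheticConfig"))
  if (is.null(truth)) truth <- generateTruth(config)
  g <- truth@genes
  r <- config$inLabSpotReplicates
  spotMap <- data.frame(
    probe_id = paste0(rep(g$gene_id, each = r), ".r", seq_len(r)),
    gene_id = rep(g$gene_id, each = r),
    stringsAsFactors = FALSE)

  ## one physical dataset -> one shared offset; the two simulated halves
  ## get none, a single offset is added afterwards
  cfg0 <- config
  cfg0$datasetOffsetSd <- 0
  dmd <- .simulateDataset(truth, cfg0, "DMD", 0L,
                          config$nCase, config$nControl,
                          config$arraysPerSubject, spotMap, 5L)
  age <- .simulateDataset(truth, cfg0, "AGE", 0L,
                          config$nCase, 2L, config$arraysPerSubject,
                          spotMap, 6L)
  keepAge <- sampleCondition(age) == "CASE"
  m <- cbind(exprsMatrix(dmd), exprsMatrix(age)[, keepAge, drop = FALSE])
  ann <- rbind(
    as.data.frame(SummarizedExperiment::colData(dmd)),
    as.data.frame(SummarizedExperiment::colData(age))[keepAge, ,
                                                      drop = FALSE])
  ann$dataset_id <- "INLAB"
  set.seed(.subSeed(config$seed, 7L))
  m <- m + stats::rnorm(1, 0, config$datasetOffsetSd)
  ## order columns: DMD cases, AGE cases, shared controls
  ord <- order(factor(ann$cohort, levels = c("DMD", "AGE", "NONE")))
  m <- m[, ord, drop = FALSE]
  ann <- ann[ord, , drop = FALSE]
  list(experiment = MuscleExperiment(m, ann, geneIds = spotMap$gene_id),
       spotMap = spotMap, truth = truth)
}

#' Generate gene sets with planted status-class enrichment
#'
#' Draws `config$nSets` sets of `config$setSize` genes from the truth's
#' gene universe.  For each planted set (one per entry of
#' `config$plantedSetClasses`) the sampling odds of genes in the target
#' status class are multiplied by `config$enrichmentOdds`; remaining sets
#' are uniform background draws.  With `enrichmentOdds = 1` all sets are
#' uniform.
#'
#' @param truth A [SyntheticTruth-class].
#' @param config The generating [syntheticConfig()].
#' @return A [GeneSetList-class] whose `metadata$planted` records the
#'   target class of each planted set.
#' @export
generateGeneSets <- function(truth, config) {
  stopifnot(inherits(config, "syntheticConfig"))
  if (config$setSize > config$nGenes)
    stop("setSize exceeds the number of genes")
  set.seed(.subSeed(config$seed, 99L))
  g <- truth@genes
  sets <- list()
  planted <- data.frame(set = character(), target_class = character(),
                        stringsAsFactors = FALSE)
  if (config$nSets > 0) {
    classes <- c(config$plantedSetClasses,
                 rep(NA_character_,
                     max(0L, config$nSets - length(config$plantedSetClasses))))
    classes <- classes[seq_len(config$nSets)]
    for (i in seq_len(config$nSets)) {
      nm <- sprintf("set%03d", i)
      w <- rep(1, nrow(g))
      if (!is.na(classes[i])) {
        w[g$status_pair == classes[i]] <- config$enrichmentOdds
        planted <- rbind(planted,
                         data.frame(set = nm, target_class = classes[i],
                                    stringsAsFactors = FALSE))
      }
      sets[[nm]] <- sample(g$gene_id, config$setSize, prob = w)
    }
  }
  GeneSetList(sets, universe = g$gene_id,
              metadata = list(planted = planted))
}
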