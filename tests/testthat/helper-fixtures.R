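## Small in-code fixtures shared across test files.

## annotation table for n samples; first nCase are CASE of the given cohort
makeAnnotation <- function(sampleIds, nCase,
                           cohort = "DMD",
                           sex = rep(c("M", "F"), length.out = length(sampleIds)),
                           dataset = "d1") {
  n <- length(sampleIds)
  data.frame(sample_id = sampleIds,
             condition = rep(c("CASE", "CONTROL"), c(nCase, n - nCase)),
             cohort = rep(c(cohort, "NONE"), c(nCase, n - nCase)),
             sex = sex,
             dataset_id = dataset,
             subject_id = sampleIds,
             array_id = sampleIds,
             stringsAsFactors = FALSE)
}

## deterministic gene x sample experiment with planted case-control shifts
makeExperiment <- function(nGenes = 50, nCase = 4, nControl = 4,
                           shift = numeric(nGenes), sd = 1, seed = 1,
                           cohort = "DMD", dataset = "d1",
                           prefix = dataset) {
  set.seed(seed)
  n <- nCase + nControl
  ids <- paste0(prefix, "_s", seq_len(n))
  m <- matrix(rnorm(nGenes * n, 0, sd), nGenes,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)), ids))
  m[, seq_len(nCase)] <- m[, seq_len(nCase)] + shift
  MuscleExperiment(m, makeAnnotation(ids, nCase, cohort, dataset = dataset))
}

## independent hypergeometric tail oracle: explicit point-mass enumeration
enumHyperTails <- function(k, K, n, N) {
  i <- max(0, K + n - N):min(K, n)
  pm <- exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  c(p_over = sum(pm[i >= k]), p_under = sum(pm[i <= k]))
}

## uniform draw from an integer vector that is safe for length-1 vectors
pickOne <- function(v) v[sample.int(length(v), 1L)]

## status-fraction vector: named cells get the given fractions, rest null
statusFracs <- function(...) {
  fr <- stats::setNames(rep(0, 9), metaClusterLabels())
  spec <- c(...)
  fr[names(spec)] <- spec
  fr["DMD0AGE0"] <- 1 - sum(spec)
  fr
}
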