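#' Simulate replicate datasets to files
#'
#' Generates replicates of a design (see [makeReplicates()]) and writes each
#' as a native TSV plus its ground-truth JSON sidecar. Rerunning with
#' identical arguments reproduces the files byte for byte.
#'
#' @inheritParams makeReplicates
#' @param outDir output directory (created if needed).
#' @param prefix filename prefix; files are `<prefix>_<i>.tsv`.
#' @return invisibly, the TSV paths written.
#' @export
simulateToFiles <- function(design, nReplicates, baseSeed, outDir,
                            prefix = if (is.character(design)) design
                                     else "dataset",
                            maf = 0.2) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  reps <- makeReplicates(design, nReplicates, baseSeed, maf = maf)
  paths <- vapply(seq_along(reps), function(i) {
    p <- file.path(outDir, sprintf("%s_%03d.tsv", prefix, i))
    writeDataset(reps[[i]], p)
    p
  }, character(1L))
  invisible(paths)
}

#' Search a dataset and rank the identified combinations
#'
#' Runs the full detector on one dataset: `nRestarts` GA runs, then the
#' combinatorial ranking of the best subsets. Optionally writes the
#' best-subset records as JSON-lines and the ranking as TSV.
#'
#' @param data a [GenotypeData-class] (or a path readable by
#'   [readGenotypeTable()]).
#' @param gaCfg a [gaConfig()]; defaults to [defaultGaConfig()] for the data
#'   size.
#' @param ensCfg an [ensembleConfig()].
#' @param masterSeed integer master seed; run i uses `masterSeed + i`.
#' @param nRestarts number of GA restarts.
#' @param kMin,kMax combination sizes to rank.
#' @param outDir optional output directory for `best_subsets.jsonl` and
#'   `combination_scores.tsv`.
#' @return list with `records` (the `BestSubsetRecord`s) and `scores` (the
#'   ranked combination table).
#' @export
searchDataset <- function(data, gaCfg = NULL, ensCfg = ensembleConfig(),
                          masterSeed = 0L, nRestarts = NULL,
                          kMin = 2L, kMax = 3L, outDir = NULL) {
  if (is.character(data)) data <- readGenotypeTable(data)
  if (is.null(gaCfg)) gaCfg <- defaultGaConfig(nFactors(data))
  if (is.null(nRestarts)) nRestarts <- gaCfg$nRestarts
  records <- runRestarts(data, gaCfg, ensCfg, nRestarts, masterSeed)
  scores <- enumerateCombinations(records, kMin, kMax)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonl <- file.path(outDir, "best_subsets.jsonl")
    lines <- vapply(records, function(r) {
      as.character(jsonlite::toJSON(list(seed = r$seed, subset = r$subset,
                            combined = r$fitness$combined,
                            fitnessB = r$fitness$fitnessB,
                            fitnessV = r$fitness$fitnessV,
                            fitnessD = r$fitness$fitnessD,
                            trace = r$trace),
                       auto_unbox = TRUE, digits = NA))
    }, character(1L))
    writeLines(lines, jsonl)
    writeCombinationScores(scores, file.path(outDir,
                                             "combination_scores.tsv"))
  }
  list(records = records, scores = scores)
}

#' Estimate detection power over simulated replicates
#'
#' Runs the detector on each replicate of a design and scores success as the
#' true functional pair being top-ranked among pairs.
#'
#' @param replicates list of [SimulatedDataset-class] objects.
#' @param gaCfg,ensCfg search configuration.
#' @param masterSeed base seed; replicate r uses master seed
#'   `masterSeed + 1000 * r` for its restarts.
#' @param nRestarts GA restarts per replicate.
#' @return list with `successes` (logical), `power` (percent), and
#'   `scoresList` (per-replicate ranking tables, for FDR/TPR curves).
#' @export
estimatePower <- function(replicates, gaCfg = NULL,
                          ensCfg = ensembleConfig(), masterSeed = 0L,
                          nRestarts = NULL) {
  scoresList <- vector("list", length(replicates))
  successes <- logical(length(replicates))
  truePairs <- vector("list", length(replicates))
  for (r in seq_along(replicates)) {
    sd <- replicates[[r]]
    res <- searchDataset(genotypeData(sd), gaCfg, ensCfg,
                         masterSeed = masterSeed + 1000L * r,
                         nRestarts = nRestarts)
    scoresList[[r]] <- res$scores
    truePairs[[r]] <- functionalIds(sd)
    successes[r] <- topPairSuccess(res$scores, functionalIds(sd))
  }
  list(successes = successes, power = identificationPower(successes),
       scoresList = scoresList, truePairs = truePairs)
}
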