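#' Configure the genetic-algorithm wrapper
#'
#' A chromosome is a fixed-length string of d positions, each holding a
#' factor id or 0 (an empty position); its decoded subset is the set of
#' distinct non-zero entries, so subsets of every size from 2 up to d are
#' explored in a single population in parallel.
#'
#' @param chromosomeSize d, the chromosome length (study range 15-25).
#' @param populationSize p (study range 40-340).
#' @param generations g, the termination generation (study range 8-20).
#' @param tournamentSize t (study range 3-7).
#' @param pCrossover single-point crossover probability (default 0.7).
#' @param pMutation probability a chromosome receives a first point mutation
#'   (default 0.1).
#' @param pChain probability each further mutation follows the previous one
#'   on the same chromosome (default 0.25; a geometric chain).
#' @param elitism number of best chromosomes copied unchanged into the next
#'   generation (default 1).
#' @param nRestarts number of independent GA runs whose best subsets feed the
#'   combinatorial ranking (default 30).
#' @return a `GAConfig` (a validated list).
#' @seealso [defaultGaConfig()] for the data-size-dependent defaults.
#' @export
gaConfig <- function(chromosomeSize = 15L, populationSize = 40L,
                     generations = 8L, tournamentSize = 3L,
                     pCrossover = 0.7, pMutation = 0.1, pChain = 0.25,
                     elitism = 1L, nRestarts = 30L) {
  stopifnot(chromosomeSize >= 2L, populationSize >= 2L, generations >= 1L,
            tournamentSize >= 1L, tournamentSize <= populationSize,
            pCrossover >= 0, pCrossover <= 1,
            pMutation >= 0, pMutation <= 1, pChain >= 0, pChain < 1,
            elitism >= 0L, nRestarts >= 1L)
  structure(list(chromosomeSize = as.integer(chromosomeSize),
                 populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 tournamentSize = as.integer(tournamentSize),
                 pCrossover = pCrossover, pMutation = pMutation,
                 pChain = pChain, elitism = as.integer(elitism),
                 nRestarts = as.integer(nRestarts)),
            class = "GAConfig")
}

#' Default GA parameters scaled to the number of factors
#'
#' Interpolates linearly within the study's parameter ranges: 20-factor data
#' get (d = 15, p = 40, g = 8, t = 3) and 100-factor data
#' (d = 25, p = 340, g = 20, t = 7); sizes outside [20, 100] are clamped.
#'
#' @param nFactors number of candidate factors in the dataset.
#' @param ... overrides passed on to [gaConfig()].
#' @return a `GAConfig`.
#' @export
defaultGaConfig <- function(nFactors, ...) {
  f <- (min(max(nFactors, 20L), 100L) - 20L) / 80
  defaults <- list(chromosomeSize = as.integer(round(15 + 10 * f)),
                   populationSize = as.integer(round(40 + 300 * f)),
                   generations = as.integer(round(8 + 12 * f)),
                   tournamentSize = as.integer(round(3 + 4 * f)))
  do.call(gaConfig, utils::modifyList(defaults, list(...)))
}

decodeSubset <- function(genes) sort(unique(genes[genes != 0L]))

#' Repair a chromosome to valid set semantics
#'
#' Collapses duplicate non-zero ids beyond their first occurrence to 0, and
#' if fewer than two distinct ids remain, resamples empty positions (from the
#' ambient RNG) until the decoded subset has at least two distinct factors.
#'
#' @param genes integer vector of factor indices and 0s.
#' @param nFactors number of valid factor indices.
#' @return the repaired chromosome.
#' @export
repairChromosome <- function(genes, nFactors) {
  nz <- genes != 0L
  dup <- duplicated(genes) & nz
  genes[dup] <- 0L
  while (length(decodeSubset(genes)) < 2L) {
    if (nFactors < 2L) stop("need at least two factors")
    slot <- which(genes == 0L)
    pick <- slot[sample.int(length(slot), 1L)]
    genes[pick] <- sample.int(nFactors, 1L)
    nz <- genes != 0L
    dup <- duplicated(genes) & nz
    genes[dup] <- 0L
  }
  genes
}

#' Initialize a GA population
#'
#' Each gene is independently 0 with probability 1/2 and otherwise a uniform
#' factor index; chromosomes are resampled until they decode to at least two
#' distinct factors. Deterministic given `seed`.
#'
#' @param config a [gaConfig()].
#' @param nFactors number of candidate factors.
#' @param seed optional integer seed; if `NULL` the ambient RNG is used.
#' @return a list of `populationSize` chromosomes.
#' @export
initializePopulation <- function(config, nFactors, seed = NULL) {
  draw <- function() {
    lapply(seq_len(config$populationSize), function(i) {
      repeat {
        genes <- ifelse(stats::runif(config$chromosomeSize) < 0.5, 0L,
                        sample.int(nFactors, config$chromosomeSize,
                                   replace = TRUE))
        if (length(decodeSubset(genes)) >= 2L)
          return(repairChromosome(genes, nFactors))
      }
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# total order on evaluated chromosomes: higher combined fitness first, exact
# ties favour the smaller decoded subset, then lexicographic factor ids
betterFitness <- function(a, b) {
  if (a$combined != b$combined) return(a$combined > b$combined)
  if (a$size != b$size) return(a$size < b$size)
  keyA <- paste(a$subset, collapse = "\r")
  keyB <- paste(b$subset, collapse = "\r")
  keyA < keyB
}

bestIndex <- function(fits, candidates = seq_along(fits)) {
  best <- candidates[1L]
  for (i in candidates[-1L])
    if (betterFitness(fits[[i]], fits[[best]])) best <- i
  best
}

#' Tournament selection
#'
#' Draws `t` chromosomes uniformly with replacement and returns the index of
#' the one with the highest combined fitness (exact ties: smaller subset,
#' then lexicographic ids).
#'
#' @param fits list of `FitnessBreakdown`s for the current population.
#' @param t tournament size.
#' @return the index of the winner.
#' @export
tournamentSelect <- function(fits, t) {
  bestIndex(fits, sample.int(length(fits), t, replace = TRUE))
}

#' Single-point crossover
#'
#' With probability `pCrossover` the two parents swap tails after a uniform
#' cut point in `1..d-1`; otherwise the children are copies. Children are
#' repaired with [repairChromosome()].
#'
#' @param a,b parent chromosomes of equal length.
#' @param nFactors number of valid factor indices.
#' @param pCrossover crossover probability.
#' @return a list of two children.
#' @export
singlePointCrossover <- function(a, b, nFactors, pCrossover = 0.7) {
  stopifnot(length(a) == length(b))
  d <- length(a)
  if (stats::runif(1L) < pCrossover && d >= 2L) {
    cut <- sample.int(d - 1L, 1L)
    tail <- seq(cut + 1L, d)
    tmp <- a[tail]
    a[tail] <- b[tail]
    b[tail] <- tmp
  }
  list(repairChromosome(a, nFactors), repairChromosome(b, nFactors))
}

#' Multi-point mutation
#'
#' With probability `pMutation` one uniform position is set to a uniform
#' value in {0} and the factor indices; each time a mutation occurs, a
#' further mutation follows with probability `pChain` (a geometric chain,
#' allowing pair mutations). The result is repaired.
#'
#' @param genes a chromosome.
#' @param nFactors number of valid factor indices.
#' @param pMutation first-mutation probability.
#' @param pChain continuation probability.
#' @return the mutated chromosome, with the number of point mutations
#'   applied in attribute `"mutations"`.
#' @export
multiMutate <- function(genes, nFactors, pMutation = 0.1, pChain = 0.25) {
  nMut <- 0L
  if (stats::runif(1L) < pMutation) {
    repeat {
      pos <- sample.int(length(genes), 1L)
      genes[pos] <- sample.int(nFactors + 1L, 1L) - 1L
      nMut <- nMut + 1L
      if (stats::runif(1L) >= pChain) break
    }
    genes <- repairChromosome(genes, nFactors)
  }
  structure(genes, mutations = nMut)
}

#' Run one GA search
#'
#' Evaluates each generation with the ensemble fitness (cached per decoded
#' subset; the stratified folds are drawn once per run and shared by every
#' subset, giving a paired evaluation), carries over the elite, and fills
#' the next generation by tournament selection, single-point crossover and
#' multi-mutation. Returns the best chromosome of the final generation,
#' which under elitism is the best subset seen. Deterministic given
#' `runSeed`.
#'
#' @param data a [GenotypeData-class] with no missing values.
#' @param gaCfg a [gaConfig()].
#' @param ensCfg an [ensembleConfig()].
#' @param runSeed integer seed for this run.
#' @return a `BestSubsetRecord`: list with `subset` (factor ids), `fitness`
#'   (a `FitnessBreakdown`), `trace` (per-generation best combined fitness,
#'   non-decreasing), `folds`, and `seed`.
#' @export
runGa <- function(data, gaCfg = defaultGaConfig(nFactors(data)),
                  ensCfg = ensembleConfig(), runSeed = 1L) {
  nFac <- nFactors(data)
  ids <- factorIds(data)
  Xall <- asCodedMatrix(data)
  yall <- asBinaryLabels(phenotype(data))
  kinds <- specKinds(ensCfg)
  param <- specParams(ensCfg)
  cache <- new.env(parent = emptyenv())
  evalChrom <- function(genes, folds) {
    subset <- decodeSubset(genes)
    key <- paste(subset, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fb <- evaluateSubsetFast(Xall, yall, subset, ids[subset], ensCfg,
                             folds, kinds, param)
    cache[[key]] <- fb
    fb
  }
  withr::with_seed(runSeed, {
    folds <- makeFolds(phenotype(data), ensCfg$nFolds)
    pop <- initializePopulation(gaCfg, nFac)
    fits <- lapply(pop, evalChrom, folds = folds)
    trace <- numeric(gaCfg$generations)
    trace[1L] <- fits[[bestIndex(fits)]]$combined
    for (gen in seq_len(gaCfg$generations)[-1L]) {
      newPop <- list()
      if (gaCfg$elitism > 0L) {
        eliteOrder <- order(vapply(fits, `[[`, numeric(1L), "combined"),
                            decreasing = TRUE)
        newPop <- pop[eliteOrder[seq_len(gaCfg$elitism)]]
      }
      while (length(newPop) < gaCfg$populationSize) {
        pa <- pop[[tournamentSelect(fits, gaCfg$tournamentSize)]]
        pb <- pop[[tournamentSelect(fits, gaCfg$tournamentSize)]]
        kids <- singlePointCrossover(pa, pb, nFac, gaCfg$pCrossover)
        for (kid in kids) {
          if (length(newPop) >= gaCfg$populationSize) break
          kid <- as.integer(multiMutate(kid, nFac, gaCfg$pMutation,
                                        gaCfg$pChain))
          newPop[[length(newPop) + 1L]] <- kid
        }
      }
      pop <- newPop
      fits <- lapply(pop, evalChrom, folds = folds)
      trace[gen] <- fits[[bestIndex(fits)]]$combined
    }
    best <- fits[[bestIndex(fits)]]
    structure(list(subset = best$subset, fitness = best, trace = trace,
                   folds = folds, seed = runSeed),
              class = "BestSubsetRecord")
  })
}

#' @export
print.BestSubsetRecord <- function(x, ...) {
  cat(sprintf("BestSubsetRecord (seed %s): {%s} combined fitness %.4f\n",
              format(x$seed), paste(x$subset, collapse = ", "),
              x$fitness$combined))
  invisible(x)
}

#' Run the n-restart protocol
#'
#' Repeats [runGa()] `nRestarts` times, run i using seed `masterSeed + i`,
#' and returns the best-subset records in run order. The records feed
#' [enumerateCombinations()].
#'
#' @inheritParams runGa
#' @param nRestarts number of restarts (defaults to the config's, study
#'   value 30).
#' @param masterSeed integer master seed.
#' @return a list of `BestSubsetRecord`s.
#' @export
runRestarts <- function(data, gaCfg = defaultGaConfig(nFactors(data)),
                        ensCfg = ensembleConfig(),
                        nRestarts = gaCfg$nRestarts, masterSeed = 0L) {
  stopifnot(nRestarts >= 1L)
  lapply(seq_len(nRestarts), function(i)
    runGa(data, gaCfg, ensCfg, runSeed = masterSeed + i))
}

#' Extract the decoded best subsets from restart records
#'
#' @param records a list of `BestSubsetRecord`s (or plain character vectors,
#'   passed through).
#' @return a list of character vectors of factor ids.
#' @export
bestSubsets <- function(records) {
  lapply(records, function(r)
    if (inherits(r, "BestSubsetRecord")) r$subset else as.character(r))
}
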