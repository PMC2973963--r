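test_that("population initialisation produces valid, reproducible chromosomes", {
  cfg <- gaConfig(chromosomeSize = 15L, populationSize = 40L)
  pop <- initializePopulation(cfg, 20L, seed = 5L)
  expect_length(pop, 40L)
  for (ch in pop) {
    expect_length(ch, 15L)
    expect_true(all(ch %in% 0:20))
    expect_gte(length(unique(ch[ch != 0])), 2L)
  }
  expect_identical(initializePopulation(cfg, 20L, seed = 5L), pop)
  # with only two factors every chromosome decodes to that pair
  pop2 <- initializePopulation(gaConfig(chromosomeSize = 15L,
                                        populationSize = 10L), 2L, seed = 1L)
  for (ch in pop2)
    expect_identical(sort(unique(ch[ch != 0])), c(1L, 2L))
})

test_that("chromosome repair collapses duplicates and refills tiny subsets", {
  genes <- c(3L, 0L, 3L, 7L, 3L)
  rep1 <- withr::with_seed(1, repairChromosome(genes, 10L))
  expect_identical(sum(rep1 == 3L), 1L)
  expect_gte(length(unique(rep1[rep1 != 0])), 2L)
  # a single-id chromosome gains a second distinct factor
  rep2 <- withr::with_seed(2, repairChromosome(c(4L, 4L, 0L, 0L), 10L))
  expect_gte(length(unique(rep2[rep2 != 0])), 2L)
})

test_that("tournament selection returns the fitness-maximal candidate", {
  mkFit <- function(combined, subset)
    combinedFitness(combined, combined, combined,
                    ensembleConfig(weights = c(blocking = 1, voting = 0,
                                               diversity = 0)),
                    subset = subset)
  fits <- list(mkFit(0.3, c("a", "b")), mkFit(0.9, c("c", "d")),
               mkFit(0.5, c("e", "f")))
  # independent oracle: replay the with-replacement draw and take the
  # argmax under the documented tie rules
  for (s in 1:20) {
    got <- withr::with_seed(s, tournamentSelect(fits, 3L))
    drawn <- withr::with_seed(s, sample.int(3L, 3L, replace = TRUE))
    vals <- vapply(fits[drawn], `[[`, numeric(1L), "combined")
    expect_identical(got, drawn[which.max(vals)])
  }
  # a large tournament all but surely sees every candidate: the global best
  # wins, and exact fitness ties favour the smaller subset
  expect_identical(withr::with_seed(1, tournamentSelect(fits, 50L)), 2L)
  tied <- list(mkFit(0.7, c("a", "b", "c", "d", "e")),
               mkFit(0.7, c("x", "y", "z")))
  expect_identical(withr::with_seed(1, tournamentSelect(tied, 50L)), 2L)
})

test_that("single-point crossover recombines and preserves set validity", {
  a <- c(1L, 2L, 3L, 4L, 5L, 6L)
  b <- c(7L, 8L, 9L, 10L, 11L, 12L)
  same <- withr::with_seed(1, singlePointCrossover(a, b, 12L, pCrossover = 0))
  expect_identical(same[[1L]], a)
  expect_identical(same[[2L]], b)
  kids <- withr::with_seed(2, singlePointCrossover(a, b, 12L, pCrossover = 1))
  # disjoint parents need no repair: children are prefix/suffix exchanges
  d <- length(a)
  cut <- sum(kids[[1L]] == a)  # prefix length from parent a
  expect_identical(kids[[1L]], c(a[seq_len(cut)], b[seq(cut + 1L, d)]))
  expect_identical(kids[[2L]], c(b[seq_len(cut)], a[seq(cut + 1L, d)]))
  idkids <- withr::with_seed(3, singlePointCrossover(a, a, 12L, pCrossover = 1))
  expect_identical(idkids[[1L]], a)
  expect_identical(idkids[[2L]], a)
})

test_that("multi-mutation fires at its nominal rate with a geometric chain", {
  genes <- c(1L, 0L, 5L, 9L, 0L, 3L)
  expect_identical(as.integer(withr::with_seed(1,
    multiMutate(genes, 10L, pMutation = 0))), genes)
  counts <- withr::with_seed(17, vapply(1:10000, function(i)
    attr(multiMutate(genes, 10L), "mutations"), integer(1L)))
  expect_lt(abs(mean(counts > 0) - 0.1), 0.01)
  # conditional mean chain length is 1 / (1 - 0.25) = 4/3
  expect_lt(abs(mean(counts[counts > 0]) - 4 / 3), 0.1)
})

test_that("GA runs are elitist, bounded, and seed-deterministic", {
  gd <- gaTestData()
  cfg <- gaConfig(chromosomeSize = 15L, populationSize = 20L,
                  generations = 5L, tournamentSize = 3L)
  rec <- runGa(gd, cfg, ensembleConfig(), runSeed = 9L)
  expect_true(all(diff(rec$trace) >= 0))
  expect_gte(length(rec$subset), 2L)
  expect_lte(length(rec$subset), cfg$chromosomeSize)
  rec2 <- runGa(gd, cfg, ensembleConfig(), runSeed = 9L)
  expect_identical(rec2$subset, rec$subset)
  expect_identical(rec2$trace, rec$trace)
  # a one-generation, two-chromosome run returns the better of the two
  tiny <- runGa(gd, gaConfig(chromosomeSize = 15L, populationSize = 2L,
                             generations = 1L, tournamentSize = 1L),
                ensembleConfig(), runSeed = 3L)
  expect_length(tiny$trace, 1L)
  expect_equal(tiny$trace, tiny$fitness$combined)
})

test_that("restart protocol yields ordered, reproducible records", {
  gd <- gaTestData()
  cfg <- gaConfig(chromosomeSize = 15L, populationSize = 15L,
                  generations = 3L, tournamentSize = 3L)
  recs <- runRestarts(gd, cfg, ensembleConfig(), nRestarts = 4L,
                      masterSeed = 100L)
  expect_length(recs, 4L)
  expect_identical(vapply(recs, function(r) r$seed, numeric(1L)),
                   as.numeric(101:104))
  again <- runRestarts(gd, cfg, ensembleConfig(), nRestarts = 4L,
                       masterSeed = 100L)
  expect_identical(lapply(recs, `[[`, "subset"),
                   lapply(again, `[[`, "subset"))
  single <- runRestarts(gd, cfg, ensembleConfig(), nRestarts = 1L,
                        masterSeed = 100L)
  expect_identical(single[[1L]]$subset,
                   runGa(gd, cfg, ensembleConfig(), runSeed = 101L)$subset)
})

test_that("a perfectly classifying pair is recovered across seeds", {
  # labels are a deterministic XOR of two loci among 18 noise SNPs
  gd <- xorBigData()
  cfg <- gaConfig(chromosomeSize = 15L, populationSize = 40L,
                  generations = 8L, tournamentSize = 3L)
  hits <- vapply(1:20, function(s) {
    rec <- runGa(gd, cfg, ensembleConfig(), runSeed = 200L + s)
    all(c("snp1", "snp2") %in% rec$subset)
  }, logical(1L))
  expect_gte(sum(hits), 18L)
})

test_that("default GA parameters scale with the factor count", {
  c20 <- defaultGaConfig(20L)
  expect_identical(c(c20$chromosomeSize, c20$populationSize,
                     c20$generations, c20$tournamentSize),
                   c(15L, 40L, 8L, 3L))
  c100 <- defaultGaConfig(100L)
  expect_identical(c(c100$chromosomeSize, c100$populationSize,
                     c100$generations, c100$tournamentSize),
                   c(25L, 340L, 20L, 7L))
  c60 <- defaultGaConfig(60L)
  expect_true(c60$chromosomeSize >= 15L && c60$chromosomeSize <= 25L)
  expect_true(c60$populationSize >= 40L && c60$populationSize <= 340L)
  expect_true(c60$generations >= 8L && c60$generations <= 20L)
  expect_true(c60$tournamentSize >= 3L && c60$tournamentSize <= 7L)
  # sizes below/above the calibration range clamp to its ends
  expect_identical(defaultGaConfig(5L)$chromosomeSize, 15L)
  expect_identical(defaultGaConfig(10000L)$populationSize, 340L)
})
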