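test_that("native TSV parses into a genotype matrix with labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp1\tsnp2\tclass",
               "0\t2\t1",
               "1\t1\t0",
               "2\t0\t1"), path)
  gd <- readGenotypeTable(path)
  expect_identical(dim(genotypes(gd)), c(3L, 2L))
  expect_identical(factorIds(gd), c("snp1", "snp2"))
  expect_identical(as.character(phenotype(gd)), c("case", "control", "case"))
  expect_identical(genotypes(gd)[, "snp2"], c(2L, 1L, 0L))
})

test_that("parse errors name the offending cell and invariant", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp1\tsnp2\tclass", "0\t5\t1", "1\t1\t0"), bad)
  expect_error(readGenotypeTable(bad), "row 1, column 'snp2'")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp1\tsnp1\tclass", "0\t1\t1", "1\t1\t0"), dup)
  expect_error(readGenotypeTable(dup), "duplicate factor id")

  oneclass <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp1\tclass", "0\t1", "1\t1"), oneclass)
  expect_error(readGenotypeTable(oneclass), "single-class")
})

test_that("PLINK .raw dialect maps additive codes and phenotype", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G",
    "F1 I1 0 0 1 2 0 2",
    "F2 I2 0 0 2 1 1 NA",
    "F3 I3 0 0 1 2 2 1"), path)
  gd <- readGenotypeTable(path, dialect = "plink_raw")
  expect_identical(factorIds(gd), c("rs1_A", "rs2_G"))
  expect_identical(as.character(phenotype(gd)), c("case", "control", "case"))
  expect_true(is.na(genotypes(gd)[2L, "rs2_G"]))
})

test_that("write-then-read round trip reproduces the object exactly", {
  g <- toyMatrix(rbind(c(0, 2, 1), c(1, NA, 0), c(2, 1, 3), c(0, 0, 1)),
                 ids = c("rs10", "rs2", "Sex"))
  g[3L, 3L] <- 1L  # environment codes stay small
  kinds <- c("snp", "snp", "environment")
  gd <- GenotypeData(g, c(1, 0, 1, 0), kinds)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(gd, path)
  back <- readGenotypeTable(path, factorKinds = kinds)
  expect_identical(genotypes(back), genotypes(gd))
  expect_identical(unname(factorKinds(back)), unname(factorKinds(gd)))
  expect_identical(phenotype(back), phenotype(gd))
  expect_identical(is.na(genotypes(back)), is.na(genotypes(gd)))
})

test_that("missingness filter keeps <= 20% and is idempotent", {
  g <- toyMatrix(cbind(c(0, 1, NA, 2),        # 25% missing -> dropped
                       c(0, 1, 2, 0),         # 0% -> kept
                       c(NA, 1, 2, 0)))       # exactly 25%... boundary below
  gd <- GenotypeData(g, c(1, 0, 1, 0))
  kept <- filterByMissingness(gd, maxRate = 0.20)
  expect_identical(factorIds(kept), "snp2")

  # exactly at the threshold is retained (strictly-greater excluded)
  g5 <- toyMatrix(matrix(c(0, 1, 2, 0, NA), 5, 1))
  gd5 <- GenotypeData(g5, c(1, 0, 1, 0, 1))
  expect_identical(factorIds(filterByMissingness(gd5, 0.20)), "snp1")

  twice <- filterByMissingness(filterByMissingness(gd, 0.20), 0.20)
  expect_identical(genotypes(twice), genotypes(kept))
  expect_warning(filterByMissingness(gd5, 0.1), "all factors")
})

test_that("mode imputation fills by column mode with smallest-code ties", {
  g <- toyMatrix(cbind(c(0, 0, 1, NA), c(0, 0, 1, 1)))
  gd <- GenotypeData(g, c(1, 0, 1, 0))
  expect_identical(unname(genotypes(imputeMode(gd))[4L, 1L]), 0L)

  g2 <- toyMatrix(matrix(c(0, 0, 1, 1, NA), 5, 1))
  gd2 <- GenotypeData(g2, c(1, 0, 1, 0, 1))
  expect_identical(unname(genotypes(imputeMode(gd2))[5L, 1L]), 0L)  # tie -> smaller

  full <- imputeMode(GenotypeData(toyMatrix(cbind(0:2)), c(1, 0, 1)))
  expect_identical(genotypes(full)[, 1L], 0:2)
})

test_that("allelic chi-square matches the hand Pearson formula", {
  # cases: 10x(g=2) + 10x(g=1) -> A=30, a=10; controls: 10x(g=1) + 10x(g=0)
  snp <- c(rep(2, 10), rep(1, 10), rep(1, 10), rep(0, 10))
  labels <- rep(c("case", "control"), each = 20)
  res <- allelicChisq(snp, labels)
  # independent oracle: Pearson chi-square = sum (O - E)^2 / E over the
  # 2x2 allele-by-class table (A,a) x (case,control)
  O <- rbind(c(30, 10), c(10, 30))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E))  # = 20
  expect_equal(res$statistic, 20)
  expect_equal(res$p, stats::pchisq(20, df = 1, lower.tail = FALSE))
  expect_identical(res$df, 1L)
})

test_that("degenerate and null allele tables give statistic 0, p 1", {
  labels <- rep(c("case", "control"), each = 4)
  same <- c(0, 1, 2, 1, 0, 1, 2, 1)  # identical allele freqs per class
  expect_equal(allelicChisq(same, labels)$statistic, 0)
  expect_equal(allelicChisq(same, labels)$p, 1)
  mono <- rep(0, 8)                  # zero allele-A margin
  expect_equal(allelicChisq(mono, labels)$statistic, 0)
  expect_equal(allelicChisq(mono, labels)$p, 1)
})

test_that("allelic chi-square is invariant to sample order and label swap", {
  withr::with_seed(5, {
    snp <- sample(0:2, 30, replace = TRUE)
    labels <- sample(c("case", "control"), 30, replace = TRUE,
                     prob = c(0.4, 0.6))
  })
  base <- allelicChisq(snp, labels)$statistic
  perm <- withr::with_seed(6, sample(30))
  expect_equal(allelicChisq(snp[perm], labels[perm])$statistic, base)
  swapped <- ifelse(labels == "case", "control", "case")
  expect_equal(allelicChisq(snp, swapped)$statistic, base)
})

test_that("association filter keeps SNPs with p < alpha and environment", {
  withr::with_seed(11, {
    m <- 60
    labels <- rep(c("case", "control"), each = m / 2)
    strong <- ifelse(labels == "case", 2L, 0L)
    noise <- sample(0:2, m, replace = TRUE)
    sex <- sample(0:1, m, replace = TRUE)
  })
  gd <- GenotypeData(toyMatrix(cbind(strong, noise, sex),
                               ids = c("rs_hit", "rs_noise", "Sex")),
                     labels, c("snp", "snp", "environment"))
  kept <- filterByAssociation(gd, alpha = 0.05)
  expect_true("rs_hit" %in% factorIds(kept))
  expect_true("Sex" %in% factorIds(kept))
  expect_false("rs_noise" %in% factorIds(kept))
})

test_that("age discretization follows the mu +/- sigma/2 rule inclusively", {
  ages <- c(50, 50, 70, 70)  # mu 60, population sd 10
  expect_identical(as.character(discretizeAge(ages)),
                   c("young", "young", "elderly", "elderly"))
  # independent oracle over an arbitrary vector
  withr::with_seed(3, ages2 <- round(runif(25, 40, 90)))
  mu <- mean(ages2); sigma <- sqrt(mean((ages2 - mu)^2))
  expected <- ifelse(ages2 <= mu - sigma / 2, "young",
                     ifelse(ages2 >= mu + sigma / 2, "elderly", "medium"))
  got <- discretizeAge(ages2)
  expect_identical(as.character(got), expected)
  # every sample gets exactly one category and counts sum to m
  expect_identical(sum(table(got)), length(ages2))
  expect_error(discretizeAge(rep(61, 5)), "constant ages")
})
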