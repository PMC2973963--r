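test_that("identification power is the success percentage", {
  expect_equal(identificationPower(c(rep(TRUE, 99), FALSE)), 99)
  expect_equal(identificationPower(rep(FALSE, 10)), 0)
  expect_equal(identificationPower(rep(TRUE, 7)), 100)
})

test_that("top-rank success includes ties containing the true pair", {
  tied <- enumerateCombinations(
    c(replicate(10, c("a", "b"), simplify = FALSE),
      replicate(10, c("c", "d"), simplify = FALSE)), kMax = 2)
  expect_true(topPairSuccess(tied, c("a", "b")))
  expect_true(topPairSuccess(tied, c("b", "a")))  # id order irrelevant
  lower <- enumerateCombinations(
    c(replicate(10, c("c", "d"), simplify = FALSE),
      replicate(4, c("a", "b"), simplify = FALSE)), kMax = 2)
  expect_false(topPairSuccess(lower, c("a", "b")))
  expect_false(topPairSuccess(enumerateCombinations(list()), c("a", "b")))
})

test_that("FDR and TPR at cutoffs follow their definitions", {
  scores <- enumerateCombinations(
    c(replicate(25, c("a", "b", "x", "y"), simplify = FALSE),
      replicate(5, c("p", "q"), simplify = FALSE)), kMax = 2)
  # at frequency cutoff 0.8 the 25/30 subsets contribute C(4,2) = 6 pairs,
  # one of which is the true pair
  expect_equal(fdrAt(scores, c("a", "b"), 0.8, "frequency"), 5 / 6)
  expect_equal(tprAt(scores, c("a", "b"), 0.8, "frequency"), 1)
  # only the true pair accepted -> FDR 0
  solo <- enumerateCombinations(replicate(10, c("a", "b"),
                                          simplify = FALSE), kMax = 2)
  expect_equal(fdrAt(solo, c("a", "b"), 0.5, "frequency"), 0)
  # nothing accepted -> FDR 0 by convention, TPR 0
  expect_equal(fdrAt(solo, c("a", "b"), 1, "frequency"), 0)
  expect_equal(tprAt(solo, c("a", "b"), 1, "frequency"), 0)
  # 1 true + 3 false accepted -> 0.75
  four <- enumerateCombinations(
    c(replicate(10, c("a", "b"), simplify = FALSE),
      replicate(10, c("c", "d"), simplify = FALSE),
      replicate(10, c("e", "f"), simplify = FALSE),
      replicate(10, c("g", "h"), simplify = FALSE)), kMax = 2)
  expect_equal(fdrAt(four, c("a", "b"), 0, "frequency"), 0.75)
  # rank cutoffs: true pair at rank 2 is missed at rank cutoff 1
  lower <- enumerateCombinations(
    c(replicate(10, c("c", "d"), simplify = FALSE),
      replicate(4, c("a", "b"), simplify = FALSE)), kMax = 2)
  expect_equal(tprAt(lower, c("a", "b"), 1, "rank"), 0)
  expect_equal(tprAt(lower, c("a", "b"), 2, "rank"), 1)
  # TPR is non-decreasing as the rank cutoff relaxes
  tprs <- vapply(1:10, function(r) tprAt(lower, c("a", "b"), r, "rank"),
                 numeric(1L))
  expect_true(all(diff(tprs) >= 0))
})

test_that("TPR at rank cutoff 1 aggregates to power over replicates", {
  withr::with_seed(30, {
    scoresList <- lapply(1:12, function(i) {
      winner <- if (i %% 3 == 0) c("a", "b") else c("c", "d")
      enumerateCombinations(
        c(replicate(9, winner, simplify = FALSE),
          replicate(3, c("a", "b"), simplify = FALSE)), kMax = 2)
    })
  })
  succ <- vapply(scoresList, topPairSuccess, logical(1L),
                 truePair = c("a", "b"))
  tpr1 <- vapply(scoresList, tprAt, numeric(1L), truePair = c("a", "b"),
                 cutoff = 1, type = "rank")
  expect_equal(mean(tpr1), identificationPower(succ) / 100)
})

test_that("averaged FDR/TPR curves are well formed", {
  scoresList <- list(
    enumerateCombinations(replicate(10, c("a", "b"), simplify = FALSE),
                          kMax = 2),
    enumerateCombinations(c(replicate(6, c("a", "b", "c"), simplify = FALSE),
                            replicate(4, c("a", "b"), simplify = FALSE)),
                          kMax = 2))
  curve <- fdrTprCurve(scoresList, c("a", "b"), type = "frequency")
  expect_true(all(curve$fdr >= 0 & curve$fdr <= 1))
  expect_true(all(diff(curve$tpr) >= 0))  # cutoffs decrease down the rows
  # the true pair is accepted everywhere here, so FDR grows as calls widen
  expect_true(all(diff(curve$fdr) >= 0))
})

test_that("fault tables cross-tabulate success and failure", {
  a <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  identical_ft <- faultTable(a, a)
  expect_identical(identical_ft$SF + identical_ft$FS, 0L)
  comp <- faultTable(a, !a)
  expect_identical(comp$FF, 0L)
  expect_identical(comp$SS, 0L)
  allfail <- faultTable(rep(FALSE, 5), rep(FALSE, 5))
  expect_identical(allfail$FF, 5L)
  expect_error(faultTable(a, a[1:3]), "length")
})

test_that("fault tables reconstruct from marginals by inclusion-exclusion", {
  ft <- faultTableFromMarginals(80, 75, 84, 100)
  expect_equal(unlist(ft[c("SS", "SF", "FS", "FF")]),
               c(SS = 71, SF = 9, FS = 4, FF = 16))
  ft2 <- faultTableFromMarginals(99, 99, 100, 100)
  expect_equal(unlist(ft2[c("SS", "SF", "FS", "FF")]),
               c(SS = 98, SF = 1, FS = 1, FF = 0))
  expect_error(faultTableFromMarginals(50, 50, 40, 100), "inconsistent")
  # agreement with direct cross-tabulation on random outcome vectors
  withr::with_seed(31, {
    for (i in 1:10) {
      x <- rbinom(50, 1, 0.6) == 1
      y <- rbinom(50, 1, 0.5) == 1
      direct <- faultTable(x, y)
      rebuilt <- faultTableFromMarginals(sum(x), sum(y), sum(x | y), 50)
      expect_equal(unlist(direct), unlist(rebuilt))
    }
  })
})

test_that("complementarity degree boundaries and undefined case", {
  expect_equal(complementarity(faultTableFromMarginals(80, 75, 84, 100)),
               13 / 29)
  noDouble <- list(SS = 90, SF = 6, FS = 4, FF = 0, N = 100)
  expect_equal(complementarity(noDouble), 1)
  subsumed <- list(SS = 50, SF = 0, FS = 0, FF = 50, N = 100)
  expect_equal(complementarity(subsumed), 0)
  bothPerfect <- list(SS = 100, SF = 0, FS = 0, FF = 0, N = 100)
  expect_true(is.na(complementarity(bothPerfect)))
})

test_that("joint power counts replicates rescued by either detector", {
  ft <- faultTableFromMarginals(80, 75, 84, 100)
  expect_equal(jointPowerPair(ft), 84)
  expect_equal(jointPowerPair(list(SS = 1, SF = 0, FS = 0, FF = 0, N = 1)),
               100)
  expect_equal(jointPowerPair(list(SS = 0, SF = 0, FS = 0, FF = 9, N = 9)),
               0)
  a <- c(TRUE, FALSE, FALSE)
  b <- c(FALSE, TRUE, FALSE)
  cc <- c(FALSE, FALSE, TRUE)
  expect_equal(jointPowerTriple(a, a, a), identificationPower(a))
  expect_equal(jointPowerTriple(a, b, cc), 100)  # never all three fail
  f <- rep(FALSE, 3)
  expect_equal(jointPowerTriple(f, f, f), 0)
  # unions grow: triple joint power dominates every pairwise joint power
  withr::with_seed(32, {
    x <- rbinom(40, 1, 0.5) == 1; y <- rbinom(40, 1, 0.5) == 1
    z <- rbinom(40, 1, 0.5) == 1
  })
  jp <- jointPowerTriple(x, y, z)
  expect_gte(jp, jointPowerPair(faultTable(x, y)))
  expect_gte(jp, jointPowerPair(faultTable(x, z)))
  expect_gte(jp, jointPowerPair(faultTable(y, z)))
  expect_gte(jointPowerPair(faultTable(x, y)),
             max(identificationPower(x), identificationPower(y)))
})

test_that("complementarity cells agree with hand inclusion-exclusion over
           the full study grid of detector marginals", {
  # (nX, nY, joint) -> expected CD as an exact fraction, derived by hand
  grid <- list(
    list(99, 97, 100, 4 / 4),    list(99, 99, 100, 2 / 2),
    list(97, 99, 99, 2 / 3),
    list(80, 75, 84, 13 / 29),   list(80, 81, 88, 15 / 27),
    list(75, 81, 81, 6 / 25),
    list(45, 43, 54, 20 / 66),   list(45, 43, 54, 20 / 66),
    list(43, 43, 45, 4 / 59),
    list(95, 93, 100, 12 / 12),  list(95, 93, 99, 10 / 11),
    list(93, 93, 95, 4 / 9),
    list(45, 49, 62, 30 / 68),   list(45, 51, 61, 26 / 65),
    list(49, 51, 54, 8 / 54),
    list(17, 19, 22, 8 / 86),    list(17, 21, 24, 10 / 86),
    list(19, 21, 21, 2 / 81),
    list(92, 90, 96, 10 / 14),   list(92, 95, 98, 9 / 11),
    list(90, 95, 97, 9 / 12),
    list(59, 45, 71, 38 / 67),   list(59, 62, 73, 25 / 52),
    list(45, 62, 68, 29 / 61),
    list(32, 24, 40, 24 / 84),   list(32, 27, 42, 25 / 83),
    list(24, 27, 38, 25 / 87))
  for (cell in grid) {
    ft <- faultTableFromMarginals(cell[[1L]], cell[[2L]], cell[[3L]], 100)
    expect_equal(complementarity(ft), cell[[4L]])
    expect_equal(jointPowerPair(ft), cell[[3L]])
  }
})

test_that("external outcome tables round-trip into success vectors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(replicate_id = rep(1:4, 3),
                   algorithm = rep(c("GE", "PIA", "MDR"), each = 4),
                   success = c(1, 1, 0, 1,  1, 0, 0, 1,  0, 1, 0, 1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- outcomeVectors(readOutcomeTable(path))
  expect_named(out, c("GE", "PIA", "MDR"))
  expect_identical(out$GE, c(TRUE, TRUE, FALSE, TRUE))
  tab <- complementarityTable(out)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$jointPower[tab$X == "GE" & tab$Y == "PIA"],
               jointPowerPair(faultTable(out$GE, out$PIA)))
  triple <- attr(tab, "tripleJointPower")
  expect_equal(triple$jointPower, jointPowerTriple(out$GE, out$PIA,
                                                   out$MDR))
  bad <- df[-2L, ]
  expect_error(outcomeVectors(bad), "mismatched replicate coverage")
})
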