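#' Identification power of a detector
#'
#' The percentage of replicate datasets in which the detector succeeded,
#' success meaning the true functional pair was reported as the top rank.
#'
#' @param successes logical (or 0/1) per-replicate success vector.
#' @return power as a percentage in [0, 100].
#' @export
identificationPower <- function(successes) {
  successes <- as.logical(successes)
  stopifnot(length(successes) >= 1L, !anyNA(successes))
  100 * mean(successes)
}

#' Did the ranking top-rank the true pair?
#'
#' Success for one replicate: the true functional pair is among the rank-1
#' size-2 combinations (ties at rank 1 that contain the true pair count as
#' success).
#'
#' @param scores output of [enumerateCombinations()] for one replicate.
#' @param truePair character vector of the two true factor ids.
#' @return `TRUE` or `FALSE`.
#' @export
topPairSuccess <- function(scores, truePair) {
  pairs <- scores[scores$k == 2L, , drop = FALSE]
  if (!nrow(pairs)) return(FALSE)
  combinationKey(truePair) %in% pairs$combination[pairs$rankK == 1L]
}

acceptedCalls <- function(scores, cutoff, type = c("frequency", "rank")) {
  type <- match.arg(type)
  pairs <- scores[scores$k == 2L, , drop = FALSE]
  if (type == "frequency") callByFrequency(pairs, cutoff)
  else callByRank(pairs, cutoff, within = "size")
}

#' False discovery rate of the called pairs at a cutoff
#'
#' Among the size-2 combinations accepted at the cutoff (frequency strictly
#' above, or dense rank at or above the cut), the fraction that are not the
#' true pair. Defined as 0 when nothing is accepted.
#'
#' @param scores output of [enumerateCombinations()] for one replicate.
#' @param truePair the two true factor ids.
#' @param cutoff frequency cutoff in [0, 1] or rank cutoff (>= 1).
#' @param type `"frequency"` or `"rank"`.
#' @return FDR in [0, 1].
#' @export
fdrAt <- function(scores, truePair, cutoff, type = c("frequency", "rank")) {
  acc <- acceptedCalls(scores, cutoff, type)
  if (!nrow(acc)) return(0)
  mean(acc$combination != combinationKey(truePair))
}

#' True positive rate of the called pairs at a cutoff
#'
#' The fraction of true pairs accepted at the cutoff; for a single replicate
#' with one embedded pair this is 0 or 1, and its mean over replicates at
#' rank cutoff 1 equals the identification power divided by 100.
#'
#' @inheritParams fdrAt
#' @return TPR in [0, 1].
#' @export
tprAt <- function(scores, truePair, cutoff, type = c("frequency", "rank")) {
  acc <- acceptedCalls(scores, cutoff, type)
  as.numeric(combinationKey(truePair) %in% acc$combination)
}

#' FDR/TPR curves averaged over replicates
#'
#' @param scoresList list of per-replicate [enumerateCombinations()] outputs.
#' @param truePairs a single true pair (character vector of 2) shared by all
#'   replicates, or a list of per-replicate pairs.
#' @param cutoffs cutoff grid; defaults to ranks 1-10 or frequencies 1-0 by
#'   0.05 depending on `type`.
#' @param type `"frequency"` or `"rank"`.
#' @return data.frame with columns `cutoff`, `fdr`, `tpr` (means over
#'   replicates).
#' @export
fdrTprCurve <- function(scoresList, truePairs, cutoffs = NULL,
                        type = c("frequency", "rank")) {
  type <- match.arg(type)
  if (is.null(cutoffs))
    cutoffs <- if (type == "rank") 1:10 else seq(1, 0, by = -0.05)
  if (!is.list(truePairs))
    truePairs <- rep(list(truePairs), length(scoresList))
  stopifnot(length(truePairs) == length(scoresList))
  rows <- lapply(cutoffs, function(cc) {
    fdr <- mapply(fdrAt, scoresList, truePairs,
                  MoreArgs = list(cutoff = cc, type = type))
    tpr <- mapply(tprAt, scoresList, truePairs,
                  MoreArgs = list(cutoff = cc, type = type))
    data.frame(cutoff = cc, fdr = mean(fdr), tpr = mean(tpr))
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Complementarity of multiple detectors

#' Cross-tabulate the success/failure of two detectors
#'
#' @param a,b logical (or 0/1) per-replicate success vectors of equal
#'   length, first index = detector X, second = detector Y.
#' @return a `FaultTable`: list with counts `SS`, `SF`, `FS`, `FF` and `N`
#'   (their sum).
#' @export
faultTable <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("outcome vectors differ in length")
  structure(list(SS = sum(a & b), SF = sum(a & !b),
                 FS = sum(!a & b), FF = sum(!a & !b),
                 N = length(a)),
            class = "FaultTable")
}

#' Reconstruct a fault table from marginal and joint success counts
#'
#' Given the per-detector success counts and the count of replicates where
#' at least one of the two succeeded (the joint-power count), recovers the
#' 2 x 2 table by inclusion-exclusion: `SS = nX + nY - joint`,
#' `SF = nX - SS`, `FS = nY - SS`, `FF = N - joint`.
#'
#' @param nX,nY success counts of the two detectors.
#' @param joint number of replicates where at least one succeeded.
#' @param N total replicates.
#' @return a `FaultTable`.
#' @export
faultTableFromMarginals <- function(nX, nY, joint, N) {
  if (joint < max(nX, nY) || joint > min(N, nX + nY))
    stop("inconsistent marginals: joint count must lie in [max(nX, nY), ",
         "min(N, nX + nY)]")
  ss <- nX + nY - joint
  structure(list(SS = ss, SF = nX - ss, FS = nY - ss, FF = N - joint, N = N),
            class = "FaultTable")
}

#' @export
print.FaultTable <- function(x, ...) {
  cat(sprintf("FaultTable (N = %d): SS %d, SF %d, FS %d, FF %d\n",
              x$N, x$SS, x$SF, x$FS, x$FF))
  invisible(x)
}

#' Degree of complementarity of two detectors
#'
#' `CD = SF / (DF + SF)` where SF counts the replicates with inconsistent
#' outcomes (one detector succeeds, the other fails) and DF those where both
#' fail. CD reaches 1 when failures never coincide and 0 when one detector's
#' successes subsume the other's. When both detectors succeed on every
#' replicate (SF + DF = 0) the ratio is undefined and `NA` is returned.
#'
#' @param ft a `FaultTable`.
#' @return CD in [0, 1], or `NA` when undefined.
#' @export
complementarity <- function(ft) {
  sf <- ft$SF + ft$FS
  df <- ft$FF
  if (sf + df == 0) return(NA_real_)
  sf / (df + sf)
}

#' Joint power of two detectors
#'
#' The percentage of replicates where at least one of the two detectors
#' succeeded: `100 (N - DF) / N`.
#'
#' @param ft a `FaultTable`.
#' @return joint power in [0, 100].
#' @export
jointPowerPair <- function(ft) 100 * (ft$N - ft$FF) / ft$N

#' Joint power of three detectors
#'
#' The percentage of replicates where at least one of the three detectors
#' succeeded; the complement counts the triple faults where all three fail.
#'
#' @param a,b,c logical (or 0/1) per-replicate success vectors.
#' @return joint power in [0, 100].
#' @export
jointPowerTriple <- function(a, b, c) {
  a <- as.logical(a); b <- as.logical(b); c <- as.logical(c)
  if (length(a) != length(b) || length(a) != length(c))
    stop("outcome vectors differ in length")
  100 * mean(a | b | c)
}

# ---------------------------------------------------------------------------
# External detector outcomes

#' Read per-replicate detector outcomes
#'
#' Reads a TSV with columns `replicate_id`, `algorithm`, `success` (0/1), so
#' results from external detectors (e.g. MDR, PIA) can be combined with this
#' package's without reimplementing them.
#'
#' @param path path to the TSV.
#' @return a data.frame of outcomes.
#' @export
readOutcomeTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("replicate_id", "algorithm", "success")
  if (!all(need %in% names(df)))
    stop("outcome table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Per-algorithm success vectors from an outcome table
#'
#' @param outcomes data.frame from [readOutcomeTable()].
#' @return named list of logical vectors, ordered by replicate id, one per
#'   algorithm; all algorithms must cover the same replicates.
#' @export
outcomeVectors <- function(outcomes) {
  algs <- unique(outcomes$algorithm)
  reps <- sort(unique(outcomes$replicate_id))
  out <- lapply(algs, function(a) {
    sub <- outcomes[outcomes$algorithm == a, ]
    if (!setequal(sub$replicate_id, reps) || anyDuplicated(sub$replicate_id))
      stop("mismatched replicate coverage for algorithm ", a)
    as.logical(sub$success[match(reps, sub$replicate_id)])
  })
  names(out) <- algs
  out
}

#' Pairwise complementarity and joint power of several detectors
#'
#' @param outcomes named list of per-replicate success vectors (see
#'   [outcomeVectors()]), all of equal length.
#' @return data.frame with one row per unordered detector pair: `X`, `Y`,
#'   `CD`, `jointPower`; if three or more detectors are given, the attribute
#'   `"tripleJointPower"` holds a data.frame of triple joint powers.
#' @export
complementarityTable <- function(outcomes) {
  algs <- names(outcomes)
  stopifnot(length(algs) >= 2L)
  pairs <- utils::combn(algs, 2L)
  rows <- apply(pairs, 2L, function(p) {
    ft <- faultTable(outcomes[[p[1L]]], outcomes[[p[2L]]])
    data.frame(X = p[1L], Y = p[2L], CD = complementarity(ft),
               jointPower = jointPowerPair(ft), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (length(algs) >= 3L) {
    triples <- utils::combn(algs, 3L)
    trows <- apply(triples, 2L, function(p) {
      data.frame(X = p[1L], Y = p[2L], Z = p[3L],
                 jointPower = jointPowerTriple(outcomes[[p[1L]]],
                                               outcomes[[p[2L]]],
                                               outcomes[[p[3L]]]),
                 stringsAsFactors = FALSE)
    })
    attr(res, "tripleJointPower") <- do.call(rbind, trows)
  }
  res
}
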