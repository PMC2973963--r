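#' Configure the classifier ensemble and its evaluation protocol
#'
#' @param specs list of [classifierSpec()] objects (M >= 2); defaults to the
#'   five of [defaultEnsembleSpecs()].
#' @param weights named weights for the three fitness components; must be
#'   non-negative and sum to 1. The tuned defaults are 0.425 (blocking),
#'   0.425 (voting) and 0.15 (diversity).
#' @param nFolds number of stratified cross-validation folds (default 5).
#' @return an `EnsembleConfig` (a validated list).
#' @export
ensembleConfig <- function(specs = defaultEnsembleSpecs(),
                           weights = c(blocking = 0.425, voting = 0.425,
                                       diversity = 0.15),
                           nFolds = 5L) {
  stopifnot(length(specs) >= 2L,
            all(vapply(specs, inherits, logical(1L), "ClassifierSpec")))
  if (is.null(names(weights)))
    names(weights) <- c("blocking", "voting", "diversity")
  stopifnot(setequal(names(weights), c("blocking", "voting", "diversity")),
            all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("integration weights must sum to 1")
  stopifnot(nFolds >= 2L)
  structure(list(specs = specs,
                 weights = weights[c("blocking", "voting", "diversity")],
                 nFolds = as.integer(nFolds)),
            class = "EnsembleConfig")
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds, stratified by class, using the
#' current RNG state (or a given seed). If a class has fewer members than
#' `k`, `k` is reduced with a warning so every fold sees both classes.
#'
#' @param labels case/control labels.
#' @param k number of folds.
#' @param seed optional integer seed; if `NULL` the ambient RNG is used.
#' @return integer vector of fold ids in `1..k`.
#' @export
makeFolds <- function(labels, k = 5L, seed = NULL) {
  y <- asPhenotype(labels)
  minClass <- min(table(y))
  if (k > minClass) {
    warning("reducing folds from ", k, " to ", minClass,
            " so every fold keeps both classes")
    k <- minClass
  }
  draw <- function() {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Balanced classification accuracy
#'
#' `BC = (Se + Sp) / 2` with sensitivity `Se = 100 N_TP / N_case` and
#' specificity `Sp = 100 N_TN / N_control`; the binary-class approximation
#' of the area under the ROC curve, robust to imbalanced class ratios.
#'
#' @param pred predicted labels.
#' @param truth true labels; both classes must be present.
#' @return BC in [0, 100].
#' @examples
#' balancedAccuracy(c(1, 1, 1, 1), c(1, 1, 0, 0)) # Se 100, Sp 0 -> 50
#' @export
balancedAccuracy <- function(pred, truth) {
  pred <- asBinaryLabels(pred)
  truth <- asBinaryLabels(truth)
  stopifnot(length(pred) == length(truth))
  nCase <- sum(truth == 1L)
  nControl <- sum(truth == 0L)
  if (nCase == 0L || nControl == 0L)
    stop("balanced accuracy needs both classes in the truth")
  se <- 100 * sum(pred == 1L & truth == 1L) / nCase
  sp <- 100 * sum(pred == 0L & truth == 0L) / nControl
  (se + sp) / 2
}

#' Pooled cross-validated ensemble predictions for a factor subset
#'
#' Restricts the data to the given factor subset, and for each stratified
#' fold trains every ensemble member on the remaining folds and predicts the
#' held-out fold, pooling predictions so that each sample is predicted
#' exactly once per classifier. The same fold assignment is shared by all
#' classifiers (and, when `folds` is supplied by the caller, across all
#' subsets of a search run, giving a paired evaluation).
#'
#' @param data a [GenotypeData-class] with no missing values.
#' @param subset factor ids (or column indices) of the candidate subset.
#' @param config an [ensembleConfig()].
#' @param folds optional precomputed fold assignment from [makeFolds()];
#'   defaults to a fresh assignment from the ambient RNG.
#' @return a `PredictionSet`: list with `predictions` (N x M 0/1 matrix,
#'   one column per classifier), `truth`, `N`, `nCase`, `nControl`, `prior`.
#' @export
crossValidatedPredictions <- function(data, subset, config = ensembleConfig(),
                                      folds = NULL) {
  stopifnot(length(subset) >= 1L)
  X <- asCodedMatrix(data[, subset])
  y <- asBinaryLabels(phenotype(data))
  if (is.null(folds)) folds <- makeFolds(phenotype(data), config$nFolds)
  pred <- cppCvEnsemble(X, y, as.integer(folds), specKinds(config),
                        specParams(config))
  colnames(pred) <- vapply(config$specs, `[[`, character(1L), "id")
  structure(list(predictions = pred, truth = y, N = length(y),
                 nCase = sum(y == 1L), nControl = sum(y == 0L),
                 prior = mean(y)),
            class = "PredictionSet")
}

#' Blocking fitness: mean per-classifier balanced accuracy
#'
#' Averages the balanced accuracy of the M classifiers on the shared data
#' split and rescales to [0, 1], so that the three fitness components are
#' commensurate under the integration weights.
#'
#' @param ps a `PredictionSet`.
#' @return value in [0, 1].
#' @export
fitnessBlocking <- function(ps) {
  y <- ps$truth
  se <- colSums(ps$predictions == 1L & y == 1L) / sum(y == 1L)
  sp <- colSums(ps$predictions == 0L & y == 0L) / sum(y == 0L)
  mean((se + sp) / 2)
}

#' Majority-voting consensus size
#'
#' The number of agreeing classifiers required for a majority decision:
#' `M/2 + 1` for even M, `(M + 1)/2` for odd M.
#'
#' @param M ensemble size.
#' @return the consensus size k.
#' @examples
#' consensusSize(5) # 3
#' consensusSize(4) # 3
#' @export
consensusSize <- function(M) {
  stopifnot(M >= 1)
  if (M %% 2 == 0) M / 2 + 1 else (M + 1) / 2
}

#' Voting fitness: balanced accuracy of the majority vote
#'
#' Each sample is assigned the class receiving at least [consensusSize()]
#' votes; an exact even split falls back to the training-class-prior
#' majority (prior tie: control). The fitness is the balanced accuracy of
#' the voted labels, rescaled to [0, 1].
#'
#' @param ps a `PredictionSet`.
#' @return value in [0, 1].
#' @export
fitnessVoting <- function(ps) {
  M <- ncol(ps$predictions)
  stopifnot(M >= 2L)
  votesCase <- rowSums(ps$predictions == 1L)
  priorLabel <- if (ps$prior > 0.5) 1L else 0L
  voted <- ifelse(votesCase * 2 > M, 1L,
                  ifelse(votesCase * 2 < M, 0L, priorLabel))
  balancedAccuracy(voted, ps$truth) / 100
}

#' Double-fault statistic of a classifier pair
#'
#' The fraction of samples misclassified by both classifiers.
#'
#' @param predA,predB predicted labels of the two classifiers.
#' @param truth true labels.
#' @return value in [0, 1].
#' @export
pairwiseDoubleFault <- function(predA, predB, truth) {
  predA <- asBinaryLabels(predA)
  predB <- asBinaryLabels(predB)
  truth <- asBinaryLabels(truth)
  stopifnot(length(predA) == length(truth), length(predB) == length(truth))
  mean(predA != truth & predB != truth)
}

#' Diversity fitness: one minus the mean pairwise double fault
#'
#' Averages the double-fault statistic over all M(M-1)/2 classifier pairs
#' and subtracts from 1. Equals 1 when no sample is misclassified by any
#' pair, and 0 when every classifier misclassifies every sample.
#'
#' @param ps a `PredictionSet`.
#' @return value in [0, 1].
#' @export
fitnessDiversity <- function(ps) {
  M <- ncol(ps$predictions)
  if (M < 2L) stop("diversity needs at least two classifiers")
  wrong <- (ps$predictions != ps$truth) * 1  # N x M
  joint <- crossprod(wrong) / ps$N           # [a, b] = double-fault rate
  total <- sum(joint[upper.tri(joint)])
  1 - 2 / (M * (M - 1)) * total
}

#' Combine the three fitness components
#'
#' The overall subset fitness is the weighted sum
#' `w_B * blocking + w_V * voting + w_D * diversity`, recorded together with
#' the subset size used by the complexity-regularization tie-break (exact
#' fitness ties favour the smaller subset).
#'
#' @param blocking,voting,diversity component values in [0, 1].
#' @param config an [ensembleConfig()] providing the weights.
#' @param subset optional factor ids, recorded for the tie-break.
#' @return a `FitnessBreakdown`: list with `fitnessB`, `fitnessV`,
#'   `fitnessD`, `combined`, `size`, `subset`.
#' @export
combinedFitness <- function(blocking, voting, diversity,
                            config = ensembleConfig(), subset = NULL) {
  stopifnot(blocking >= 0, blocking <= 1, voting >= 0, voting <= 1,
            diversity >= 0, diversity <= 1)
  w <- config$weights
  structure(list(
    fitnessB = blocking, fitnessV = voting, fitnessD = diversity,
    combined = unname(w["blocking"] * blocking + w["voting"] * voting +
                        w["diversity"] * diversity),
    size = length(subset), subset = subset),
    class = "FitnessBreakdown")
}

specKinds <- function(config) {
  vapply(config$specs, function(s)
    match(s$kind, c("decision_tree", "knn", "kstar")) - 1L, integer(1L))
}

specParams <- function(config) {
  vapply(config$specs, function(s)
    switch(s$kind, decision_tree = as.numeric(s$maxDepth),
           knn = as.numeric(s$k), kstar = s$blend), numeric(1L))
}

# hot path used by the GA: pre-extracted integer matrix and 0/1 labels,
# column indices, precomputed spec encoding — no S4 construction
evaluateSubsetFast <- function(X, y, subsetIdx, ids, config, folds,
                               kinds, param) {
  pred <- cppCvEnsemble(X[, subsetIdx, drop = FALSE], y,
                        folds, kinds, param)
  ps <- list(predictions = pred, truth = y, N = length(y),
             nCase = sum(y == 1L), nControl = sum(y == 0L),
             prior = mean(y))
  combinedFitness(fitnessBlocking(ps), fitnessVoting(ps),
                  fitnessDiversity(ps), config, subset = ids)
}

#' Evaluate a factor subset with the ensemble
#'
#' Runs [crossValidatedPredictions()] and assembles the blocking, voting and
#' diversity components into a combined fitness.
#'
#' @inheritParams crossValidatedPredictions
#' @return a `FitnessBreakdown` (see [combinedFitness()]).
#' @export
evaluateSubset <- function(data, subset, config = ensembleConfig(),
                           folds = NULL) {
  subset <- sort(subset)
  ps <- crossValidatedPredictions(data, subset, config, folds)
  ids <- if (is.character(subset)) subset else factorIds(data)[subset]
  combinedFitness(fitnessBlocking(ps), fitnessVoting(ps),
                  fitnessDiversity(ps), config, subset = ids)
}

#' @export
print.FitnessBreakdown <- function(x, ...) {
  cat(sprintf(
    "FitnessBreakdown [%s]: combined %.4f (B %.4f, V %.4f, D %.4f)\n",
    paste(x$subset, collapse = ", "),
    x$combined, x$fitnessB, x$fitnessV, x$fitnessD))
  invisible(x)
}
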