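#' Specify a base classifier
#'
#' The ensemble members are categorical classifiers sharing a uniform
#' train/predict contract: a gain-ratio decision tree (a C4.5-style
#' categorical tree without error-based pruning), exact k-nearest-neighbour
#' under the overlap (Hamming) distance, and a simplified KStar using the
#' categorical entropic transformation distance with instance-weighted
#' voting. Genotypes are treated as unordered categories throughout.
#'
#' @param kind `"decision_tree"`, `"knn"`, or `"kstar"`.
#' @param k neighbourhood size for `"knn"` (default 1).
#' @param blend KStar blend parameter in (0, 1) (default 0.20).
#' @param maxDepth depth limit for the tree; 0 means unlimited.
#' @param id identifier string; defaults to a descriptive name.
#' @return a `ClassifierSpec` (a validated list).
#' @export
classifierSpec <- function(kind = c("decision_tree", "knn", "kstar"),
                           k = 1L, blend = 0.20, maxDepth = 0L, id = NULL) {
  kind <- match.arg(kind)
  stopifnot(k >= 1, blend > 0, blend < 1, maxDepth >= 0)
  if (is.null(id))
    id <- switch(kind, decision_tree = "tree", kstar = "kstar",
                 knn = paste0(k, "nn"))
  structure(list(kind = kind, k = as.integer(k), blend = blend,
                 maxDepth = as.integer(maxDepth), id = id),
            class = "ClassifierSpec")
}

#' The default five-member ensemble
#'
#' The selected base classifiers: a gain-ratio decision tree (J48-like),
#' KStar, and k-nearest-neighbour with k = 1, 3 and 5 (equivalent in
#' predictions to their cover-tree-indexed variants, the cover tree being
#' only a search accelerator).
#'
#' @return a list of five [classifierSpec()] objects.
#' @export
defaultEnsembleSpecs <- function() {
  list(
    classifierSpec("decision_tree", id = "J48"),
    classifierSpec("kstar", id = "KStar"),
    classifierSpec("knn", k = 1L, id = "CT1NN"),
    classifierSpec("knn", k = 3L, id = "CT3NN"),
    classifierSpec("knn", k = 5L, id = "CT5NN")
  )
}

asCodedMatrix <- function(x) {
  if (is(x, "GenotypeData")) x <- genotypes(x)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (anyNA(x)) stop("missing values: impute upstream (see imputeMode)")
  x
}

asBinaryLabels <- function(labels) {
  if (is.numeric(labels) || is.logical(labels)) {
    v <- as.integer(labels)
    if (all(v == 0L | v == 1L)) return(v)
  }
  as.integer(asPhenotype(labels) == "case")
}

#' Train a base classifier
#'
#' @param spec a [classifierSpec()].
#' @param x training data: a [GenotypeData-class] or an integer matrix of
#'   category codes (no missing values), restricted to the factor subset
#'   under evaluation.
#' @param labels case/control labels (ignored and taken from `x` when `x` is
#'   a [GenotypeData-class]).
#' @return a `TrainedModel` holding the fitted state, the training factor
#'   ids, and the training class prior. Fitting is deterministic.
#' @export
fitClassifier <- function(spec, x, labels = NULL) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  if (is(x, "GenotypeData") && is.null(labels)) labels <- phenotype(x)
  y <- asBinaryLabels(labels)
  X <- asCodedMatrix(x)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("single-class training data")
  structure(list(spec = spec, X = X, y = y,
                 factorIds = colnames(X),
                 prior = mean(y)),
            class = "TrainedModel")
}

#' Predict case/control labels with a trained classifier
#'
#' The decision tree routes each sample through its splits, falling back to
#' a node's majority label for an unseen category; kNN takes the k nearest
#' training rows under the Hamming distance (distance ties broken by
#' training-row order, vote ties by the training class prior); KStar sums
#' per-instance transformation probabilities by class.
#'
#' @param model a `TrainedModel` from [fitClassifier()].
#' @param newdata a [GenotypeData-class] or coded matrix over the same factor
#'   ids the model was trained on.
#' @return a factor of predicted labels with levels `c("control", "case")`.
#' @export
predictClassifier <- function(model, newdata) {
  stopifnot(inherits(model, "TrainedModel"))
  Xte <- asCodedMatrix(newdata)
  if (!is.null(model$factorIds) && !is.null(colnames(Xte)) &&
      !identical(colnames(Xte), model$factorIds))
    stop("factor mismatch: model was trained on ",
         paste(model$factorIds, collapse = ", "))
  if (ncol(Xte) != ncol(model$X)) stop("factor mismatch: wrong column count")
  if (nrow(Xte) == 0L)
    return(factor(character(), levels = c("control", "case")))
  spec <- model$spec
  pred <- switch(spec$kind,
    decision_tree = cppTreePredict(model$X, model$y, Xte, spec$maxDepth),
    knn = cppKnnPredict(model$X, model$y, Xte, spec$k),
    kstar = cppKstarPredict(model$X, model$y, Xte, spec$blend))
  factor(ifelse(pred == 1L, "case", "control"),
         levels = c("control", "case"))
}
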