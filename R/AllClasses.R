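#' @useDynLib geneticEnsemble, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Case-control genotype/factor data
#'
#' An S4 container for a samples x factors table of categorical codes together
#' with case/control phenotype labels. SNP-kind factors are coded 0/1/2 for the
#' genotypes aa/Aa/AA (code 2 = major-allele homozygote); environment-kind
#' factors hold small non-negative integer category codes (e.g. Sex 0/1).
#' Missing cells are `NA`.
#'
#' @slot genotypes integer matrix (m samples x n factors) with unique, non-empty
#'   column names (the factor ids); `NA` marks a missing genotype.
#' @slot factorKinds character vector of length n, each `"snp"` or
#'   `"environment"`.
#' @slot phenotype factor of length m with levels `c("control", "case")`; both
#'   classes must be present.
#'
#' @seealso [GenotypeData()], [readGenotypeTable()], [filterByMissingness()]
#' @export
setClass("GenotypeData",
  representation(
    genotypes  = "matrix",
    factorKinds = "character",
    phenotype  = "factor"
  )
)

setValidity("GenotypeData", function(object) {
  g <- object@genotypes
  msgs <- character()
  if (!is.numeric(g) && !(is.matrix(g) && nrow(g) == 0L))
    msgs <- c(msgs, "genotypes must be a numeric/integer matrix")
  ids <- colnames(g)
  if (ncol(g) > 0L) {
    if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
      msgs <- c(msgs, "all factors must have non-empty ids (column names)")
    else if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicate factor id: %s",
                              ids[duplicated(ids)][1L]))
  }
  if (length(object@factorKinds) != ncol(g))
    msgs <- c(msgs, "factorKinds must have one entry per factor")
  if (!all(object@factorKinds %in% c("snp", "environment")))
    msgs <- c(msgs, "factorKinds must be 'snp' or 'environment'")
  snpCols <- which(object@factorKinds == "snp")
  if (length(snpCols)) {
    v <- g[, snpCols, drop = FALSE]
    bad <- !is.na(v) & !(v %in% c(0, 1, 2))
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      msgs <- c(msgs, sprintf(
        "SNP genotype outside {0,1,2} at row %d, column '%s'",
        idx[1L], ids[snpCols[idx[2L]]]))
    }
  }
  envCols <- which(object@factorKinds == "environment")
  if (length(envCols)) {
    v <- g[, envCols, drop = FALSE]
    bad <- !is.na(v) & (v < 0 | v != round(v))
    if (any(bad))
      msgs <- c(msgs, "environment factor codes must be non-negative integers")
  }
  if (length(object@phenotype) != nrow(g))
    msgs <- c(msgs, "phenotype length must equal the number of samples")
  if (!identical(levels(object@phenotype), c("control", "case")))
    msgs <- c(msgs, "phenotype levels must be c('control', 'case')")
  if (nrow(g) > 0L && length(unique(object@phenotype)) < 2L)
    msgs <- c(msgs, "single-class data: need at least one case and one control")
  if (length(msgs)) msgs else TRUE
})

#' Two-locus penetrance model
#'
#' A 3 x 3 penetrance table over the genotype pair of two biallelic loci, with
#' the minor-allele frequency of each locus. Genotype frequencies follow
#' Hardy-Weinberg equilibrium; cell `[i, j]` is the disease probability
#' given genotype code `i - 1` at locus A and `j - 1` at locus B
#' (0 = aa, 1 = Aa, 2 = AA). Prevalence and heritability are derived via
#' [prevalence()] and [heritability()].
#'
#' @slot mafA,mafB minor-allele frequencies in (0, 0.5].
#' @slot table 3 x 3 numeric matrix of penetrances in [0, 1].
#'
#' @seealso [PenetranceModel()], [findPenetranceTable()], [simulateDataset()]
#' @export
setClass("PenetranceModel",
  representation(mafA = "numeric", mafB = "numeric", table = "matrix")
)

setValidity("PenetranceModel", function(object) {
  msgs <- character()
  for (nm in c("mafA", "mafB")) {
    maf <- slot(object, nm)
    if (length(maf) != 1L || !is.finite(maf) || maf <= 0 || maf > 0.5)
      msgs <- c(msgs, sprintf("%s must be a single value in (0, 0.5]", nm))
  }
  f <- object@table
  if (!is.numeric(f) || !identical(dim(f), c(3L, 3L)))
    msgs <- c(msgs, "table must be a 3 x 3 numeric matrix")
  else if (any(!is.finite(f)) || any(f < -1e-12) || any(f > 1 + 1e-12))
    msgs <- c(msgs, "penetrances must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Simulated case-control dataset with an embedded functional pair
#'
#' The output of [simulateDataset()]: a [GenotypeData-class] matrix in which
#' two columns hold a functional SNP pair drawn from a [PenetranceModel-class]
#' conditional on case/control status, surrounded by label-independent noise
#' SNPs.
#'
#' @slot data the [GenotypeData-class] object.
#' @slot functionalIndices integer vector of length 2: the column positions of
#'   the functional pair (locus A, locus B).
#' @slot model the generating [PenetranceModel-class].
#' @slot seed the integer seed the dataset was drawn with.
#'
#' @export
setClass("SimulatedDataset",
  representation(
    data = "GenotypeData",
    functionalIndices = "integer",
    model = "PenetranceModel",
    seed = "numeric"
  )
)

setValidity("SimulatedDataset", function(object) {
  msgs <- character()
  fi <- object@functionalIndices
  n <- ncol(object@data@genotypes)
  if (length(fi) != 2L || anyDuplicated(fi) || any(fi < 1L) || any(fi > n))
    msgs <- c(msgs, "functionalIndices must be two distinct valid columns")
  if (length(msgs)) msgs else TRUE
})
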