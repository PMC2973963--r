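#' @rdname GenotypeData
#' @param x,object a `GenotypeData` object.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeData
#' @export
setGeneric("factorIds", function(x) standardGeneric("factorIds"))

#' @rdname GenotypeData
#' @export
setGeneric("factorKinds", function(x) standardGeneric("factorKinds"))

#' @rdname GenotypeData
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname GenotypeData
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeData
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))

#' Population prevalence of a penetrance model
#'
#' The disease prevalence K = sum over genotype-pair cells of
#' `P(gA) P(gB) f(gA, gB)` under Hardy-Weinberg genotype frequencies.
#'
#' @param model a [PenetranceModel-class].
#' @return the prevalence K in [0, 1].
#' @export
setGeneric("prevalence", function(model) standardGeneric("prevalence"))

#' Heritability of a penetrance model
#'
#' Heritability on the penetrance scale: the genotypic variance of penetrance
#' divided by the phenotypic variance `K (1 - K)`,
#' `h2 = sum_ij p_i p_j (f_ij - K)^2 / (K (1 - K))`. This is the standard
#' definition for purely epistatic penetrance-table simulation models.
#'
#' @param model a [PenetranceModel-class].
#' @return h2 in [0, 1].
#' @export
setGeneric("heritability", function(model) standardGeneric("heritability"))

#' @rdname SimulatedDataset-class
#' @param x a `SimulatedDataset`.
#' @export
setGeneric("genotypeData", function(x) standardGeneric("genotypeData"))

#' @rdname SimulatedDataset-class
#' @export
setGeneric("functionalIndices", function(x) standardGeneric("functionalIndices"))

#' @rdname SimulatedDataset-class
#' @export
setGeneric("functionalIds", function(x) standardGeneric("functionalIds"))
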