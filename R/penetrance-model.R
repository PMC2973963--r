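#' Hardy-Weinberg genotype frequencies
#'
#' Genotype probabilities for a biallelic locus with minor-allele frequency
#' `maf`, in genotype-code order (aa, Aa, AA) so that code 2 (AA) is the
#' major-allele homozygote: `(maf^2, 2 maf (1 - maf), (1 - maf)^2)`.
#'
#' @param maf minor-allele frequency in (0, 0.5].
#' @return numeric vector of length 3 summing to 1.
#' @examples
#' genotypeFreqs(0.2) # 0.04 0.32 0.64
#' @export
genotypeFreqs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("maf must be a single value in (0, 0.5]")
  c(aa = maf^2, Aa = 2 * maf * (1 - maf), AA = (1 - maf)^2)
}

#' Construct a two-locus penetrance model
#'
#' @param table 3 x 3 numeric matrix of penetrances `f[i, j]` indexed by the
#'   genotype codes (0 = aa, 1 = Aa, 2 = AA) of locus A (rows) and locus B
#'   (columns).
#' @param mafA,mafB minor-allele frequencies of the two loci; `mafB` defaults
#'   to `mafA`.
#' @return a [PenetranceModel-class] object.
#' @examples
#' xor <- matrix(0, 3, 3); xor[2, c(1, 3)] <- 1; xor[c(1, 3), 2] <- 1
#' m <- PenetranceModel(xor, 0.5)
#' prevalence(m)   # 0.5
#' heritability(m) # 1
#' @export
PenetranceModel <- function(table, mafA, mafB = mafA) {
  table <- as.matrix(table)
  dimnames(table) <- list(A = 0:2, B = 0:2)
  new("PenetranceModel", mafA = mafA, mafB = mafB, table = table)
}

#' @rdname prevalence
#' @export
setMethod("prevalence", "PenetranceModel", function(model) {
  p <- outer(genotypeFreqs(model@mafA), genotypeFreqs(model@mafB))
  sum(p * model@table)
})

#' @rdname heritability
#' @export
setMethod("heritability", "PenetranceModel", function(model) {
  p <- outer(genotypeFreqs(model@mafA), genotypeFreqs(model@mafB))
  K <- sum(p * model@table)
  if (K <= 0 || K >= 1)
    stop("heritability undefined: prevalence is ", K)
  sum(p * (model@table - K)^2) / (K * (1 - K))
})

#' Marginal penetrance deviations of a model
#'
#' For each locus, the per-genotype marginal penetrance minus the prevalence
#' K. A purely epistatic model has all deviations (numerically) zero.
#'
#' @param model a [PenetranceModel-class].
#' @return list with components `A` and `B`, each a length-3 numeric vector.
#' @export
marginalEffects <- function(model) {
  pA <- genotypeFreqs(model@mafA)
  pB <- genotypeFreqs(model@mafB)
  K <- prevalence(model)
  list(A = as.vector(model@table %*% pB) - K,
       B = as.vector(pA %*% model@table) - K)
}

#' @rdname PenetranceModel
#' @param object a `PenetranceModel`.
#' @export
setMethod("show", "PenetranceModel", function(object) {
  cat(sprintf("PenetranceModel: MAF A = %.3g, MAF B = %.3g\n",
              object@mafA, object@mafB))
  print(round(object@table, 4))
  K <- prevalence(object)
  if (K > 0 && K < 1)
    cat(sprintf("  prevalence K = %.4f, heritability h2 = %.4f\n",
                K, heritability(object)))
  else
    cat(sprintf("  prevalence K = %.4f (unusable for simulation)\n", K))
})

#' Find a purely epistatic penetrance table at a target heritability
#'
#' Seeded stochastic search for a 3 x 3 penetrance table with the requested
#' heritability and no marginal (main) effects at either locus. Each
#' iteration draws a candidate prevalence K and a random 3 x 3 perturbation,
#' projects the perturbation onto the subspace with zero
#' genotype-frequency-weighted row and column sums (so marginal penetrances
#' equal K exactly), scales it so the penetrance-scale heritability equals
#' `h2Target` exactly, and accepts the first candidate whose penetrances all
#' lie in [0, 1]. The search is deterministic given `seed`.
#'
#' @param h2Target target heritability in (0, 1).
#' @param maf minor-allele frequency of both functional loci (default 0.2).
#' @param seed integer seed.
#' @param tol acceptance tolerance on `|heritability - h2Target|` (the
#'   construction is exact up to floating point, far inside this tolerance).
#' @param maxIter maximum number of stochastic-search iterations.
#' @param kRange range the candidate prevalence is drawn from.
#' @return a [PenetranceModel-class] passing both the heritability and the
#'   no-main-effect checks.
#' @export
findPenetranceTable <- function(h2Target, maf = 0.2, seed = 1L, tol = 1e-3,
                                maxIter = 10000L, kRange = c(0.05, 0.5)) {
  if (!is.numeric(h2Target) || h2Target <= 0 || h2Target >= 1)
    stop("h2Target must lie in (0, 1)")
  pA <- genotypeFreqs(maf)
  pB <- genotypeFreqs(maf)
  pp <- outer(pA, pB)
  withr::with_seed(seed, {
    for (iter in seq_len(maxIter)) {
      K <- stats::runif(1L, kRange[1L], kRange[2L])
      e <- matrix(stats::runif(9L, -1, 1), 3L, 3L)
      # weighted double-centering: zero HWE-weighted row and column sums
      r <- as.vector(e %*% pB)
      cc <- as.vector(pA %*% e)
      t0 <- sum(pp * e)
      e <- e - outer(r, rep(1, 3L)) - outer(rep(1, 3L), cc) + t0
      varE <- sum(pp * e^2)
      if (varE < 1e-12) next
      f <- K + e * sqrt(h2Target * K * (1 - K) / varE)
      if (all(f >= 0) && all(f <= 1)) {
        model <- PenetranceModel(f, maf)
        if (abs(heritability(model) - h2Target) <= tol &&
            all(abs(unlist(marginalEffects(model))) <= 1e-3))
          return(model)
      }
    }
  })
  stop(sprintf(
    "no penetrance table with h2 = %g (maf = %g) found in %d iterations",
    h2Target, maf, maxIter))
}
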