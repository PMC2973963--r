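#' Simulate a case-control dataset with one embedded functional SNP pair
#'
#' Draws the genotype pair at the two functional loci conditional on disease
#' status — `P(gA, gB | case) = pA pB f / K` and
#' `P(gA, gB | control) = pA pB (1 - f) / (1 - K)` — by exact inverse-CDF
#' sampling over the nine genotype-pair cells, and draws every noise SNP
#' independently of the label under Hardy-Weinberg equilibrium. The two
#' functional loci are placed at seeded-random column positions, recorded in
#' the returned object.
#'
#' @param model a usable [PenetranceModel-class] (0 < K < 1).
#' @param nCase,nControl numbers of case and control samples.
#' @param nNoiseSnps number of non-functional SNPs; the matrix has
#'   `nNoiseSnps + 2` columns.
#' @param noiseMaf minor-allele frequency of the noise SNPs: a single value,
#'   or a range from which each noise SNP's MAF is drawn uniformly
#'   (default `c(0.05, 0.5)`).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [SimulatedDataset-class].
#' @examples
#' m <- findPenetranceTable(0.1, maf = 0.2, seed = 3)
#' sd <- simulateDataset(m, 100, 100, 18, seed = 11)
#' functionalIds(sd)
#' @export
simulateDataset <- function(model, nCase, nControl, nNoiseSnps,
                            noiseMaf = c(0.05, 0.5), seed = 1L) {
  stopifnot(nCase >= 1, nControl >= 1, nNoiseSnps >= 0)
  K <- prevalence(model)
  if (K <= 0 || K >= 1)
    stop("model prevalence is ", K, ": cannot condition on status")
  pp <- outer(genotypeFreqs(model@mafA), genotypeFreqs(model@mafB))
  wCase <- pp * model@table
  wControl <- pp * (1 - model@table)
  m <- nCase + nControl
  n <- nNoiseSnps + 2L
  withr::with_seed(seed, {
    pos <- sample.int(n, 2L)
    g <- matrix(NA_integer_, m, n,
                dimnames = list(NULL, paste0("snp", seq_len(n))))
    drawPairs <- function(k, w) {
      cells <- sample.int(9L, k, replace = TRUE, prob = as.vector(w))
      cbind((cells - 1L) %% 3L, (cells - 1L) %/% 3L)  # (gA, gB), column-major
    }
    pc <- drawPairs(nCase, wCase)
    pt <- drawPairs(nControl, wControl)
    g[, pos[1L]] <- c(pc[, 1L], pt[, 1L])
    g[, pos[2L]] <- c(pc[, 2L], pt[, 2L])
    noiseCols <- setdiff(seq_len(n), pos)
    mafs <- if (length(noiseMaf) == 2L)
      stats::runif(length(noiseCols), noiseMaf[1L], noiseMaf[2L])
    else rep(noiseMaf, length(noiseCols))
    for (i in seq_along(noiseCols)) {
      g[, noiseCols[i]] <- sample.int(3L, m, replace = TRUE,
                                      prob = genotypeFreqs(mafs[i])) - 1L
    }
    # emit samples in random order so that no downstream method can read the
    # phenotype off the row order (real cohorts are not class-sorted)
    ord <- sample.int(m)
    g <- g[ord, , drop = FALSE]
  })
  labels <- rep(c("case", "control"), c(nCase, nControl))[ord]
  new("SimulatedDataset",
      data = GenotypeData(g, labels),
      functionalIndices = as.integer(pos),
      model = model,
      seed = as.numeric(seed))
}

#' @rdname SimulatedDataset-class
#' @export
setMethod("genotypeData", "SimulatedDataset", function(x) x@data)

#' @rdname SimulatedDataset-class
#' @export
setMethod("functionalIndices", "SimulatedDataset", function(x)
  x@functionalIndices)

#' @rdname SimulatedDataset-class
#' @export
setMethod("functionalIds", "SimulatedDataset", function(x)
  colnames(x@data@genotypes)[x@functionalIndices])

#' @rdname SimulatedDataset-class
#' @param object a `SimulatedDataset`.
#' @export
setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset (seed %d): functional pair %s at columns %s\n",
              as.integer(object@seed),
              paste(functionalIds(object), collapse = " x "),
              paste(object@functionalIndices, collapse = ", ")))
  show(object@data)
})

#' Simulation designs of the evaluation study
#'
#' The nine case-control designs used for power evaluation: 200 samples with
#' a balanced (100:100) or imbalanced (67:133) case:control ratio, 20 or 100
#' SNPs (one embedded functional pair plus noise SNPs), heritability 0.2, 0.1
#' or 0.05, and 100 replicates per condition.
#'
#' @return a data.frame with one row per design.
#' @export
simDesigns <- function() {
  balanced <- expand.grid(h2 = c(0.2, 0.1, 0.05), nSnps = c(20L, 100L))
  imbal <- data.frame(h2 = c(0.2, 0.1, 0.05), nSnps = 20L)
  d <- rbind(
    data.frame(ratio = "1:1", nCase = 100L, nControl = 100L, balanced),
    data.frame(ratio = "1:2", nCase = 67L, nControl = 133L, imbal)
  )
  d$name <- sprintf("%s_200_%s_%d",
                    ifelse(d$ratio == "1:1", "balanced", "imbalanced"),
                    as.character(d$h2),
                    d$nSnps)
  d$nReplicates <- 100L
  d[, c("name", "nCase", "nControl", "ratio", "h2", "nSnps", "nReplicates")]
}

resolveDesign <- function(design) {
  if (is.character(design)) {
    d <- simDesigns()
    row <- d[d$name == design, ]
    if (nrow(row) != 1L)
      stop("unknown design name '", design, "'; see simDesigns()")
    as.list(row)
  } else if (is.list(design)) {
    stopifnot(all(c("nCase", "nControl", "h2", "nSnps") %in% names(design)))
    design
  } else stop("design must be a design name or a parameter list")
}

#' Generate replicate datasets of a simulation design
#'
#' Finds one penetrance model for the design's heritability (shared by all
#' replicates) and draws `nReplicates` datasets; replicate i uses seed
#' `baseSeed + i`.
#'
#' @param design a design name from [simDesigns()], or a list with `nCase`,
#'   `nControl`, `h2`, `nSnps`.
#' @param nReplicates number of replicates (each design's study value is 100).
#' @param baseSeed integer base seed; the model search uses `baseSeed`, and
#'   replicate i uses `baseSeed + i`.
#' @param maf functional-locus minor-allele frequency, default 0.2.
#' @param model optionally a pre-built [PenetranceModel-class] to use instead
#'   of searching.
#' @return a list of [SimulatedDataset-class] objects.
#' @export
makeReplicates <- function(design, nReplicates = 100L, baseSeed = 1L,
                           maf = 0.2, model = NULL) {
  stopifnot(nReplicates >= 1)
  d <- resolveDesign(design)
  if (is.null(model))
    model <- findPenetranceTable(d$h2, maf = maf, seed = baseSeed)
  lapply(seq_len(nReplicates), function(i) {
    simulateDataset(model, d$nCase, d$nControl, d$nSnps - 2L,
                    seed = baseSeed + i)
  })
}

#' Write a simulated dataset with its ground truth
#'
#' Writes the genotype table in the native TSV format plus a sidecar JSON
#' file recording the functional factor ids and column positions, the
#' penetrance model, and the seed.
#'
#' @param sd a [SimulatedDataset-class].
#' @param path output TSV path; the sidecar is written to
#'   `paste0(path, ".truth.json")`.
#' @return invisibly, the two paths written.
#' @export
writeDataset <- function(sd, path) {
  writeGenotypeTable(genotypeData(sd), path)
  truth <- list(
    functional_ids = functionalIds(sd),
    functional_indices = functionalIndices(sd),
    maf = c(sd@model@mafA, sd@model@mafB),
    penetrance_table = sd@model@table,
    prevalence = prevalence(sd@model),
    heritability = heritability(sd@model),
    seed = sd@seed
  )
  sidecar <- paste0(path, ".truth.json")
  jsonlite::write_json(truth, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}
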