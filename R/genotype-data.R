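#' Construct a GenotypeData object
#'
#' @param genotypes numeric matrix of category codes, samples in rows, factors
#'   in columns; column names are the factor ids. `NA` marks missing cells.
#' @param phenotype case/control labels: a factor with levels
#'   `c("control", "case")`, or a vector coercible to one (characters
#'   `"case"`/`"control"`, or 0 = control / 1 = case).
#' @param factorKinds character vector, one of `"snp"` or `"environment"` per
#'   factor; defaults to all `"snp"`.
#'
#' @return a [GenotypeData-class] object.
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 3,
#'             dimnames = list(NULL, c("snp1", "snp2")))
#' gd <- GenotypeData(g, c(0, 1, 1))
#' nSamples(gd)
#' @export
GenotypeData <- function(genotypes, phenotype,
                         factorKinds = rep("snp", ncol(genotypes))) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  new("GenotypeData",
      genotypes = genotypes,
      factorKinds = as.character(factorKinds),
      phenotype = asPhenotype(phenotype))
}

asPhenotype <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels) || all(labels %in% c("0", "1"))) {
    labels <- ifelse(as.numeric(labels) == 1, "case", "control")
  }
  if (!all(labels %in% c("case", "control")))
    stop("phenotype labels must be case/control (or 1/0)")
  factor(labels, levels = c("control", "case"))
}

#' @rdname GenotypeData
#' @export
setMethod("genotypes", "GenotypeData", function(x) x@genotypes)

#' @rdname GenotypeData
#' @export
setMethod("factorIds", "GenotypeData", function(x) colnames(x@genotypes))

#' @rdname GenotypeData
#' @export
setMethod("factorKinds", "GenotypeData", function(x) {
  structure(x@factorKinds, names = colnames(x@genotypes))
})

#' @rdname GenotypeData
#' @export
setMethod("phenotype", "GenotypeData", function(x) x@phenotype)

#' @rdname GenotypeData
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@genotypes))

#' @rdname GenotypeData
#' @export
setMethod("nFactors", "GenotypeData", function(x) ncol(x@genotypes))

#' @rdname GenotypeData
#' @param i,j sample and factor subscripts.
#' @param ...,drop ignored (present for generic compatibility).
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  if (is.character(j)) j <- match(j, colnames(x@genotypes))
  new("GenotypeData",
      genotypes = x@genotypes[i, j, drop = FALSE],
      factorKinds = x@factorKinds[j],
      phenotype = x@phenotype[i])
})

#' @rdname GenotypeData
#' @export
setMethod("show", "GenotypeData", function(object) {
  tab <- table(object@phenotype)
  cat(sprintf("GenotypeData: %d samples x %d factors (%d SNP, %d environment)\n",
              nrow(object@genotypes), ncol(object@genotypes),
              sum(object@factorKinds == "snp"),
              sum(object@factorKinds == "environment")))
  cat(sprintf("  %d cases / %d controls; %d missing cells\n",
              tab[["case"]], tab[["control"]], sum(is.na(object@genotypes))))
})

# ---------------------------------------------------------------------------
# I/O

#' Read a case-control genotype/factor table
#'
#' Reads a delimited text file with one sample per row and a header of factor
#' ids. Two layouts are supported: the package's native TSV/CSV (a label
#' column, by default named `"class"`, with 1 = case and 0 = control), and the
#' PLINK `.raw` additive-recode dialect (leading FID/IID/PAT/MAT/SEX/PHENOTYPE
#' columns, PHENOTYPE 2 = case / 1 = control, remaining columns 0/1/2 SNP
#' dosages).
#'
#' @param path path to the file.
#' @param dialect `"tsv"`, `"csv"`, or `"plink_raw"`.
#' @param missing token encoding a missing genotype (native dialects only;
#'   `.raw` uses `NA`).
#' @param labelColumn name of the label column in the native dialects.
#' @param factorKinds optional per-factor kinds (`"snp"`/`"environment"`) for
#'   the native dialects, in column order after removing the label column;
#'   defaults to all `"snp"`.
#' @return a [GenotypeData-class] object.
#' @seealso [writeGenotypeTable()]
#' @export
readGenotypeTable <- function(path,
                              dialect = c("tsv", "csv", "plink_raw"),
                              missing = "NA",
                              labelColumn = "class",
                              factorKinds = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "plink_raw") {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            na.strings = "NA", stringsAsFactors = FALSE)
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(lead %in% names(df)))
      stop("not a PLINK .raw file: missing leading columns")
    phen <- df[["PHENOTYPE"]]
    if (!all(phen %in% c(1, 2)))
      stop("PHENOTYPE must be 2 = case / 1 = control")
    labels <- ifelse(phen == 2, "case", "control")
    g <- df[, !(names(df) %in% lead), drop = FALSE]
    kinds <- rep("snp", ncol(g))
  } else {
    sep <- if (dialect == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, na.strings = missing,
                            stringsAsFactors = FALSE)
    if (!labelColumn %in% names(df))
      stop("label column '", labelColumn, "' not found")
    lab <- df[[labelColumn]]
    if (!all(lab %in% c(0, 1)))
      stop("label column must contain 1 = case / 0 = control")
    labels <- ifelse(lab == 1, "case", "control")
    g <- df[, names(df) != labelColumn, drop = FALSE]
    kinds <- if (is.null(factorKinds)) rep("snp", ncol(g)) else factorKinds
  }
  if (length(unique(labels)) < 2L) stop("single-class data: ", path)
  # data-frame subsetting silently uniquifies repeated header names, so the
  # duplicate check must run on the raw header
  if (anyDuplicated(names(df)))
    stop("duplicate factor id: ", names(df)[duplicated(names(df))][1L])
  gm <- as.matrix(g)
  if (!is.numeric(gm)) stop("non-numeric genotype codes in ", path)
  snpCols <- which(kinds == "snp")
  bad <- !is.na(gm[, snpCols, drop = FALSE]) &
    !(gm[, snpCols, drop = FALSE] %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid SNP genotype code at row %d, column '%s'",
                 idx[1L], colnames(gm)[snpCols[idx[2L]]]))
  }
  GenotypeData(gm, labels, kinds)
}

#' Write a genotype table in the native TSV format
#'
#' Writes one sample per row with a trailing `"class"` column (1 = case,
#' 0 = control) and missing cells as the given token. A file written here and
#' re-read with [readGenotypeTable()] (passing the same `factorKinds`)
#' reproduces the object exactly.
#'
#' @param gd a [GenotypeData-class] object.
#' @param path output path.
#' @param missing token to write for missing cells.
#' @export
writeGenotypeTable <- function(gd, path, missing = "NA") {
  df <- as.data.frame(genotypes(gd), check.names = FALSE)
  df[["class"]] <- as.integer(phenotype(gd) == "case")
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = missing,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Preprocessing

#' Drop factors with too many missing genotypes
#'
#' Retains exactly the factors whose missing fraction is less than or equal to
#' `maxRate`; a factor with strictly more missingness is excluded. Column
#' order is preserved, and the operation is idempotent.
#'
#' @param gd a [GenotypeData-class] object.
#' @param maxRate maximum tolerated missing fraction, default 0.20.
#' @return the filtered [GenotypeData-class].
#' @export
filterByMissingness <- function(gd, maxRate = 0.20) {
  stopifnot(maxRate >= 0, maxRate <= 1)
  rate <- colMeans(is.na(genotypes(gd)))
  keep <- which(rate <= maxRate)
  if (!length(keep)) warning("all factors exceeded the missingness threshold")
  gd[, keep]
}

#' Impute missing genotypes by the column mode
#'
#' Replaces each missing cell with the most frequent code in its column; ties
#' are broken toward the smallest code.
#'
#' @param gd a [GenotypeData-class] object.
#' @return a [GenotypeData-class] with no missing cells.
#' @export
imputeMode <- function(gd) {
  g <- genotypes(gd)
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (!any(miss)) next
    obs <- g[!miss, j]
    if (!length(obs)) stop("all-missing column: ", colnames(g)[j])
    counts <- table(obs)
    # names(counts) sorts numerically-as-character for small codes; take the
    # smallest code among the maxima
    modes <- as.integer(names(counts)[counts == max(counts)])
    g[miss, j] <- min(modes)
  }
  GenotypeData(g, phenotype(gd), factorKinds(gd))
}

#' Allelic chi-square test of a single SNP
#'
#' Forms the 2 x 2 allele-by-class table (a genotype coded g contributes g
#' copies of the major allele A and 2 - g copies of a) and computes the plain
#' Pearson chi-square statistic with 1 degree of freedom, without continuity
#' correction. A degenerate table (any zero margin) yields statistic 0 and
#' p = 1.
#'
#' @param snp per-sample genotype codes in {0, 1, 2} (`NA` allowed; missing
#'   samples are dropped).
#' @param labels case/control labels (anything [GenotypeData()] accepts).
#' @return a list with `statistic`, `p`, and `df = 1`.
#' @export
allelicChisq <- function(snp, labels) {
  labels <- asPhenotype(labels)
  keep <- !is.na(snp)
  snp <- snp[keep]
  labels <- labels[keep]
  tab <- rbind(
    case    = c(A = sum(snp[labels == "case"]),
                a = sum(2 - snp[labels == "case"])),
    control = c(A = sum(snp[labels == "control"]),
                a = sum(2 - snp[labels == "control"]))
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = 0, p = 1, df = 1L))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value), df = 1L)
}

#' Keep SNPs allelically associated with the phenotype
#'
#' Applies [allelicChisq()] to every SNP-kind factor and keeps those with
#' p-value strictly below `alpha`; environment-kind factors are always
#' retained.
#'
#' @param gd a [GenotypeData-class] object.
#' @param alpha significance threshold, default 0.05.
#' @return the filtered [GenotypeData-class].
#' @export
filterByAssociation <- function(gd, alpha = 0.05) {
  kinds <- factorKinds(gd)
  g <- genotypes(gd)
  keep <- vapply(seq_len(ncol(g)), function(j) {
    if (kinds[j] != "snp") return(TRUE)
    allelicChisq(g[, j], phenotype(gd))$p < alpha
  }, logical(1L))
  if (!any(keep)) warning("no factors passed the association filter")
  gd[, which(keep)]
}

#' Gaussian discretization of age
#'
#' Partitions numeric ages into three categories around the mean: `young` for
#' `x <= mu - sigma/2`, `elderly` for `x >= mu + sigma/2`, and `medium`
#' in between. `sigma` is the population standard deviation (divisor m).
#'
#' @param ages numeric vector with at least two distinct values.
#' @return a factor with levels `c("young", "medium", "elderly")`.
#' @export
discretizeAge <- function(ages) {
  stopifnot(is.numeric(ages), !anyNA(ages))
  mu <- mean(ages)
  sigma <- sqrt(mean((ages - mu)^2))
  if (sigma == 0) stop("constant ages: standard deviation is zero")
  out <- ifelse(ages <= mu - sigma / 2, "young",
                ifelse(ages >= mu + sigma / 2, "elderly", "medium"))
  factor(out, levels = c("young", "medium", "elderly"))
}
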