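# fixtures built in code; everything seeded

# m x n genotype matrix with named SNP columns
toyMatrix <- function(values, ids = paste0("snp", seq_len(ncol(values)))) {
  values <- as.matrix(values)
  colnames(values) <- ids
  values
}

# dataset whose label equals an XOR-like function of two SNPs: case iff
# exactly one of the two loci is heterozygous; every 9-cell combo present
xorData <- function(reps = 4L, nNoise = 0L, seed = 99L) {
  grid <- expand.grid(a = 0:2, b = 0:2)
  g <- grid[rep(seq_len(nrow(grid)), reps), ]
  labels <- ifelse((g$a == 1) + (g$b == 1) == 1, "case", "control")
  m <- nrow(g)
  gm <- cbind(g$a, g$b)
  if (nNoise > 0L) {
    gm <- cbind(gm, withr::with_seed(seed,
      matrix(sample(0:2, m * nNoise, replace = TRUE), m, nNoise)))
  }
  colnames(gm) <- paste0("snp", seq_len(ncol(gm)))
  GenotypeData(gm, labels)
}

# pure 2x2 XOR over the homozygote codes: case iff exactly one locus is AA;
# each single locus carries zero information gain
xor2Data <- function(reps = 5L) {
  grid <- expand.grid(a = c(0L, 2L), b = c(0L, 2L))
  g <- grid[rep(seq_len(nrow(grid)), reps), ]
  labels <- ifelse((g$a == 2) + (g$b == 2) == 1, "case", "control")
  gm <- toyMatrix(cbind(g$a, g$b))
  GenotypeData(gm, labels)
}

# two Hamming-separated clusters of unique rows with cluster-constant labels:
# every classifier can memorise this set
clusterData <- function() {
  a <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  b <- as.matrix(expand.grid(3:4, 3:4, 3:4))
  g <- rbind(a, b)
  colnames(g) <- c("f1", "f2", "f3")
  labels <- rep(c("control", "case"), each = 8L)
  list(x = g, labels = labels)
}

# a dataset where one SNP separates the classes perfectly
separableData <- function(m = 40L, nNoise = 3L, seed = 7L) {
  labels <- rep(c("case", "control"), length.out = m)
  g <- matrix(ifelse(labels == "case", 2L, 0L), m, 1L)
  g <- cbind(g, withr::with_seed(seed,
    matrix(sample(0:2, m * nNoise, replace = TRUE), m, nNoise)))
  colnames(g) <- paste0("snp", seq_len(ncol(g)))
  GenotypeData(g, labels)
}

# hand-made prediction set
makePs <- function(pred, truth) {
  pred <- as.matrix(pred)
  list(predictions = pred, truth = truth, N = length(truth),
       nCase = sum(truth == 1L), nControl = sum(truth == 0L),
       prior = mean(truth))
}

# memoised shared fixtures for the slower tests
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

epiModel <- function(h2, seed = 1L) {
  fixture(paste0("model_", h2, "_", seed),
          findPenetranceTable(h2, maf = 0.2, seed = seed))
}

# small simulated dataset shared by the GA tests
gaTestData <- function() {
  fixture("gaData",
          genotypeData(simulateDataset(epiModel(0.2), 60, 60, 8,
                                       seed = 31L)))
}

# a perfectly classifying XOR pair hidden among 18 noise SNPs
xorBigData <- function() {
  fixture("xorBig", {
    base <- xor2Data(reps = 25L)  # 100 samples
    noise <- withr::with_seed(8,
      matrix(sample(0:2, 100 * 18, replace = TRUE), 100, 18))
    g <- cbind(genotypes(base), noise)
    colnames(g) <- paste0("snp", 1:20)
    GenotypeData(g, phenotype(base))
  })
}
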