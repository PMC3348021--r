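# Shared in-code fixtures for the test suite.

# Small named expression matrix from a numeric matrix.
namedMatrix <- function(values, n = nrow(values), m = ncol(values)) {
  dimnames(values) <- list(paste0("g", seq_len(n)), paste0("c", seq_len(m)))
  values
}

randomMatrix <- function(n, m) {
  namedMatrix(matrix(rnorm(n * m), n, m))
}

# Write a matrix as the TSV layout the readers expect.
writeMatrixTsv <- function(M, path, sep = "\t") {
  df <- cbind(gene = rownames(M), as.data.frame(M))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# The implanted-block recovery benchmark: one 30x8 rank-coherent block in
# a 300x25 background, with a seed bicluster overlapping 60% of the truth
# in both dimensions (18/30 genes, 5/8 conditions; dimensions preserved).
recoveryFixture <- function(seed = 42L) {
  sp <- syntheticSpec(300, 25,
                      biclusters = list(list(nGenes = 30, nConditions = 8,
                                             trend = "shift",
                                             noiseSd = 0.5)),
                      seed = seed)
  out <- generateSynthetic(sp)
  tr <- out$truth[[1L]]
  set.seed(seed)
  seedGenes <- c(sample(biclusterGenes(tr), 18),
                 sample(setdiff(seq_len(300), biclusterGenes(tr)), 12))
  seedConds <- c(sample(biclusterConditions(tr), 5),
                 sample(setdiff(seq_len(25), biclusterConditions(tr)), 3))
  list(matrix = out$matrix, truth = out$truth,
       init = bicluster(seedGenes, seedConds))
}

# Hand-built behavior matrix over 4 conditions (6 pair-columns) from an
# explicit trit matrix; used to stage exact move-operator scenarios.
handBehavior <- function(trits) {
  m <- 4L
  k <- rep.int(1:3, 3:1)
  q <- c(2:4, 3:4, 4L)
  storage.mode(trits) <- "integer"
  new("BehaviorMatrix", trits = trits,
      pairIndex = cbind(k = k, q = q),
      conditionIds = paste0("c", 1:m))
}
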