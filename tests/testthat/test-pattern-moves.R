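test_that("pattern takes per-column dominating values with the 1 > -1 > 0 tie-break", {
  trits <- rbind(c( 1,  1, -1,  1,  0,  1),
                 c( 1,  1, -1, -1,  0,  1),
                 c(-1,  1,  0,  1,  0, -1),
                 c( 0,  1, -1, -1,  1,  1))
  bm <- handBehavior(trits)
  cfg <- new("Configuration", genes = 1:4, pairColumns = 1:6,
             behavior = bm)
  p <- computePattern(cfg)
  # col 1: counts 1:2, -1:1, 0:1 -> 1 (0.5); col 4: 2 vs 2 tie -> 1;
  # col 5: 0 three times -> 0
  expect_equal(p@values, c(1L, 1L, -1L, 1L, 0L, 1L))
  expect_equal(p@dominance, c(0.5, 1, 0.75, 0.5, 0.75, 0.75))
  expect_true(all(p@dominance >= 1 / 3))
  # two-gene tie between 1 and -1 resolves to 1
  cfg2 <- new("Configuration", genes = 1:2, pairColumns = 4L,
              behavior = bm)
  expect_equal(computePattern(cfg2)@values, 1L)
  # tie between -1 and 0 resolves to -1
  cfg3 <- new("Configuration", genes = 3:4, pairColumns = 3L,
              behavior = bm)
  expect_equal(computePattern(cfg3)@values, -1L)
})

test_that("identical gene rows give their own pattern with full dominance", {
  trits <- matrix(rep(c(1L, -1L, 0L, 1L, -1L, 1L), each = 3), nrow = 3)
  bm <- handBehavior(trits)
  cfg <- new("Configuration", genes = 1:3, pairColumns = 1:6,
             behavior = bm)
  p <- computePattern(cfg)
  expect_equal(p@values, c(1L, -1L, 0L, 1L, -1L, 1L))
  expect_equal(p@dominance, rep(1, 6))
})

test_that("gene and column quality are concordance fractions", {
  p <- new("BiclusterPattern", values = c(1L, 1L, 1L, 0L, -1L, -1L),
           dominance = rep(1, 6))
  expect_equal(geneQuality(c(1L, 1L, 0L, 0L, -1L, 1L), p), 4 / 6)
  expect_equal(geneQuality(p@values, p), 1)
  expect_error(geneQuality(c(1L, 0L), p), "length mismatch")
  expect_equal(columnQuality(c(1L, 1L, -1L, 0L), 1L), 0.5)
  expect_equal(columnQuality(rep(-1L, 5), -1L), 1)
})

test_that("gene move drops low-quality genes and admits high-quality outsiders", {
  # Config genes 1-4 agree with the pattern except gene 4 (quality 3/6);
  # outside gene 5 matches on 5/6 columns (83%), gene 6 on 2/6.
  patternRow <- c(1L, 1L, -1L, 1L, 0L, 1L)
  trits <- rbind(patternRow, patternRow, patternRow,
                 c(1L, 1L, 1L, -1L, 1L, 1L),   # quality 3/6 = 50%
                 c(1L, 1L, -1L, 1L, 0L, -1L),  # quality 5/6 ~ 83%
                 c(-1L, -1L, -1L, -1L, 0L, -1L))
  bm <- handBehavior(trits)
  cfg <- new("Configuration", genes = 1:4, pairColumns = 1:6,
             behavior = bm)
  p <- computePattern(cfg)
  expect_equal(p@values, patternRow)
  expect_equal(geneQuality(trits[4, ], p), 0.5)
  expect_equal(geneQuality(trits[5, ], p), 5 / 6)
  res <- mvGene(cfg, p, alpha = 0.7)
  expect_equal(res$move@removed, 4L)
  expect_equal(res$move@added, 5L)
  expect_equal(biclusterGenes(res$config), c(1L, 2L, 3L, 5L))
  expect_equal(pairColumns(res$config), 1:6)  # columns untouched
})

test_that("gene move is the identity when every gene already qualifies", {
  trits <- matrix(rep(c(1L, -1L, 1L, 0L, -1L, 1L), each = 4), nrow = 4)
  bm <- handBehavior(trits)
  cfg <- new("Configuration", genes = 1:3, pairColumns = 1:6,
             behavior = bm)
  p <- computePattern(cfg)
  res <- mvGene(cfg, p, alpha = 0.7, maxAdd = 0)
  expect_length(res$move@removed, 0L)
  expect_length(res$move@added, 0L)
})

test_that("gene move rejects results with fewer than 2 genes", {
  trits <- rbind(c(1L, 1L, 1L, 1L, 1L, 1L),
                 c(-1L, -1L, -1L, 1L, 1L, 1L),
                 c(-1L, -1L, -1L, -1L, -1L, -1L))
  bm <- handBehavior(trits)
  cfg <- new("Configuration", genes = 1:2, pairColumns = 1:6,
             behavior = bm)
  p <- computePattern(cfg)
  res <- mvGene(cfg, p, alpha = 0.9, maxAdd = 0)
  expect_match(res$move@note, "fewer than 2 genes")
  expect_identical(res$config, cfg)
})

test_that("column move removes weakly dominated columns and adds strong ones", {
  # Column 2 of the configuration has dominance 0.5 (< beta); outside
  # column 5 is constant over the genes (dominance 1) and qualifies.
  trits <- rbind(c(1L,  1L, -1L, 0L, 1L, 0L),
                 c(1L, -1L, -1L, 0L, 1L, 1L),
                 c(1L,  1L, -1L, 1L, 1L, 0L),
                 c(1L, -1L, -1L, 1L, 1L, 1L))
  bm <- handBehavior(trits)
  cfg <- new("Configuration", genes = 1:4, pairColumns = 1:3,
             behavior = bm)
  p <- computePattern(cfg)
  expect_equal(p@dominance, c(1, 0.5, 1))
  res <- mvColumn(cfg, p, beta = 0.7)
  expect_equal(res$move@removed, 2L)
  expect_equal(res$move@added, 5L)
  expect_equal(pairColumns(res$config), c(1L, 3L, 5L))
  expect_equal(biclusterGenes(res$config), 1:4)  # genes untouched
})

test_that("column move is the identity when all columns dominate strongly", {
  trits <- matrix(rep(c(1L, -1L, 1L, 0L, -1L, 1L), each = 4), nrow = 4)
  bm <- handBehavior(trits)
  cfg <- new("Configuration", genes = 1:4, pairColumns = 1:6,
             behavior = bm)
  p <- computePattern(cfg)
  res <- mvColumn(cfg, p, beta = 0.7)
  expect_length(res$move@removed, 0L)
  expect_length(res$move@added, 0L)
})

test_that("move operators honor their thresholds on randomized configurations", {
  set.seed(30)
  for (rep in 1:100) {
    M <- randomMatrix(sample(8:20, 1), sample(4:8, 1))
    bm <- buildBehaviorMatrix(M)
    nPairs <- ncol(tritMatrix(bm))
    cfg <- new("Configuration",
               genes = sort(sample.int(nrow(M), sample(3:6, 1))),
               pairColumns = sort(sample.int(nPairs, sample(2:min(6, nPairs), 1))),
               behavior = bm)
    alpha <- runif(1, 0.4, 0.9)
    beta <- runif(1, 0.4, 0.9)
    p <- computePattern(cfg)

    g <- mvGene(cfg, p, alpha, maxAdd = Inf)
    if (!length(g$move@note)) {
      q <- sapply(biclusterGenes(g$config), function(i) {
        geneQuality(tritMatrix(bm)[i, pairColumns(g$config)], p)
      })
      expect_true(all(q >= alpha))
      expect_identical(pairColumns(g$config), pairColumns(cfg))
      expect_length(intersect(g$move@removed, g$move@added), 0L)
      # deterministic
      g2 <- mvGene(cfg, p, alpha, maxAdd = Inf)
      expect_identical(biclusterGenes(g2$config), biclusterGenes(g$config))
    }

    cmv <- mvColumn(cfg, p, beta)
    if (!length(cmv$move@note)) {
      dom <- sapply(pairColumns(cmv$config), function(j) {
        col <- tritMatrix(bm)[biclusterGenes(cfg), j]
        max(columnQuality(col, 1L), columnQuality(col, -1L),
            columnQuality(col, 0L))
      })
      expect_true(all(dom >= beta))
      expect_identical(biclusterGenes(cmv$config), biclusterGenes(cfg))
      expect_length(intersect(cmv$move@removed, cmv$move@added), 0L)
    }
  }
})
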