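test_that("behavior matrix encodes the up/down/no-change trichotomy", {
  M <- namedMatrix(rbind(c(5, 5, 5), c(1, 3, 2)))
  bm <- buildBehaviorMatrix(M)
  # pairs in lexicographic order: (c1,c2), (c1,c3), (c2,c3)
  expect_equal(unname(tritMatrix(bm)[1, ]), c(0L, 0L, 0L))
  expect_equal(unname(tritMatrix(bm)[2, ]), c(1L, 1L, -1L))
  expect_equal(colnames(tritMatrix(bm)), c("c1|c2", "c1|c3", "c2|c3"))
})

test_that("pair-column count is m(m-1)/2 with lexicographic index", {
  set.seed(10)
  for (m in c(3, 5, 8)) {
    bm <- buildBehaviorMatrix(randomMatrix(4, m))
    expect_equal(ncol(tritMatrix(bm)), m * (m - 1) / 2)
    pi <- pairIndex(bm)
    expect_true(all(pi[, 1] < pi[, 2]))
    key <- pi[, 1] * (m + 1) + pi[, 2]
    expect_false(is.unsorted(key, strictly = TRUE))
  }
})

test_that("negating the matrix negates the behavior matrix", {
  set.seed(11)
  for (rep in 1:20) {
    M <- randomMatrix(sample(2:8, 1), sample(3:7, 1))
    Mneg <- -M
    dimnames(Mneg) <- dimnames(M)
    expect_identical(tritMatrix(buildBehaviorMatrix(Mneg)),
                     -tritMatrix(buildBehaviorMatrix(M)))
  }
})

test_that("behavior matrix is invariant under strictly increasing transforms", {
  set.seed(12)
  transforms <- list(function(x) exp(x), function(x) x^3,
                     function(x) 2 * x + 10)
  for (rep in 1:20) {
    M <- randomMatrix(sample(2:8, 1), sample(3:7, 1))
    f <- transforms[[sample(3, 1)]]
    Mt <- f(M)
    dimnames(Mt) <- dimnames(M)
    expect_identical(tritMatrix(buildBehaviorMatrix(Mt)),
                     tritMatrix(buildBehaviorMatrix(M)))
  }
})

test_that("encoding selects exactly the within-bicluster pair-columns", {
  set.seed(13)
  M <- randomMatrix(6, 6)
  bm <- buildBehaviorMatrix(M)
  cfg2 <- encodeConfiguration(bicluster(1:3, 1:2), bm)
  expect_length(pairColumns(cfg2), 1L)
  cfg4 <- encodeConfiguration(bicluster(1:3, c(1, 2, 4, 6)), bm)
  expect_length(pairColumns(cfg4), 6L)
  cfgAll <- encodeConfiguration(bicluster(1:3, 1:6), bm)
  expect_equal(pairColumns(cfgAll), seq_len(ncol(tritMatrix(bm))))
  pi <- pairIndex(bm)[pairColumns(cfg4), ]
  expect_true(all(pi %in% c(1, 2, 4, 6)))
  expect_error(encodeConfiguration(bicluster(1:3, 2), bm),
               "degenerate")
})

test_that("decoding drops conditions combined with under half the others", {
  set.seed(14)
  bm <- buildBehaviorMatrix(randomMatrix(5, 4))
  # pair-columns 1..4 are (c1,c2), (c1,c3), (c1,c4), (c2,c3): c4 is paired
  # with only c1, below 50% of the other three conditions
  cfg <- new("Configuration", genes = 1:4, pairColumns = 1:4,
             behavior = bm)
  dec <- decodeConfiguration(cfg)
  expect_equal(biclusterConditions(dec), 1:3)
  expect_equal(biclusterGenes(dec), 1:4)
})

test_that("a complete pair set keeps every condition", {
  set.seed(15)
  bm <- buildBehaviorMatrix(randomMatrix(5, 6))
  cfg <- encodeConfiguration(bicluster(1:3, c(2, 3, 5)), bm)
  expect_equal(biclusterConditions(decodeConfiguration(cfg)), c(2L, 3L, 5L))
})

test_that("chain pair sets collapse to the inner conditions at fixpoint", {
  set.seed(16)
  bm <- buildBehaviorMatrix(randomMatrix(5, 4))
  # (c1,c2), (c2,c3), (c3,c4): ends below coverage, removed together;
  # the surviving pair (c2,c3) covers both remaining conditions fully
  cfg <- new("Configuration", genes = 1:3,
             pairColumns = c(1L, 4L, 6L), behavior = bm)
  expect_equal(biclusterConditions(decodeConfiguration(cfg)), c(2L, 3L))
})

test_that("decoding matches an independent fixpoint oracle on random pair sets", {
  # Oracle: adjacency-matrix formulation of the same rule — each round
  # drops every condition adjacent to < coverage of the other remaining
  # conditions, until stable.
  oracle <- function(pairs, coverage = 0.5) {
    sel <- sort(unique(as.integer(pairs)))
    repeat {
      if (length(sel) < 2L) return(NULL)
      A <- matrix(0L, max(sel), max(sel))
      keep <- pairs[, 1] %in% sel & pairs[, 2] %in% sel
      A[pairs[keep, , drop = FALSE]] <- 1L
      A <- A + t(A)
      deg <- rowSums(A)[sel]
      bad <- deg / (length(sel) - 1L) < coverage
      if (!any(bad)) return(sel)
      sel <- sel[!bad]
    }
  }
  set.seed(17)
  bm <- buildBehaviorMatrix(randomMatrix(4, 7))
  nPairs <- ncol(tritMatrix(bm))
  for (rep in 1:50) {
    cols <- sort(sample.int(nPairs, sample(2:8, 1)))
    cfg <- new("Configuration", genes = 1:3, pairColumns = cols,
               behavior = bm)
    expected <- oracle(pairIndex(bm)[cols, , drop = FALSE])
    if (is.null(expected)) {
      expect_error(decodeConfiguration(cfg), "degenerate")
    } else {
      expect_equal(biclusterConditions(decodeConfiguration(cfg)), expected)
    }
  }
})

test_that("decoding is idempotent", {
  set.seed(18)
  bm <- buildBehaviorMatrix(randomMatrix(5, 7))
  nPairs <- ncol(tritMatrix(bm))
  for (rep in 1:30) {
    cols <- sort(sample.int(nPairs, sample(3:10, 1)))
    cfg <- new("Configuration", genes = 1:4, pairColumns = cols,
               behavior = bm)
    dec <- tryCatch(decodeConfiguration(cfg), error = function(e) NULL)
    if (is.null(dec)) next
    endpoints <- sort(unique(as.integer(pairIndex(bm)[cols, ])))
    expect_true(all(biclusterConditions(dec) %in% endpoints))
    again <- decodeConfiguration(encodeConfiguration(dec, bm))
    expect_equal(biclusterConditions(again), biclusterConditions(dec))
    expect_equal(biclusterGenes(again), biclusterGenes(dec))
  }
})
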