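#' Cheng-Church-style greedy initializer (single node deletion)
#'
#' Starting from the full matrix, repeatedly deletes the row or column
#' with the largest mean squared-residue contribution until the MSR of the
#' remaining submatrix is at most \code{delta}.  This is the single-node
#' deletion core only — no multiple-node deletion, node addition, or
#' masking — which is sufficient to produce a reasonable-quality seed for
#' the PDNS search.  MSR is scale-sensitive: whether the input should be
#' log-transformed is left to the caller.
#'
#' @param M numeric expression matrix.
#' @param delta non-negative MSR target.
#' @return an unscored [Bicluster-class] with MSR <= delta.
#' @export
ccInitial <- function(M, delta) {
  validateExpressionMatrix(M)
  if (delta < 0) stop("delta must be >= 0")
  rows <- seq_len(nrow(M))
  cols <- seq_len(ncol(M))
  repeat {
    sub <- M[rows, cols, drop = FALSE]
    r2 <- .residues(sub)^2
    if (mean(r2) <= delta) break
    if (length(rows) <= 2L && length(cols) <= 2L)
      stop("cannot reach delta = ", delta,
           " before shrinking below 2x2; use a larger delta")
    rowContrib <- rowMeans(r2)
    colContrib <- colMeans(r2)
    bestRow <- if (length(rows) > 2L) max(rowContrib) else -Inf
    bestCol <- if (length(cols) > 2L) max(colContrib) else -Inf
    if (bestRow >= bestCol) {
      rows <- rows[-which.max(rowContrib)]
    } else {
      cols <- cols[-which.max(colContrib)]
    }
  }
  bicluster(rows, cols)
}

# Number of rows of M strictly increasing along the given condition order.
.orderSupport <- function(M, ord) {
  if (length(ord) < 2L) stop("order must have length >= 2")
  ok <- rep(TRUE, nrow(M))
  for (i in seq_len(length(ord) - 1L)) {
    ok <- ok & (M[, ord[i]] < M[, ord[i + 1L]])
  }
  sum(ok)
}

.orderSupporters <- function(M, ord) {
  ok <- rep(TRUE, nrow(M))
  for (i in seq_len(length(ord) - 1L)) {
    ok <- ok & (M[, ord[i]] < M[, ord[i + 1L]])
  }
  which(ok)
}

#' OPSM-style greedy initializer
#'
#' Greedily grows an ordering of \code{modelWidth} conditions maximizing
#' the number of genes whose expression is strictly increasing along the
#' ordering.  The seed is the best-supported ordered condition pair; each
#' growth step tries every remaining condition at every insertion
#' position, keeping the extension with the largest support (ties broken
#' by lowest condition index, then earliest position).  The returned
#' bicluster contains the supporting genes and the participating
#' conditions; the discovered ordering is attached as
#' \code{attr(, "conditionOrder")}.
#'
#' @param M numeric expression matrix.
#' @param modelWidth number of conditions in the ordering (2..m).
#' @return an unscored [Bicluster-class].
#' @export
opsmInitial <- function(M, modelWidth) {
  validateExpressionMatrix(M)
  m <- ncol(M)
  if (modelWidth < 2L || modelWidth > m)
    stop("modelWidth must be between 2 and the number of conditions")
  bestPair <- NULL
  bestSupp <- -1L
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a == b) next
      s <- sum(M[, a] < M[, b])
      if (s > bestSupp) {
        bestSupp <- s
        bestPair <- c(a, b)
      }
    }
  }
  if (bestSupp < 1L)
    stop("no gene supports any ordered condition pair")
  ord <- bestPair
  while (length(ord) < modelWidth) {
    bestExt <- NULL
    bestS <- -1L
    for (d in setdiff(seq_len(m), ord)) {
      for (p in 0:length(ord)) {
        cand <- append(ord, d, after = p)
        s <- .orderSupport(M, cand)
        if (s > bestS) {
          bestS <- s
          bestExt <- cand
        }
      }
    }
    ord <- bestExt
  }
  supporters <- .orderSupporters(M, ord)
  if (length(supporters) < 1L)
    stop("no gene supports the grown condition ordering")
  b <- bicluster(supporters, sort(ord))
  attr(b, "conditionOrder") <- ord
  b
}

#' Random initial bicluster
#'
#' Uniform sample of gene and condition indices without replacement,
#' drawn from the current R random number generator state (seed it for
#' reproducibility).
#'
#' @param M numeric expression matrix.
#' @param nGenes number of genes to sample (2..n).
#' @param nConditions number of conditions to sample (2..m).
#' @return an unscored [Bicluster-class].
#' @export
randomInitial <- function(M, nGenes, nConditions) {
  validateExpressionMatrix(M)
  if (nGenes < 2L || nGenes > nrow(M))
    stop("nGenes must be between 2 and the number of genes")
  if (nConditions < 2L || nConditions > ncol(M))
    stop("nConditions must be between 2 and the number of conditions")
  bicluster(sample.int(nrow(M), nGenes),
            sample.int(ncol(M), nConditions))
}
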