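#' Spearman rank correlation with average ranks
#'
#' Ranks both vectors with average (fractional) ranks for ties and
#' computes the Pearson correlation of the rank vectors from the explicit
#' sum formula.  If either vector has zero rank variance (all values
#' tied), the correlation is defined as 0: a flat profile carries no
#' evidence of association, and this convention keeps the ASR score
#' defined on flat rows and columns.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Spearman's rho in [-1, 1].
#' @examples
#' spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y))
    stop("degenerate input: vectors must have equal length")
  if (length(x) < 2L)
    stop("degenerate input: need length >= 2")
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx * dx)
  sy <- sum(dy * dy)
  if (sx == 0 || sy == 0) return(0)
  sum(dx * dy) / sqrt(sx * sy)
}

# Mean pairwise Spearman correlation among the rows of a matrix.
# Rows are rank-transformed, centered and normalized; zero-variance rows
# become zero vectors so every correlation involving them is 0, matching
# the spearmanRho convention.
.meanPairwiseRho <- function(mat) {
  n <- nrow(mat)
  if (n < 2L)
    stop("degenerate input: need at least 2 vectors")
  r <- t(apply(mat, 1L, rank))
  r <- r - rowMeans(r)
  ss <- sqrt(rowSums(r * r))
  nz <- ss > 0
  r[nz, ] <- r[nz, , drop = FALSE] / ss[nz]
  r[!nz, ] <- 0
  C <- tcrossprod(r)
  mean(C[upper.tri(C)])
}

# ASR over explicit index sets, without constructing a Bicluster.
.asrIndices <- function(M, genes, conditions) {
  if (length(genes) < 2L || length(conditions) < 2L)
    stop("degenerate bicluster: ASR needs >= 2 genes and >= 2 conditions")
  sub <- M[genes, conditions, drop = FALSE]
  rowTerm <- .meanPairwiseRho(sub)
  colTerm <- .meanPairwiseRho(t(sub))
  max(rowTerm, colTerm)
}

#' Average Spearman's Rho (ASR) of a bicluster
#'
#' ASR is the larger of (a) the average pairwise Spearman correlation
#' among the bicluster's gene rows restricted to its conditions and (b)
#' the average pairwise Spearman correlation among its condition columns
#' restricted to its genes.  Values lie in [-1, 1]; values near 1 indicate
#' strongly rank-coherent expression trajectories.  The score is computed
#' on the original expression values, not on the trinary behavior matrix,
#' and is therefore invariant under any strictly increasing transform of
#' the data.
#'
#' @param M numeric expression matrix.
#' @param b a [Bicluster-class] with >= 2 genes and >= 2 conditions.
#' @return ASR score in [-1, 1].
#' @examples
#' M <- rbind(g1 = 1:4, g2 = 2:5, g3 = 3:6)
#' colnames(M) <- paste0("c", 1:4)
#' asrScore(M, bicluster(1:3, 1:4))  # 1
#' @export
asrScore <- function(M, b) {
  .asrIndices(M, b@genes, b@conditions)
}

#' Mean squared residue (MSR) of a submatrix
#'
#' The Cheng-Church residue of cell (i, j) is
#' \eqn{a_{ij} - a_{iJ} - a_{Ij} + a_{IJ}} (cell minus row mean minus
#' column mean plus overall mean of the submatrix); the MSR is the mean of
#' the squared residues.  It is 0 exactly for additive submatrices and is
#' used by the Cheng-Church-style greedy initializer.
#'
#' @param M numeric expression matrix.
#' @param genes integer vector of row indices (non-empty).
#' @param conditions integer vector of column indices (non-empty).
#' @return non-negative MSR value.
#' @examples
#' M <- rbind(g1 = c(1, 2), g2 = c(2, 1))
#' colnames(M) <- c("c1", "c2")
#' msrScore(M, 1:2, 1:2)  # 0.25
#' @export
msrScore <- function(M, genes, conditions) {
  if (length(genes) < 1L || length(conditions) < 1L)
    stop("degenerate input: empty index set")
  sub <- M[genes, conditions, drop = FALSE]
  mean(.residues(sub)^2)
}

.residues <- function(sub) {
  sub - rowMeans(sub)[row(sub)] -
    rep(colMeans(sub), each = nrow(sub)) + mean(sub)
}
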