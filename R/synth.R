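#' Specify a synthetic expression matrix with implanted biclusters
#'
#' Each implanted block shares a condition trend (an evenly spaced ramp
#' over the member conditions) that every member gene carries after a
#' per-gene strictly monotone transform, plus i.i.d. Gaussian noise — so
#' the implanted structure is rank-coherent (trajectory-pattern coherent)
#' rather than constant-valued, which is the kind of signal a
#' trajectory-pattern search targets.  Trend types: \code{"shift"} adds a
#' per-gene offset, \code{"scale"} multiplies by a per-gene positive
#' factor, \code{"monotone"} applies an arbitrary per-gene strictly
#' increasing map.  With \code{noiseSd = 0} every member pair of genes has
#' Spearman correlation exactly 1 on the member conditions; the default
#' \code{noiseSd = 0.5} yields member-pair Spearman around 0.9 for blocks
#' of 8 conditions.
#'
#' @param nGenes,nConditions matrix dimensions.
#' @param biclusters list of block specifications, each a list with
#'   elements \code{nGenes}, \code{nConditions}, and optionally
#'   \code{trend} (default \code{"shift"}) and \code{noiseSd} (default
#'   0.5).
#' @param background \code{"normal"} for i.i.d. N(bgMean, bgSd) background
#'   or \code{"permuted"} to draw background cells from the empirical
#'   pool of implanted member values (preserving marginals).
#' @param bgMean,bgSd background Gaussian parameters.
#' @param allowOverlap permit blocks to overlap in genes/conditions
#'   (blocks are placed on disjoint index ranges otherwise).
#' @param seed integer seed; generation is bit-reproducible under it.
#' @return a named list usable by [generateSynthetic()].
#' @export
syntheticSpec <- function(nGenes, nConditions, biclusters = list(),
                          background = c("normal", "permuted"),
                          bgMean = 0, bgSd = 1, allowOverlap = FALSE,
                          seed = 0L) {
  background <- match.arg(background)
  biclusters <- lapply(biclusters, function(b) {
    b$trend <- if (is.null(b$trend)) "shift" else
      match.arg(b$trend, c("shift", "scale", "monotone"))
    if (is.null(b$noiseSd)) b$noiseSd <- 0.5
    if (b$noiseSd < 0) stop("noiseSd must be >= 0")
    if (is.null(b$nGenes) || is.null(b$nConditions))
      stop("each bicluster spec needs nGenes and nConditions")
    b$nGenes <- as.integer(b$nGenes)
    b$nConditions <- as.integer(b$nConditions)
    b
  })
  list(nGenes = as.integer(nGenes), nConditions = as.integer(nConditions),
       biclusters = biclusters, background = background,
       bgMean = bgMean, bgSd = bgSd, allowOverlap = allowOverlap,
       seed = as.integer(seed))
}

# One member gene's realization of the shared trend.
.applyTrend <- function(t, trend) {
  switch(trend,
    shift = t + stats::rnorm(1, 0, 1),
    scale = t * stats::rlnorm(1, 0, 0.25),
    monotone = sort(stats::rnorm(length(t)))[rank(t)]
  )
}

#' Generate a synthetic expression matrix with known implanted biclusters
#'
#' Blocks are implanted on disjoint gene/condition index ranges (unless
#' \code{allowOverlap}), then the rows and columns of the whole matrix are
#' shuffled; the returned ground truth carries the post-shuffle indices.
#' Gene ids \code{g1..gn} and condition ids \code{c1..cm} name the
#' shuffled positions.
#'
#' @param spec a specification from [syntheticSpec()].
#' @return list with \code{matrix} (the expression matrix) and
#'   \code{truth} (list of implanted [Bicluster-class] memberships).
#' @examples
#' sp <- syntheticSpec(60, 12,
#'                     biclusters = list(list(nGenes = 10, nConditions = 5,
#'                                            noiseSd = 0)),
#'                     seed = 7)
#' out <- generateSynthetic(sp)
#' asrScore(out$matrix, out$truth[[1]])  # 1 at zero noise
#' @export
generateSynthetic <- function(spec) {
  set.seed(spec$seed)
  n <- spec$nGenes
  m <- spec$nConditions
  need <- function(sizes, total, what) {
    if (sum(sizes) > total)
      stop("implanted blocks do not fit in the matrix (", what, ")")
  }
  if (!spec$allowOverlap && length(spec$biclusters)) {
    need(vapply(spec$biclusters, `[[`, integer(1), "nGenes"), n, "genes")
    need(vapply(spec$biclusters, `[[`, integer(1), "nConditions"), m,
         "conditions")
  }
  mat <- matrix(stats::rnorm(n * m, spec$bgMean, spec$bgSd), n, m)
  memberMask <- matrix(FALSE, n, m)
  truthPre <- list()
  gOff <- 0L
  cOff <- 0L
  for (b in spec$biclusters) {
    gIdx <- if (spec$allowOverlap) {
      .sampleFrom(seq_len(n), b$nGenes)
    } else {
      gOff + seq_len(b$nGenes)
    }
    cIdx <- if (spec$allowOverlap) {
      .sampleFrom(seq_len(m), b$nConditions)
    } else {
      cOff + seq_len(b$nConditions)
    }
    gOff <- gOff + if (spec$allowOverlap) 0L else b$nGenes
    cOff <- cOff + if (spec$allowOverlap) 0L else b$nConditions
    t <- seq(-2, 2, length.out = b$nConditions)
    for (g in gIdx) {
      mat[g, cIdx] <- .applyTrend(t, b$trend) +
        stats::rnorm(b$nConditions, 0, b$noiseSd)
    }
    memberMask[gIdx, cIdx] <- TRUE
    truthPre[[length(truthPre) + 1L]] <- list(genes = gIdx, conds = cIdx)
  }
  if (spec$background == "permuted" && any(memberMask)) {
    bg <- !memberMask
    mat[bg] <- sample(mat[memberMask], sum(bg), replace = TRUE)
  }
  rowPerm <- sample.int(n)
  colPerm <- sample.int(m)
  mat <- mat[rowPerm, colPerm, drop = FALSE]
  dimnames(mat) <- list(paste0("g", seq_len(n)), paste0("c", seq_len(m)))
  # position of original index i after the permutation
  rowPos <- order(rowPerm)
  colPos <- order(colPerm)
  truth <- lapply(truthPre, function(tp) {
    bicluster(rowPos[tp$genes], colPos[tp$conds])
  })
  list(matrix = validateExpressionMatrix(mat), truth = truth)
}

.cellKeys <- function(b, m) {
  as.vector(outer(b@genes, b@conditions, function(g, cc) (g - 1L) * m + cc))
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Match recovered biclusters against ground truth
#'
#' Pairs found and true biclusters greedily by descending cell-level
#' Jaccard (each found bicluster used at most once), then reports the
#' cell, gene and condition Jaccard indices of each true bicluster's
#' match, plus their averages over the true biclusters (unmatched truths
#' score 0).
#'
#' @param found list of recovered [Bicluster-class] objects.
#' @param truth list of implanted [Bicluster-class] objects.
#' @param M the expression matrix (its dimensions define the cell grid).
#' @return list with \code{cellJaccard}, \code{geneJaccard},
#'   \code{conditionJaccard} (averages over truths) and \code{table}
#'   (per-truth best-match data.frame).
#' @export
matchScore <- function(found, truth, M) {
  m <- ncol(M)
  pairScores <- matrix(0, nrow = length(truth), ncol = length(found))
  for (i in seq_along(truth)) {
    for (j in seq_along(found)) {
      pairScores[i, j] <- .jaccard(.cellKeys(truth[[i]], m),
                                   .cellKeys(found[[j]], m))
    }
  }
  matchOf <- rep(NA_integer_, length(truth))
  usedF <- logical(length(found))
  ps <- pairScores
  repeat {
    if (!length(ps) || all(ps <= 0 | is.na(ps))) break
    ij <- which(ps == max(ps, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    matchOf[ij[1L]] <- ij[2L]
    ps[ij[1L], ] <- NA
    ps[, ij[2L]] <- NA
    usedF[ij[2L]] <- TRUE
    if (all(!is.na(matchOf)) || all(usedF)) break
  }
  rows <- lapply(seq_along(truth), function(i) {
    j <- matchOf[i]
    if (is.na(j)) {
      data.frame(truth = i, found = NA_integer_, cellJaccard = 0,
                 geneJaccard = 0, conditionJaccard = 0)
    } else {
      data.frame(truth = i, found = j,
                 cellJaccard = pairScores[i, j],
                 geneJaccard = .jaccard(truth[[i]]@genes, found[[j]]@genes),
                 conditionJaccard = .jaccard(truth[[i]]@conditions,
                                             found[[j]]@conditions))
    }
  })
  tab <- do.call(rbind, rows)
  list(cellJaccard = mean(tab$cellJaccard),
       geneJaccard = mean(tab$geneJaccard),
       conditionJaccard = mean(tab$conditionJaccard),
       table = tab)
}
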