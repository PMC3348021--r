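#' Build the trinary behavior matrix of an expression matrix
#'
#' For every unordered pair of conditions (k, q) with k < q (taken in
#' lexicographic order) and every gene i, the behavior matrix records 1
#' when expression rises (M[i, k] < M[i, q]), -1 when it falls, and 0 when
#' the two stored values are exactly equal.  The comparison is exact — no
#' tolerance — so ties arise only from identical stored values.  Rows of
#' the result are the up/down/no-change trajectory patterns of the genes
#' across all combined condition pairs.
#'
#' @param M validated numeric expression matrix (genes x conditions).
#' @return a [BehaviorMatrix-class] with m(m-1)/2 pair-columns.
#' @examples
#' M <- matrix(c(1, 3, 2, 5, 5, 5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' tritMatrix(buildBehaviorMatrix(M))
#' @export
buildBehaviorMatrix <- function(M) {
  validateExpressionMatrix(M)
  m <- ncol(M)
  k <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  q <- unlist(lapply(seq_len(m - 1L), function(i) (i + 1L):m))
  trits <- matrix(as.integer(sign(M[, q, drop = FALSE] -
                                  M[, k, drop = FALSE])),
                  nrow = nrow(M))
  dimnames(trits) <- list(rownames(M),
                          paste(colnames(M)[k], colnames(M)[q], sep = "|"))
  new("BehaviorMatrix",
      trits = trits,
      pairIndex = cbind(k = as.integer(k), q = as.integer(q)),
      conditionIds = colnames(M))
}

#' Encode a bicluster as a search configuration
#'
#' The configuration keeps the bicluster's gene set and selects every
#' behavior-matrix pair-column whose two endpoint conditions both belong
#' to the bicluster, so |K| = |J'|(|J'|-1)/2.
#'
#' @param b a [Bicluster-class] with at least 2 conditions.
#' @param bm the [BehaviorMatrix-class] of the full expression matrix.
#' @return a [Configuration-class]
#' @export
encodeConfiguration <- function(b, bm) {
  if (length(b@conditions) < 2L)
    stop("degenerate bicluster: need at least 2 conditions to encode")
  if (length(b@genes) < 1L)
    stop("degenerate bicluster: need at least 1 gene to encode")
  inJ <- bm@pairIndex[, 1L] %in% b@conditions &
         bm@pairIndex[, 2L] %in% b@conditions
  new("Configuration",
      genes = b@genes,
      pairColumns = which(inJ),
      behavior = bm)
}

#' Decode a configuration into a bicluster
#'
#' The selected conditions are the union of the endpoints of the
#' configuration's pair-columns.  A condition is only meaningful for the
#' bicluster if it is combined with at least \code{coverage} (default 50%)
#' of the other selected conditions; each round removes every condition
#' below that coverage (coverages evaluated at the start of the round),
#' restricts the surviving pairs accordingly, and repeats until a
#' fixpoint is reached.  Genes pass through unchanged.  Removing the
#' whole below-coverage set per round keeps the result independent of any
#' within-round removal order.
#'
#' @param config a [Configuration-class].
#' @param coverage minimum fraction of the other selected conditions a
#'   condition must be paired with (comparison is \code{>=}).
#' @return an unscored [Bicluster-class]
#' @examples
#' M <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
#' bm <- buildBehaviorMatrix(M)
#' cfg <- encodeConfiguration(bicluster(1:4, 1:3), bm)
#' decodeConfiguration(cfg)
#' @export
decodeConfiguration <- function(config, coverage = 0.5) {
  if (length(config@pairColumns) < 1L)
    stop("degenerate configuration: no pair-columns to decode")
  pairs <- config@behavior@pairIndex[config@pairColumns, , drop = FALSE]
  sel <- sort(unique(as.integer(pairs)))
  repeat {
    if (length(sel) < 2L)
      stop("degenerate result: fewer than 2 conditions survive decoding")
    live <- pairs[pairs[, 1L] %in% sel & pairs[, 2L] %in% sel, ,
                  drop = FALSE]
    deg <- vapply(sel, function(cc) {
      sum(live[, 1L] == cc | live[, 2L] == cc)
    }, integer(1))
    frac <- deg / (length(sel) - 1L)
    below <- frac < coverage
    if (!any(below)) break
    sel <- sel[!below]
  }
  bicluster(config@genes, sel)
}
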