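# Dominating trit and dominance frequency per column of a trit submatrix.
# Tie-break priority is 1 > -1 > 0: a trend (up, then down) wins over
# "no change", and any fixed rule keeps the operators deterministic.
.dominate <- function(sub) {
  nr <- nrow(sub)
  cUp <- colSums(sub == 1L)
  cDn <- colSums(sub == -1L)
  cZe <- nr - cUp - cDn
  val <- ifelse(cUp >= cDn & cUp >= cZe, 1L, ifelse(cDn >= cZe, -1L, 0L))
  list(values = as.integer(val), dominance = pmax(cUp, cDn, cZe) / nr)
}

#' Bicluster pattern of a configuration
#'
#' For each pair-column of the configuration, the pattern takes the
#' dominating value — the trit in {1, 0, -1} with the highest count among
#' the configuration's genes — together with its frequency.  Ties are
#' broken by the fixed priority 1 > -1 > 0.
#'
#' @param config a [Configuration-class].
#' @return a [BiclusterPattern-class]; \code{values} and \code{dominance}
#'   are parallel to \code{pairColumns(config)}.
#' @export
computePattern <- function(config) {
  sub <- config@behavior@trits[config@genes, config@pairColumns,
                               drop = FALSE]
  d <- .dominate(sub)
  new("BiclusterPattern", values = d$values, dominance = d$dominance)
}

#' Quality of a gene row against a bicluster pattern
#'
#' The fraction of pair-columns where the gene's trinary trajectory agrees
#' with the pattern's dominating value.
#'
#' @param geneRow integer trit vector (the gene's behavior restricted to
#'   the configuration's pair-columns).
#' @param pattern a [BiclusterPattern-class] of the same length.
#' @return concordance fraction in [0, 1].
#' @export
geneQuality <- function(geneRow, pattern) {
  if (length(geneRow) != length(pattern@values))
    stop("length mismatch between gene row and pattern")
  mean(geneRow == pattern@values)
}

#' Quality of a pair-column against a pattern value
#'
#' The fraction of genes whose trit in the column equals the reference
#' value.  When the reference is the column's own dominating value this is
#' exactly the dominance frequency.
#'
#' @param column integer trit vector (one pair-column over a gene set).
#' @param patternValue a single trit in {-1, 0, 1}.
#' @return concordance fraction in [0, 1].
#' @export
columnQuality <- function(column, patternValue) {
  if (length(column) < 1L) stop("empty column")
  mean(column == patternValue)
}

# Quality of each listed gene (rows of the full behavior matrix) against
# the pattern, over the configuration's pair-columns.
.geneQualities <- function(bm, geneIdx, pairCols, patternValues) {
  sub <- bm@trits[geneIdx, pairCols, drop = FALSE]
  rowMeans(sub == matrix(patternValues, nrow = length(geneIdx),
                         ncol = length(pairCols), byrow = TRUE))
}

#' Gene move operator
#'
#' Removes from the configuration every gene whose quality against the
#' pre-move pattern falls below \code{alpha}, and adds genes from outside
#' the configuration whose quality (on the same pair-columns) reaches
#' \code{alpha} — highest quality first, ties by lowest gene index, up to
#' \code{maxAdd}.  All bad genes are removed, but only a limited number of
#' good ones are admitted per move: by default as many as were removed.
#' An uncapped addition step can absorb, in a single move, every outside
#' gene whose quality clears the threshold by chance; the pattern of the
#' enlarged configuration then reflects the absorbed genes and confirms
#' them, leaving the descent unable to expel them later.  The
#' symmetric-by-default cap keeps each move incremental (set \code{maxAdd
#' = Inf} to lift it).  The pair-columns are never changed.  If the
#' result would contain fewer than 2 genes the move is rejected and the
#' input configuration is returned with an explanatory note.
#'
#' @param config a [Configuration-class].
#' @param pattern the [BiclusterPattern-class] computed from \code{config}.
#' @param alpha gene quality threshold in (0, 1].
#' @param maxAdd cap on the number of genes added; \code{NA} (default)
#'   means "number of genes removed in this move".
#' @return list with elements \code{config} (the new or unchanged
#'   [Configuration-class]) and \code{move} (a [MoveResult-class]).
#' @export
mvGene <- function(config, pattern, alpha, maxAdd = NA) {
  bm <- config@behavior
  qIn <- .geneQualities(bm, config@genes, config@pairColumns,
                        pattern@values)
  bad <- config@genes[qIn < alpha]
  if (is.na(maxAdd)) maxAdd <- length(bad)
  outside <- setdiff(seq_len(nrow(bm@trits)), config@genes)
  added <- integer(0)
  if (length(outside) && maxAdd > 0) {
    qOut <- .geneQualities(bm, outside, config@pairColumns,
                           pattern@values)
    good <- outside[qOut >= alpha]
    if (length(good)) {
      good <- good[order(-qOut[qOut >= alpha], good)]
      added <- good[seq_len(min(length(good), maxAdd))]
    }
  }
  newGenes <- sort(c(setdiff(config@genes, bad), added))
  if (length(newGenes) < 2L) {
    return(list(
      config = config,
      move = new("MoveResult", removed = integer(0), added = integer(0),
                 kind = "gene",
                 note = "rejected: result would have fewer than 2 genes")
    ))
  }
  list(
    config = new("Configuration", genes = newGenes,
                 pairColumns = config@pairColumns, behavior = bm),
    move = new("MoveResult", removed = as.integer(bad),
               added = as.integer(added), kind = "gene")
  )
}

# Dominance frequency of each listed pair-column over a gene set.
.columnDominance <- function(bm, geneIdx, colIdx) {
  sub <- bm@trits[geneIdx, colIdx, drop = FALSE]
  .dominate(sub)$dominance
}

#' Column move operator
#'
#' Removes every pair-column whose dominance frequency over the
#' configuration's genes falls below \code{beta}, and adds pair-columns
#' from the rest of the behavior matrix whose dominance over the same gene
#' set reaches \code{beta} — highest dominance first, ties by lowest
#' column index, up to \code{maxAdd} (by default, as many as were removed
#' in this move, so repeated applications cannot balloon toward all
#' m(m-1)/2 columns).  The genes are never changed.  If the result would
#' contain no column the move is rejected and the input configuration is
#' returned with an explanatory note.
#'
#' @param config a [Configuration-class].
#' @param pattern the [BiclusterPattern-class] computed from \code{config}
#'   (its dominance frequencies drive the removals).
#' @param beta column quality threshold in (0, 1].
#' @param maxAdd cap on the number of columns added; \code{NA} (default)
#'   means "number of columns removed in this move".
#' @return list with elements \code{config} and \code{move}, as [mvGene()].
#' @export
mvColumn <- function(config, pattern, beta, maxAdd = NA) {
  bm <- config@behavior
  bad <- config@pairColumns[pattern@dominance < beta]
  if (is.na(maxAdd)) maxAdd <- length(bad)
  candidates <- setdiff(seq_len(ncol(bm@trits)), config@pairColumns)
  added <- integer(0)
  if (length(candidates) && maxAdd > 0) {
    dom <- .columnDominance(bm, config@genes, candidates)
    good <- candidates[dom >= beta]
    if (length(good)) {
      good <- good[order(-dom[dom >= beta], good)]
      added <- good[seq_len(min(length(good), maxAdd))]
    }
  }
  newCols <- sort(c(setdiff(config@pairColumns, bad), added))
  if (length(newCols) < 1L) {
    return(list(
      config = config,
      move = new("MoveResult", removed = integer(0), added = integer(0),
                 kind = "column",
                 note = "rejected: result would have no pair-column")
    ))
  }
  list(
    config = new("Configuration", genes = config@genes,
                 pairColumns = newCols, behavior = bm),
    move = new("MoveResult", removed = as.integer(bad),
               added = as.integer(added), kind = "column")
  )
}
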