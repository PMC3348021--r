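#' @import methods
NULL

#' Trinary behavior matrix of an expression matrix
#'
#' The behavior matrix recodes an n x m expression matrix into an
#' n x m(m-1)/2 trinary matrix: for every unordered pair of conditions
#' (k, q) with k < q there is one column whose entry for gene i is 1 if
#' expression rises from k to q, -1 if it falls, and 0 if it is exactly
#' equal.  Rows are gene trajectory patterns over all combined condition
#' pairs; the column order is lexicographic in (k, q).
#'
#' @slot trits integer matrix with entries in {-1, 0, 1}; one row per gene,
#'   one column per unordered condition pair.
#' @slot pairIndex integer matrix with two columns (k, q), k < q, one row
#'   per column of \code{trits}, in strictly increasing lexicographic order.
#' @slot conditionIds character vector of the m condition identifiers of
#'   the source matrix.
#'
#' @seealso [buildBehaviorMatrix()]
#' @export
setClass("BehaviorMatrix",
  representation(
    trits = "matrix",
    pairIndex = "matrix",
    conditionIds = "character"
  )
)

setValidity("BehaviorMatrix", function(object) {
  msg <- character(0)
  m <- length(object@conditionIds)
  if (ncol(object@trits) != m * (m - 1) / 2)
    msg <- c(msg, "trits must have m(m-1)/2 columns")
  if (!all(object@trits %in% c(-1L, 0L, 1L)))
    msg <- c(msg, "trits entries must be in {-1, 0, 1}")
  pi <- object@pairIndex
  if (ncol(pi) != 2L || nrow(pi) != ncol(object@trits))
    msg <- c(msg, "pairIndex must have one (k, q) row per trits column")
  if (nrow(pi) > 0) {
    if (any(pi[, 1] >= pi[, 2]))
      msg <- c(msg, "pairIndex rows must satisfy k < q")
    key <- pi[, 1] * (m + 1) + pi[, 2]
    if (is.unsorted(key, strictly = TRUE))
      msg <- c(msg, "pairIndex must be strictly lexicographically increasing")
  }
  if (length(msg)) msg else TRUE
})

#' A bicluster: a gene subset crossed with a condition subset
#'
#' Indices are 1-based positions into the expression matrix the bicluster
#' was derived from.  The ASR score slot is \code{NA_real_} until the
#' bicluster has been scored; a scored bicluster must have at least two
#' genes and two conditions.
#'
#' @slot genes integer vector of gene row indices (sorted, unique).
#' @slot conditions integer vector of condition column indices (sorted,
#'   unique).
#' @slot asr numeric scalar in [-1, 1], or \code{NA_real_} when unscored.
#'
#' @seealso [asrScore()], [decodeConfiguration()]
#' @export
setClass("Bicluster",
  representation(
    genes = "integer",
    conditions = "integer",
    asr = "numeric"
  ),
  prototype(asr = NA_real_)
)

setValidity("Bicluster", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@genes) || is.unsorted(object@genes))
    msg <- c(msg, "genes must be sorted and unique")
  if (anyDuplicated(object@conditions) || is.unsorted(object@conditions))
    msg <- c(msg, "conditions must be sorted and unique")
  if (length(object@genes) && min(object@genes) < 1L)
    msg <- c(msg, "gene indices must be >= 1")
  if (length(object@conditions) && min(object@conditions) < 1L)
    msg <- c(msg, "condition indices must be >= 1")
  if (length(object@asr) != 1L)
    msg <- c(msg, "asr must be a scalar")
  if (!is.na(object@asr)) {
    if (object@asr < -1 || object@asr > 1)
      msg <- c(msg, "asr must lie in [-1, 1]")
    if (length(object@genes) < 2L || length(object@conditions) < 2L)
      msg <- c(msg, "a scored bicluster needs >= 2 genes and >= 2 conditions")
  }
  if (length(msg)) msg else TRUE
})

#' Search configuration: gene subset plus behavior-matrix pair-columns
#'
#' The search state of PDNS encodes a bicluster as its gene set I' together
#' with a set K of pair-columns of the behavior matrix.  When freshly
#' encoded from a bicluster, K contains every pair with both endpoints in
#' the bicluster's condition set (|K| = |J'|(|J'|-1)/2); after move
#' operators have acted, K may be any non-empty subset of the pair-columns.
#'
#' @slot genes integer vector of gene row indices (sorted, unique).
#' @slot pairColumns integer vector of column indices into the backing
#'   behavior matrix (sorted, unique, non-empty).
#' @slot behavior the backing [BehaviorMatrix-class].
#'
#' @seealso [encodeConfiguration()], [decodeConfiguration()]
#' @export
setClass("Configuration",
  representation(
    genes = "integer",
    pairColumns = "integer",
    behavior = "BehaviorMatrix"
  )
)

setValidity("Configuration", function(object) {
  msg <- character(0)
  if (length(object@genes) < 1L)
    msg <- c(msg, "configuration needs at least one gene")
  if (length(object@pairColumns) < 1L)
    msg <- c(msg, "configuration needs at least one pair-column")
  if (anyDuplicated(object@genes) || is.unsorted(object@genes))
    msg <- c(msg, "genes must be sorted and unique")
  if (anyDuplicated(object@pairColumns) || is.unsorted(object@pairColumns))
    msg <- c(msg, "pairColumns must be sorted and unique")
  if (length(object@genes) &&
      max(object@genes) > nrow(object@behavior@trits))
    msg <- c(msg, "gene index out of range of the behavior matrix")
  if (length(object@pairColumns) &&
      max(object@pairColumns) > ncol(object@behavior@trits))
    msg <- c(msg, "pair-column index out of range of the behavior matrix")
  if (length(msg)) msg else TRUE
})

#' Per-column dominating trinary pattern of a configuration
#'
#' For each pair-column of a configuration, the pattern holds the trinary
#' value occurring most often among the configuration's genes (ties broken
#' by the fixed priority 1 > -1 > 0) and the frequency of that value.
#' With three symbols the dominance frequency is always at least 1/3.
#'
#' @slot values integer vector in {-1, 0, 1}, one per pair-column.
#' @slot dominance numeric vector of dominance frequencies in [1/3, 1].
#'
#' @seealso [computePattern()]
#' @export
setClass("BiclusterPattern",
  representation(values = "integer", dominance = "numeric")
)

setValidity("BiclusterPattern", function(object) {
  msg <- character(0)
  if (length(object@values) != length(object@dominance))
    msg <- c(msg, "values and dominance must have equal length")
  if (!all(object@values %in% c(-1L, 0L, 1L)))
    msg <- c(msg, "pattern values must be in {-1, 0, 1}")
  if (length(object@dominance) &&
      (any(object@dominance < 1 / 3 - 1e-12) || any(object@dominance > 1)))
    msg <- c(msg, "dominance frequencies must lie in [1/3, 1]")
  if (length(msg)) msg else TRUE
})

#' Outcome of a move operator application
#'
#' @slot removed integer indices removed from the configuration (gene rows
#'   for a gene move, pair-columns for a column move).
#' @slot added integer indices added.
#' @slot kind `"gene"` or `"column"`.
#' @slot note free-text note; non-empty when the move was rejected as a
#'   no-op (for example because it would leave fewer than two genes).
#'
#' @seealso [mvGene()], [mvColumn()]
#' @export
setClass("MoveResult",
  representation(
    removed = "integer",
    added = "integer",
    kind = "character",
    note = "character"
  ),
  prototype(note = character(0))
)

setValidity("MoveResult", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("gene", "column"))
    msg <- c(msg, "kind must be 'gene' or 'column'")
  if (length(intersect(object@removed, object@added)))
    msg <- c(msg, "removed and added sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Tuning parameters of the PDNS search
#'
#' @slot alpha gene quality threshold in (0, 1]: a configuration gene whose
#'   concordance with the bicluster pattern falls below \code{alpha} is
#'   dropped by the gene move.
#' @slot beta column quality threshold in (0, 1], the analogue for
#'   pair-columns.
#' @slot asrThreshold ASR level in [-1, 1] at which a descent stops early.
#' @slot maxDescentIters maximum accepted-or-attempted iterations per
#'   descent (Y).
#' @slot maxStagnantPerturbations number of consecutive perturbation cycles
#'   without improvement of the best bicluster after which the search
#'   terminates (Z).
#' @slot perturbFraction fraction of genes and of conditions replaced by a
#'   perturbation (default 0.10).
#' @slot decodeCoverage decoding coverage fraction (default 0.50): a
#'   condition is retained only if it is paired with at least this fraction
#'   of the other selected conditions.
#' @slot maxAddGenes cap on genes added per gene move; \code{NA} means
#'   "as many as were removed in the same move" (\code{Inf} = unbounded).
#' @slot maxAddColumns cap on columns added per column move; \code{NA}
#'   means "as many as were removed in the same move".
#' @slot operatorOrder order in which the two move operators are tried
#'   within a descent iteration.
#' @slot seed integer seed making the whole run reproducible.
#'
#' @seealso [pdnsParams()], [pdnsRun()]
#' @export
setClass("PDNSParams",
  representation(
    alpha = "numeric",
    beta = "numeric",
    asrThreshold = "numeric",
    maxDescentIters = "integer",
    maxStagnantPerturbations = "integer",
    perturbFraction = "numeric",
    decodeCoverage = "numeric",
    maxAddGenes = "numeric",
    maxAddColumns = "numeric",
    operatorOrder = "character",
    seed = "integer"
  )
)

setValidity("PDNSParams", function(object) {
  msg <- character(0)
  inUnit <- function(x) length(x) == 1L && !is.na(x) && x > 0 && x <= 1
  if (!inUnit(object@alpha)) msg <- c(msg, "alpha must be in (0, 1]")
  if (!inUnit(object@beta)) msg <- c(msg, "beta must be in (0, 1]")
  if (!inUnit(object@perturbFraction))
    msg <- c(msg, "perturbFraction must be in (0, 1]")
  if (!inUnit(object@decodeCoverage))
    msg <- c(msg, "decodeCoverage must be in (0, 1]")
  if (length(object@asrThreshold) != 1L || is.na(object@asrThreshold) ||
      object@asrThreshold < -1 || object@asrThreshold > 1)
    msg <- c(msg, "asrThreshold must be in [-1, 1]")
  if (object@maxDescentIters < 1L)
    msg <- c(msg, "maxDescentIters (Y) must be >= 1")
  if (object@maxStagnantPerturbations < 1L)
    msg <- c(msg, "maxStagnantPerturbations (Z) must be >= 1")
  if (!is.na(object@maxAddGenes) && object@maxAddGenes < 0)
    msg <- c(msg, "maxAddGenes must be >= 0 or NA")
  if (!is.na(object@maxAddColumns) && object@maxAddColumns < 0)
    msg <- c(msg, "maxAddColumns must be >= 0 or NA")
  if (!identical(sort(object@operatorOrder), c("column", "gene")))
    msg <- c(msg, "operatorOrder must be a permutation of c('gene', 'column')")
  if (length(msg)) msg else TRUE
})

#' Result of a PDNS run
#'
#' @slot bicluster the best decoded [Bicluster-class], with its ASR score.
#' @slot trace data.frame of accepted moves: cycle, iteration, operator,
#'   ASR before/after, and configuration sizes.
#' @slot bestAsrHistory numeric vector of the best decoded ASR after each
#'   perturbation cycle (cycle 0 is the initial descent).
#' @slot params the [PDNSParams-class] used.
#'
#' @seealso [pdnsRun()]
#' @export
setClass("PDNSResult",
  representation(
    bicluster = "Bicluster",
    trace = "data.frame",
    bestAsrHistory = "numeric",
    params = "PDNSParams"
  )
)
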