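#' Construct PDNS search parameters
#'
#' Defaults follow the settings used for the Saccharomyces cerevisiae
#' benchmark of the method: alpha = 0.8, beta = 0.8, ASR threshold 0.7,
#' Y = 100 descent iterations, Z = 50 stagnant perturbations, 10%
#' perturbation, 50% decoding coverage.  For noisier data lower
#' thresholds (for example alpha = 0.5, beta = 0.7, ASR threshold 0.5)
#' are appropriate.
#'
#' @param alpha gene quality threshold in (0, 1].
#' @param beta column quality threshold in (0, 1].
#' @param asrThreshold ASR level in [-1, 1] at which a descent stops.
#' @param Y maximum iterations per descent.
#' @param Z consecutive perturbation cycles without improvement before the
#'   search stops.
#' @param perturbFraction fraction of genes/conditions replaced per
#'   perturbation.
#' @param decodeCoverage decoding coverage fraction.
#' @param maxAddGenes cap on genes added per gene move (NA = as many as
#'   removed in the same move, Inf = unbounded).
#' @param maxAddColumns cap on columns added per column move (NA = as many
#'   as removed in the same move).
#' @param operatorOrder order of move operators within a descent
#'   iteration.
#' @param seed integer seed for all randomized steps of the run.
#' @return a validated [PDNSParams-class]
#' @export
pdnsParams <- function(alpha = 0.8, beta = 0.8, asrThreshold = 0.7,
                       Y = 100L, Z = 50L,
                       perturbFraction = 0.10, decodeCoverage = 0.50,
                       maxAddGenes = NA, maxAddColumns = NA,
                       operatorOrder = c("gene", "column"),
                       seed = 0L) {
  new("PDNSParams",
      alpha = alpha, beta = beta, asrThreshold = asrThreshold,
      maxDescentIters = as.integer(Y),
      maxStagnantPerturbations = as.integer(Z),
      perturbFraction = perturbFraction,
      decodeCoverage = decodeCoverage,
      maxAddGenes = as.numeric(maxAddGenes),
      maxAddColumns = as.numeric(maxAddColumns),
      operatorOrder = operatorOrder,
      seed = as.integer(seed))
}

# ASR of a configuration during search: genes crossed with the union of
# the pair-column endpoints.  The 50% coverage filter is applied only at
# decoding time, not while searching.
.configAsr <- function(M, config) {
  pairs <- config@behavior@pairIndex[config@pairColumns, , drop = FALSE]
  conds <- sort(unique(as.integer(pairs)))
  .asrIndices(M, config@genes, conds)
}

.emptyTrace <- function() {
  data.frame(cycle = integer(0), iteration = integer(0),
             operator = character(0), asrBefore = numeric(0),
             asrAfter = numeric(0), nGenes = integer(0),
             nPairColumns = integer(0), stringsAsFactors = FALSE)
}

#' Descent phase of the PDNS search
#'
#' Repeats for at most Y iterations: compute the bicluster pattern of the
#' current configuration, then try the move operators in
#' \code{operatorOrder} (gene move first by default).  A move is accepted
#' only if the ASR of the resulting configuration — genes crossed with the
#' union of its pair-column endpoints — strictly increases.  The descent
#' stops as soon as the ASR reaches \code{asrThreshold}, when neither
#' operator yields an improvement (a local optimum), or when Y iterations
#' have been used.
#'
#' @param config starting [Configuration-class] (>= 2 genes).
#' @param M the expression matrix.
#' @param params a [PDNSParams-class].
#' @param cycle cycle label recorded in the trace.
#' @return list with \code{config} (final configuration), \code{asr} (its
#'   search ASR) and \code{trace} (data.frame of accepted moves).
#' @export
descend <- function(config, M, params, cycle = 0L) {
  if (length(config@genes) < 2L)
    stop("degenerate configuration: descent needs >= 2 genes")
  trace <- .emptyTrace()
  currentAsr <- .configAsr(M, config)
  iter <- 0L
  while (iter < params@maxDescentIters &&
         currentAsr < params@asrThreshold) {
    iter <- iter + 1L
    pattern <- computePattern(config)
    accepted <- FALSE
    for (op in params@operatorOrder) {
      cand <- if (op == "gene") {
        mvGene(config, pattern, params@alpha, params@maxAddGenes)
      } else {
        mvColumn(config, pattern, params@beta, params@maxAddColumns)
      }
      if (length(cand$move@note) ||
          (!length(cand$move@removed) && !length(cand$move@added)))
        next
      candAsr <- .configAsr(M, cand$config)
      if (candAsr > currentAsr) {
        trace <- rbind(trace, data.frame(
          cycle = cycle, iteration = iter, operator = op,
          asrBefore = currentAsr, asrAfter = candAsr,
          nGenes = length(cand$config@genes),
          nPairColumns = length(cand$config@pairColumns),
          stringsAsFactors = FALSE))
        config <- cand$config
        currentAsr <- candAsr
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  list(config = config, asr = currentAsr, trace = trace)
}

.sampleFrom <- function(x, k) x[sample.int(length(x), k)]

#' Perturb a bicluster
#'
#' Replaces \code{ceiling(fraction * |genes|)} genes and
#' \code{ceiling(fraction * |conditions|)} conditions — each chosen
#' uniformly without replacement — by uniformly chosen outsiders, keeping
#' the bicluster's dimensions unchanged.  The ceiling guarantees that a
#' 10% perturbation always changes at least one gene and one condition.
#' If an outsider pool is too small, as many as possible are replaced and
#' a warning is emitted.  Randomness comes from the current R RNG state.
#'
#' @param b a [Bicluster-class].
#' @param M the expression matrix (defines the outsider pools).
#' @param fraction fraction in (0, 1] of genes and of conditions to
#'   replace.
#' @return a perturbed, unscored [Bicluster-class] of the same dimensions.
#' @export
perturbBicluster <- function(b, M, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  nG <- ceiling(fraction * length(b@genes))
  nC <- ceiling(fraction * length(b@conditions))
  poolG <- setdiff(seq_len(nrow(M)), b@genes)
  poolC <- setdiff(seq_len(ncol(M)), b@conditions)
  kG <- min(nG, length(poolG))
  kC <- min(nC, length(poolC))
  if (kG < nG || kC < nC)
    warning("outsider pool too small: replacing ", kG, " genes and ",
            kC, " conditions instead of ", nG, " and ", nC)
  genes <- b@genes
  conds <- b@conditions
  if (kG > 0) {
    genes <- c(setdiff(genes, .sampleFrom(genes, kG)),
               .sampleFrom(poolG, kG))
  }
  if (kC > 0) {
    conds <- c(setdiff(conds, .sampleFrom(conds, kC)),
               .sampleFrom(poolC, kC))
  }
  bicluster(genes, conds)
}

#' Run the full PDNS iterated local search
#'
#' Encodes the initial bicluster over the behavior matrix, runs a descent,
#' and records the decoded result as the best bicluster.  Then it
#' alternates perturbation and descent: each cycle perturbs the best
#' bicluster (replacing \code{perturbFraction} of its genes and
#' conditions), re-encodes, descends, decodes with the coverage rule, and
#' updates the best bicluster when the decoded ASR strictly improves (ties
#' keep the incumbent).  The search terminates after Z consecutive cycles
#' without improvement.  The whole run is a deterministic function of
#' (M, initial, params): the seed in \code{params} is applied on entry.
#'
#' @param M numeric expression matrix (validated).
#' @param initial starting [Bicluster-class] (>= 2 genes, >= 2
#'   conditions).
#' @param params a [PDNSParams-class].
#' @param bm optional precomputed [BehaviorMatrix-class] of \code{M}.
#' @return a [PDNSResult-class]
#' @examples
#' set.seed(1)
#' M <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
#' res <- pdnsRun(M, randomInitial(M, 5, 4),
#'                pdnsParams(alpha = 0.6, beta = 0.6, Z = 3, seed = 1))
#' bestBicluster(res)
#' @export
pdnsRun <- function(M, initial, params = pdnsParams(), bm = NULL) {
  validateExpressionMatrix(M)
  validObject(params)
  if (length(initial@genes) < 2L || length(initial@conditions) < 2L)
    stop("degenerate bicluster: initial solution needs >= 2 genes and >= 2 conditions")
  set.seed(params@seed)
  if (is.null(bm)) bm <- buildBehaviorMatrix(M)

  decodeScore <- function(config) {
    b <- tryCatch(decodeConfiguration(config, params@decodeCoverage),
                  error = function(e) NULL)
    if (is.null(b)) return(NULL)
    b@asr <- .asrIndices(M, b@genes, b@conditions)
    b
  }

  d <- descend(encodeConfiguration(initial, bm), M, params, cycle = 0L)
  trace <- d$trace
  best <- decodeScore(d$config)
  if (is.null(best)) {
    # The first descent thinned the pair-columns past decodability; fall
    # back to the decoded initial configuration (complete K always
    # decodes).
    best <- decodeScore(encodeConfiguration(initial, bm))
  }
  bestAsrHistory <- best@asr

  stagnant <- 0L
  cycle <- 0L
  while (stagnant < params@maxStagnantPerturbations) {
    cycle <- cycle + 1L
    pert <- perturbBicluster(best, M, params@perturbFraction)
    d <- descend(encodeConfiguration(pert, bm), M, params, cycle = cycle)
    trace <- rbind(trace, d$trace)
    cand <- decodeScore(d$config)
    if (!is.null(cand) && cand@asr > best@asr) {
      best <- cand
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    bestAsrHistory <- c(bestAsrHistory, best@asr)
  }
  new("PDNSResult", bicluster = best, trace = trace,
      bestAsrHistory = bestAsrHistory, params = params)
}
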