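#' Gene indices of a bicluster or configuration
#' @param x a [Bicluster-class] or [Configuration-class]
#' @return integer vector of gene row indices
#' @export
setGeneric("biclusterGenes", function(x) standardGeneric("biclusterGenes"))

#' Condition indices of a bicluster
#' @param x a [Bicluster-class]
#' @return integer vector of condition column indices
#' @export
setGeneric("biclusterConditions",
           function(x) standardGeneric("biclusterConditions"))

#' ASR score stored in an object
#' @param x a [Bicluster-class] or [PDNSResult-class]
#' @return numeric scalar (NA when unscored)
#' @export
setGeneric("asrValue", function(x) standardGeneric("asrValue"))

#' Pair-column indices of a configuration
#' @param x a [Configuration-class]
#' @return integer vector of behavior-matrix column indices
#' @export
setGeneric("pairColumns", function(x) standardGeneric("pairColumns"))

#' Condition-pair index of a behavior matrix
#' @param x a [BehaviorMatrix-class]
#' @return integer matrix with columns k, q (k < q), one row per pair-column
#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))

#' Trinary entries of a behavior matrix
#' @param x a [BehaviorMatrix-class]
#' @return integer matrix with entries in {-1, 0, 1}
#' @export
setGeneric("tritMatrix", function(x) standardGeneric("tritMatrix"))

#' @rdname biclusterGenes
#' @export
setMethod("biclusterGenes", "Bicluster", function(x) x@genes)

#' @rdname biclusterGenes
#' @export
setMethod("biclusterGenes", "Configuration", function(x) x@genes)

#' @rdname biclusterConditions
#' @export
setMethod("biclusterConditions", "Bicluster", function(x) x@conditions)

#' @rdname asrValue
#' @export
setMethod("asrValue", "Bicluster", function(x) x@asr)

#' @rdname asrValue
#' @export
setMethod("asrValue", "PDNSResult", function(x) x@bicluster@asr)

#' @rdname pairColumns
#' @export
setMethod("pairColumns", "Configuration", function(x) x@pairColumns)

#' @rdname pairIndex
#' @export
setMethod("pairIndex", "BehaviorMatrix", function(x) x@pairIndex)

#' @rdname tritMatrix
#' @export
setMethod("tritMatrix", "BehaviorMatrix", function(x) x@trits)

#' Best bicluster of a PDNS run
#' @param x a [PDNSResult-class]
#' @return the best decoded [Bicluster-class]
#' @export
setGeneric("bestBicluster", function(x) standardGeneric("bestBicluster"))

#' @rdname bestBicluster
#' @export
setMethod("bestBicluster", "PDNSResult", function(x) x@bicluster)

#' Accepted-move trace of a PDNS run
#' @param x a [PDNSResult-class]
#' @return data.frame of accepted moves
#' @export
setGeneric("searchTrace", function(x) standardGeneric("searchTrace"))

#' @rdname searchTrace
#' @export
setMethod("searchTrace", "PDNSResult", function(x) x@trace)

setMethod("show", "BehaviorMatrix", function(object) {
  cat("BehaviorMatrix:", nrow(object@trits), "genes x",
      ncol(object@trits), "condition pairs (",
      length(object@conditionIds), "conditions )\n")
  tab <- table(factor(object@trits, levels = c(-1, 0, 1)))
  cat("  trit frequencies: -1:", tab[["-1"]], " 0:", tab[["0"]],
      " 1:", tab[["1"]], "\n")
})

setMethod("show", "Bicluster", function(object) {
  cat("Bicluster:", length(object@genes), "genes x",
      length(object@conditions), "conditions; ASR =",
      if (is.na(object@asr)) "unscored" else format(object@asr, digits = 4),
      "\n")
})

setMethod("show", "Configuration", function(object) {
  cat("Configuration:", length(object@genes), "genes x",
      length(object@pairColumns), "pair-columns ( backing",
      nrow(object@behavior@trits), "x", ncol(object@behavior@trits),
      "behavior matrix )\n")
})

setMethod("show", "PDNSParams", function(object) {
  cat("PDNSParams: alpha =", object@alpha, ", beta =", object@beta,
      ", asrThreshold =", object@asrThreshold,
      ", Y =", object@maxDescentIters,
      ", Z =", object@maxStagnantPerturbations, "\n")
  cat("  perturbFraction =", object@perturbFraction,
      ", decodeCoverage =", object@decodeCoverage,
      ", seed =", object@seed, "\n")
})

setMethod("show", "PDNSResult", function(object) {
  cat("PDNSResult over", length(object@bestAsrHistory), "cycles;",
      nrow(object@trace), "accepted moves\n")
  show(object@bicluster)
})
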