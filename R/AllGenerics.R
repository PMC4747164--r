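#' Accessors for FoxoChIP classes
#'
#' Small accessor generics: \code{binWidth} and \code{trackStage} and
#' \code{trackValues} for \linkS4class{BinTrack} /
#' \linkS4class{SummitMatrix}, \code{sampleName} for both,
#' \code{columnMeans} for \linkS4class{SummitMatrix}, \code{pssmMatrix},
#' \code{pssmLength} and \code{pssmConsensus} for \linkS4class{PSSM},
#' and \code{bgOrder} for \linkS4class{MarkovBackground}.
#'
#' @param x an object.
#' @return the slot value.
#' @name accessors
#' @aliases binWidth trackStage trackValues sampleName columnMeans
#'   pssmMatrix pssmLength pssmConsensus bgOrder
NULL

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("trackStage", function(x) standardGeneric("trackStage"))

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname accessors
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @rdname accessors
#' @export
setGeneric("columnMeans", function(x) standardGeneric("columnMeans"))

#' @rdname accessors
#' @export
setGeneric("pssmMatrix", function(x) standardGeneric("pssmMatrix"))

#' @rdname accessors
#' @export
setGeneric("pssmLength", function(x) standardGeneric("pssmLength"))

#' @rdname accessors
#' @export
setGeneric("pssmConsensus", function(x) standardGeneric("pssmConsensus"))

#' @rdname accessors
#' @export
setGeneric("bgOrder", function(x) standardGeneric("bgOrder"))

#' @rdname accessors
#' @export
setMethod("binWidth", "BinTrack", function(x) x@binWidth)

#' @rdname accessors
#' @export
setMethod("binWidth", "SummitMatrix", function(x) x@binWidth)

#' @rdname accessors
#' @export
setMethod("trackStage", "BinTrack", function(x) x@stage)

#' @rdname accessors
#' @export
setMethod("trackValues", "BinTrack", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("trackValues", "SummitMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("sampleName", "BinTrack", function(x) x@sample)

#' @rdname accessors
#' @export
setMethod("sampleName", "SummitMatrix", function(x) x@sample)

#' @rdname accessors
#' @export
setMethod("columnMeans", "SummitMatrix", function(x) x@columnMeans)

#' @rdname accessors
#' @export
setMethod("pssmMatrix", "PSSM", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("pssmLength", "PSSM", function(x) ncol(x@matrix))

#' @rdname accessors
#' @export
setMethod("pssmConsensus", "PSSM", function(x) x@consensus)

#' @rdname accessors
#' @export
setMethod("bgOrder", "MarkovBackground", function(x) x@order)

setMethod("show", "BinTrack", function(object) {
    cat(sprintf("BinTrack '%s': %d chromosome(s), %d-bp bins, stage '%s'\n",
                object@sample, length(object@values), object@binWidth,
                object@stage))
    cat(sprintf("  %d bins total\n",
                sum(lengths(object@values))))
})

setMethod("show", "SummitMatrix", function(object) {
    cat(sprintf(
        "SummitMatrix '%s': %d peaks x %d offsets (+/-%d bins of %d bp), %d dropped at edges\n",
        object@sample, nrow(object@values), ncol(object@values),
        object@flankBins, object@binWidth, object@nDropped))
})

setMethod("show", "PSSM", function(object) {
    cat(sprintf("PSSM '%s': length %d, consensus %s\n",
                object@name, ncol(object@matrix), object@consensus))
})

setMethod("show", "MarkovBackground", function(object) {
    cat(sprintf("MarkovBackground '%s': order %d, marginal A/C/G/T = %s\n",
                object@label, object@order,
                paste(sprintf("%.3f", object@marginal), collapse = "/")))
})

setMethod("show", "ScoreNull", function(object) {
    cat(sprintf("ScoreNull (%s): %d score keys at %.3g-bit resolution%s\n",
                object@type, length(object@keys), object@binWidth,
                if (object@type == "mc")
                    sprintf(", %d draws", object@draws) else ""))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d genes on %d x %d-bp chromosome(s), seed %d\n",
        object@nGenes, object@nChroms, object@chromLength, object@seed))
    cat(sprintf("  motif %s (+ %s at %+d bp), %.0f%% genes bound, %gx ChIP enrichment\n",
                object@motifConsensus, object@comotifConsensus,
                object@comotifOffset, 100 * object@fractionBoundGenes,
                object@chipEnrichment))
})

setMethod("show", "MotifEnrichment", function(object) {
    cat(sprintf(
        "MotifEnrichment: r = %.3g at %.2f bits; cor(score, height) = %.3f\n",
        object@r, object@matchThreshold, object@pearsonRVsHeight))
})
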