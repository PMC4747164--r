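#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
NULL

.TRACK_STAGES <- c("raw", "per_million", "input_subtracted", "quantile", "rank")

#' BinTrack: fixed-width binned genome-wide signal
#'
#' A \code{BinTrack} holds one sample's read-derived signal, binned into
#' fixed-width non-overlapping bins along each chromosome.  The
#' \code{stage} flag records how far along the normalization pipeline
#' (raw counts, reads-per-million, input-subtracted, quantile-normalized,
#' rank-transformed) the values are, and is checked by every downstream
#' operation so that the fixed pipeline order cannot be violated
#' silently.
#'
#' @slot sample sample label.
#' @slot binWidth bin width in bp.
#' @slot stage one of \code{"raw"}, \code{"per_million"},
#'   \code{"input_subtracted"}, \code{"quantile"}, \code{"rank"}.
#' @slot values a \code{SimpleList} of per-chromosome numeric vectors,
#'   one entry per bin (\code{ceiling(chrom_length / binWidth)} bins).
#' @slot chromLengths named integer-ish vector of chromosome lengths.
#'
#' @exportClass BinTrack
setClass("BinTrack",
    representation(
        sample = "character",
        binWidth = "integer",
        stage = "character",
        values = "SimpleList",
        chromLengths = "numeric"
    )
)

setValidity("BinTrack", function(object) {
    msg <- NULL
    if (length(object@binWidth) != 1L || object@binWidth < 1L)
        msg <- c(msg, "binWidth must be a single integer >= 1")
    if (!object@stage %in% .TRACK_STAGES)
        msg <- c(msg, sprintf("stage must be one of: %s",
                              paste(.TRACK_STAGES, collapse = ", ")))
    if (is.null(names(object@values)) ||
        !identical(sort(names(object@values)), sort(names(object@chromLengths))))
        msg <- c(msg, "values and chromLengths must share chromosome names")
    for (chrom in names(object@values)) {
        expected <- ceiling(object@chromLengths[[chrom]] / object@binWidth)
        if (length(object@values[[chrom]]) != expected)
            msg <- c(msg, sprintf("chromosome %s: %d bins, expected %d",
                                  chrom, length(object@values[[chrom]]), expected))
    }
    if (object@stage == "raw") {
        vals <- unlist(as.list(object@values), use.names = FALSE)
        if (any(vals < 0) || any(vals != round(vals)))
            msg <- c(msg, "raw-stage values must be non-negative integers")
    }
    if (is.null(msg)) TRUE else msg
})

#' SummitMatrix: summit-centered read-density matrix
#'
#' Rows are peaks (ranked by the summit-bin value, descending), columns
#' are signed bin offsets from the summit bin; \code{columnMeans} is the
#' mean read density (MRD) profile across peaks.
#'
#' @slot values numeric matrix, peaks x (2*flankBins + 1) offsets.
#' @slot columnMeans per-offset mean across rows.
#' @slot flankBins number of bins on each side of the summit bin.
#' @slot binWidth bin width in bp.
#' @slot nDropped number of peaks dropped because their window crossed a
#'   chromosome edge.
#' @slot sample label of the source track.
#'
#' @exportClass SummitMatrix
setClass("SummitMatrix",
    representation(
        values = "matrix",
        columnMeans = "numeric",
        flankBins = "integer",
        binWidth = "integer",
        nDropped = "integer",
        sample = "character"
    )
)

setValidity("SummitMatrix", function(object) {
    msg <- NULL
    expected <- 2L * object@flankBins + 1L
    if (ncol(object@values) != expected)
        msg <- c(msg, sprintf("matrix must have %d columns", expected))
    if (length(object@columnMeans) != expected)
        msg <- c(msg, "columnMeans length must equal column count")
    if (is.null(msg)) TRUE else msg
})

#' PSSM: position-specific scoring matrix
#'
#' Column-stochastic 4 x L base-frequency matrix (rows A, C, G, T) with
#' pseudocount already applied; scored downstream as a log2
#' likelihood ratio against a \linkS4class{MarkovBackground}.
#'
#' @slot name motif name.
#' @slot matrix 4 x L numeric frequency matrix, rows named A, C, G, T;
#'   every column sums to 1.
#' @slot consensus consensus string (most frequent base per column).
#'
#' @exportClass PSSM
setClass("PSSM",
    representation(
        name = "character",
        matrix = "matrix",
        consensus = "character"
    )
)

setValidity("PSSM", function(object) {
    msg <- NULL
    m <- object@matrix
    if (!identical(rownames(m), c("A", "C", "G", "T")))
        msg <- c(msg, "matrix rows must be named A, C, G, T")
    if (ncol(m) < 4L)
        msg <- c(msg, "motif length must be >= 4")
    if (any(m <= 0))
        msg <- c(msg, "all frequencies must be positive (apply a pseudocount)")
    if (any(abs(colSums(m) - 1) > 1e-8))
        msg <- c(msg, "every column must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' MarkovBackground: order-m Markov sequence model
#'
#' Conditional base probabilities given the previous \code{order} bases,
#' trained with a +1 pseudocount per context cell; used both to score
#' scanned windows and to define the null distribution of PSSM scores.
#'
#' @slot order Markov order m (0 = i.i.d. base composition).
#' @slot conditional 4^m x 4 matrix of P(base | context); rows named by
#'   context string ("" for order 0), columns A, C, G, T; rows sum to 1.
#' @slot contextProbs stationary probabilities of the 4^m contexts.
#' @slot marginal marginal base probabilities (A, C, G, T).
#' @slot label training-set label.
#'
#' @exportClass MarkovBackground
setClass("MarkovBackground",
    representation(
        order = "integer",
        conditional = "matrix",
        contextProbs = "numeric",
        marginal = "numeric",
        label = "character"
    )
)

setValidity("MarkovBackground", function(object) {
    msg <- NULL
    if (object@order < 0L)
        msg <- c(msg, "order must be >= 0")
    if (nrow(object@conditional) != 4L^object@order)
        msg <- c(msg, "conditional must have 4^order rows")
    if (any(object@conditional <= 0))
        msg <- c(msg, "all conditional probabilities must be > 0")
    if (any(abs(rowSums(object@conditional) - 1) > 1e-8))
        msg <- c(msg, "conditional rows must sum to 1")
    if (abs(sum(object@marginal) - 1) > 1e-8)
        msg <- c(msg, "marginal must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' ScoreNull: null distribution of PSSM window scores
#'
#' Distribution of the discretized PSSM weight score of a random L-mer
#' drawn from a \linkS4class{MarkovBackground}: exact (dynamic
#' programming over the discretized column-score distribution) for order
#' 0, seeded Monte Carlo for order >= 1.  Scores are discretized to an
#' integer grid of \code{binWidth}-bit steps; \code{tailProbs[i]} is
#' P(score >= keys[i]).
#'
#' @slot type \code{"exact"} or \code{"mc"}.
#' @slot binWidth score grid resolution in bits.
#' @slot keys sorted integer score keys (score = key * binWidth).
#' @slot tailProbs upper-tail probabilities aligned with \code{keys}.
#' @slot draws Monte-Carlo sample size (0 for exact).
#'
#' @exportClass ScoreNull
setClass("ScoreNull",
    representation(
        type = "character",
        binWidth = "numeric",
        keys = "integer",
        tailProbs = "numeric",
        draws = "integer"
    )
)

setValidity("ScoreNull", function(object) {
    msg <- NULL
    if (!object@type %in% c("exact", "mc"))
        msg <- c(msg, "type must be 'exact' or 'mc'")
    if (is.unsorted(object@keys, strictly = TRUE))
        msg <- c(msg, "keys must be strictly increasing")
    if (length(object@keys) != length(object@tailProbs))
        msg <- c(msg, "keys and tailProbs must be the same length")
    if (any(diff(object@tailProbs) > 1e-12))
        msg <- c(msg, "tailProbs must be non-increasing in score")
    if (is.null(msg)) TRUE else msg
})

#' SimulationConfig: parameters of the synthetic study
#'
#' Defines a toy genome, its gene models, the planted primary motif and
#' co-motif, the ChIP enrichment model for the three study conditions
#' (wild type, the low-insulin-signalling \code{daf2} mutant and the
#' \code{daf16daf2} double mutant in which the transcription factor is
#' absent), and the negative-binomial expression model in which
#' activation is coupled to promoter-proximal binding.  See
#' \code{\link{simulationConfig}} for the defaults and their rationale.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        seed = "integer",
        nChroms = "integer",
        chromLength = "integer",
        nGenes = "integer",
        gcContent = "numeric",
        motifConsensus = "character",
        comotifConsensus = "character",
        comotifOffset = "integer",
        comotifFraction = "numeric",
        fractionBoundGenes = "numeric",
        fractionActivated = "numeric",
        backgroundActivatedFraction = "numeric",
        fractionRepressed = "numeric",
        plantedSummitDistanceBands = "integer",
        fragmentLength = "integer",
        readLength = "integer",
        chipEnrichment = "numeric",
        wtEnrichmentRatio = "numeric",
        readsPerSample = "integer",
        totalMappedReads = "integer",
        nbMean = "numeric",
        nbDispersion = "numeric",
        activationFold = "numeric",
        nReplicates = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    fracs <- c(gcContent = object@gcContent,
               fractionBoundGenes = object@fractionBoundGenes,
               fractionActivated = object@fractionActivated,
               backgroundActivatedFraction = object@backgroundActivatedFraction,
               fractionRepressed = object@fractionRepressed,
               comotifFraction = object@comotifFraction)
    bad <- names(fracs)[fracs < 0 | fracs > 1]
    if (length(bad))
        msg <- c(msg, sprintf("fractions out of [0,1]: %s",
                              paste(bad, collapse = ", ")))
    if (object@fragmentLength <= object@readLength)
        msg <- c(msg, "fragmentLength must exceed readLength")
    if (object@activationFold < 1)
        msg <- c(msg, "activationFold must be >= 1")
    if (object@chipEnrichment < 1)
        msg <- c(msg, "chipEnrichment must be >= 1")
    if (!grepl("^[ACGT]+$", object@motifConsensus) ||
        !grepl("^[ACGT]+$", object@comotifConsensus))
        msg <- c(msg, "motif consensus strings must be over A,C,G,T")
    if (is.null(msg)) TRUE else msg
})

#' MotifEnrichment: motif frequency in peaks vs random promoters
#'
#' Per-threshold best-hit frequencies in peak sequences and in matched
#' random promoter sequences, the enrichment ratio r at the match
#' p-value threshold, the Pearson correlation of best scores with peak
#' heights, and an unpaired t-test comparing the two frequency profiles.
#'
#' @slot thresholds score-threshold grid (bits).
#' @slot peakFreq fraction of peak sequences with best score >= threshold.
#' @slot randomFreq same for random promoter sequences.
#' @slot r frequency ratio at the match threshold (+Inf if no random
#'   sequence passes).
#' @slot matchThreshold score threshold (bits) implied by the match
#'   p-value cutoff.
#' @slot pearsonRVsHeight Pearson correlation of per-peak best score
#'   with peak height.
#' @slot tTestP unpaired two-sample t-test p comparing the frequency
#'   profiles.
#'
#' @exportClass MotifEnrichment
setClass("MotifEnrichment",
    representation(
        thresholds = "numeric",
        peakFreq = "numeric",
        randomFreq = "numeric",
        r = "numeric",
        matchThreshold = "numeric",
        pearsonRVsHeight = "numeric",
        tTestP = "numeric"
    )
)

setValidity("MotifEnrichment", function(object) {
    msg <- NULL
    if (length(object@peakFreq) != length(object@thresholds) ||
        length(object@randomFreq) != length(object@thresholds))
        msg <- c(msg, "frequency vectors must match the threshold grid")
    if (any(object@peakFreq < 0 | object@peakFreq > 1) ||
        any(object@randomFreq < 0 | object@randomFreq > 1))
        msg <- c(msg, "frequencies must lie in [0,1]")
    if (any(diff(object@peakFreq) > 1e-12) || any(diff(object@randomFreq) > 1e-12))
        msg <- c(msg, "frequencies must be non-increasing in threshold")
    if (is.null(msg)) TRUE else msg
})
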