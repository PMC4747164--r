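#' Shift reads to fragment centers
#'
#' Each single-end read is shifted towards its 3' direction by half the
#' library's mean fragment size, producing one genomic position per
#' read (the estimated fragment midpoint): \code{start + round(f/2)}
#' for \code{+} reads, \code{end - round(f/2)} for \code{-} reads.
#' Positions are clamped to chromosome bounds when
#' \code{chromLengths} is supplied.  Full-fragment shifting is
#' available via \code{fullFragment = TRUE}.
#'
#' The library mean fragment sizes of the original study were 171 bp
#' (wild type), 158 bp (\code{daf2}) and 200 bp (\code{daf16daf2});
#' fragment size is always an input here, never estimated.
#'
#' @param reads a stranded reads \code{GRanges}.
#' @param fragmentSize mean fragment size in bp.
#' @param chromLengths optional named vector of chromosome lengths for
#'   clamping.
#' @param fullFragment shift by the full fragment size instead of half.
#' @return a width-1 \code{GRanges} of shifted positions.
#' @export
shiftReads <- function(reads, fragmentSize, chromLengths = NULL,
                       fullFragment = FALSE) {
    st <- as.character(strand(reads))
    if (any(!st %in% c("+", "-")))
        stop("every read must have a +/- strand")
    shift <- as.integer(round(if (fullFragment) fragmentSize else
                              fragmentSize / 2))
    pos <- ifelse(st == "+", start(reads) + shift, end(reads) - shift)
    if (!is.null(chromLengths)) {
        lim <- chromLengths[as.character(seqnames(reads))]
        pos <- pmax(1L, pmin(as.integer(pos), as.integer(lim)))
    } else {
        pos <- pmax(1L, as.integer(pos))
    }
    out <- GRanges(seqnames(reads), IRanges(pos, width = 1L))
    mcols(out)$sample <- mcols(reads)$sample
    out
}

#' Bin shifted positions and scale to reads per million
#'
#' Counts positions in fixed-width non-overlapping bins per chromosome,
#' then scales each bin by \code{1e6 / totalUniqueReads} so that
#' libraries of different depth are comparable.
#'
#' @param positions width-1 \code{GRanges} from \code{\link{shiftReads}}.
#' @param chromLengths named vector of chromosome lengths.
#' @param binWidth bin width in bp (default 25).
#' @param totalUniqueReads library size used for scaling; defaults to
#'   \code{length(positions)}.
#' @param sample sample label.
#' @param perMillion if \code{FALSE}, stop at the raw-count stage.
#' @return a \linkS4class{BinTrack} at stage \code{"per_million"} (or
#'   \code{"raw"}).
#' @export
binAndNormalize <- function(positions, chromLengths, binWidth = 25L,
                            totalUniqueReads = length(positions),
                            sample = "sample", perMillion = TRUE) {
    if (totalUniqueReads <= 0)
        stop("totalUniqueReads must be > 0")
    binWidth <- as.integer(binWidth)
    chrom <- as.character(seqnames(positions))
    bad <- setdiff(unique(chrom), names(chromLengths))
    if (length(bad))
        stop("positions on unknown chromosome(s): ", paste(bad, collapse = ", "))
    pos <- start(positions)
    lim <- chromLengths[chrom]
    if (any(pos < 1L | pos > lim))
        stop("position beyond chromosome bounds")
    vals <- S4Vectors::SimpleList(lapply(names(chromLengths), function(ch) {
        nbins <- as.integer(ceiling(chromLengths[[ch]] / binWidth))
        idx <- (pos[chrom == ch] - 1L) %/% binWidth + 1L
        counts <- tabulate(idx, nbins)
        if (perMillion) counts * 1e6 / totalUniqueReads else as.numeric(counts)
    }))
    names(vals) <- names(chromLengths)
    new("BinTrack", sample = sample, binWidth = binWidth,
        stage = if (perMillion) "per_million" else "raw",
        values = vals,
        chromLengths = stats::setNames(as.numeric(chromLengths),
                                       names(chromLengths)))
}

.checkComparable <- function(a, b) {
    if (a@binWidth != b@binWidth)
        stop("bin widths differ")
    if (!identical(names(a@values), names(b@values)) ||
        !identical(lengths(a@values), lengths(b@values)))
        stop("tracks cover different genomes")
}

#' Subtract a normalized input track from a ChIP track
#'
#' Elementwise \code{chip - input} on the per-million scale.  Negative
#' values are retained by default (quantile normalization follows in
#' the pipeline); set \code{clip = TRUE} to floor at zero.
#'
#' @param chip,input \linkS4class{BinTrack}s at stage
#'   \code{"per_million"}.
#' @param clip floor negative differences at zero.
#' @return a \linkS4class{BinTrack} at stage \code{"input_subtracted"}.
#' @export
subtractInput <- function(chip, input, clip = FALSE) {
    if (chip@stage != "per_million" || input@stage != "per_million")
        stop("both tracks must be at the per_million stage, got '",
             chip@stage, "' and '", input@stage, "'")
    .checkComparable(chip, input)
    vals <- S4Vectors::SimpleList(lapply(names(chip@values), function(ch) {
        d <- chip@values[[ch]] - input@values[[ch]]
        if (clip) pmax(d, 0) else d
    }))
    names(vals) <- names(chip@values)
    new("BinTrack", sample = chip@sample, binWidth = chip@binWidth,
        stage = "input_subtracted", values = vals,
        chromLengths = chip@chromLengths)
}

#' Quantile-normalize a set of tracks
#'
#' Classic quantile normalization over the concatenated genome-wide bin
#' vectors: the value at rank k in each sample is replaced by the
#' across-sample mean of the k-th order statistics, ties receiving the
#' mean of the replacement values they span.  Afterwards all samples
#' have identical sorted vectors.  Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param tracks a list of >= 2 \linkS4class{BinTrack}s with equal
#'   genome and stage.
#' @return a list of \linkS4class{BinTrack}s at stage
#'   \code{"quantile"}.
#' @export
quantileNormalizeTracks <- function(tracks) {
    if (length(tracks) < 2L)
        stop("need at least two tracks")
    for (t in tracks[-1L]) {
        .checkComparable(tracks[[1L]], t)
        if (t@stage != tracks[[1L]]@stage)
            stop("all tracks must be at the same stage")
    }
    mat <- vapply(tracks, function(t)
        unlist(as.list(t@values), use.names = FALSE),
        numeric(sum(lengths(tracks[[1L]]@values))))
    normed <- limma::normalizeQuantiles(mat, ties = TRUE)
    splitIdx <- rep(seq_along(tracks[[1L]]@values),
                    lengths(tracks[[1L]]@values))
    lapply(seq_along(tracks), function(j) {
        vals <- split(normed[, j], splitIdx)
        names(vals) <- names(tracks[[1L]]@values)
        new("BinTrack", sample = tracks[[j]]@sample,
            binWidth = tracks[[j]]@binWidth, stage = "quantile",
            values = S4Vectors::SimpleList(vals),
            chromLengths = tracks[[j]]@chromLengths)
    })
}

#' Build a summit-centered read-density matrix
#'
#' For each peak, the bin containing the summit is identified and the
#' normalized values of that bin and \code{flankBins} bins on each side
#' are collected into one row.  Rows are ranked by the summit-bin value
#' (descending); \code{columnMeans} holds the mean read density (MRD)
#' per signed offset.  Peaks whose window crosses a chromosome edge are
#' dropped, with the count recorded in the \code{nDropped} slot and
#' reported via \code{message()}.
#'
#' @param track a \linkS4class{BinTrack}.
#' @param peaks a peaks \code{GRanges} (see \code{\link{readPeaks}}).
#' @param flankBins bins on each side of the summit bin (default 20,
#'   i.e. +/- 500 bp at 25-bp bins).
#' @return a \linkS4class{SummitMatrix}.
#' @export
summitMatrix <- function(track, peaks, flankBins = 20L) {
    flankBins <- as.integer(flankBins)
    bw <- track@binWidth
    chrom <- as.character(seqnames(peaks))
    bad <- setdiff(unique(chrom), names(track@values))
    if (length(bad))
        stop("peaks on chromosome(s) not covered by the track: ",
             paste(bad, collapse = ", "))
    centerBin <- (mcols(peaks)$summit - 1L) %/% bw + 1L
    nbins <- lengths(track@values)[chrom]
    keep <- centerBin - flankBins >= 1L & centerBin + flankBins <= nbins
    nDropped <- sum(!keep)
    if (nDropped > 0L)
        message(nDropped, " peak(s) dropped: window crosses a chromosome edge")
    offsets <- seq(-flankBins, flankBins)
    rows <- lapply(which(keep), function(i)
        track@values[[chrom[i]]][centerBin[i] + offsets])
    mat <- do.call(rbind, c(rows, list(matrix(0, 0, length(offsets)))))
    colnames(mat) <- as.character(offsets)
    rownames(mat) <- mcols(peaks)$peak_id[keep]
    ord <- order(mat[, flankBins + 1L], decreasing = TRUE)
    mat <- mat[ord, , drop = FALSE]
    cm <- if (nrow(mat)) colMeans(mat) else
        stats::setNames(rep(NaN, length(offsets)), colnames(mat))
    new("SummitMatrix", values = mat, columnMeans = cm,
        flankBins = flankBins, binWidth = bw,
        nDropped = as.integer(nDropped), sample = track@sample)
}

#' Export a SummitMatrix as TSV
#'
#' Rows are peaks (ranked), columns the signed bin offsets; suitable for
#' external heat-mapping.
#'
#' @param mat a \linkS4class{SummitMatrix}.
#' @param path output file.
#' @export
writeSummitMatrix <- function(mat, path) {
    df <- data.frame(peak_id = rownames(mat@values), mat@values,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Rank-transform a track
#'
#' Replaces every bin value by its genome-wide fractional rank in
#' (0, 1], ties receiving the mean rank.  The transform is invariant
#' under any strictly monotone transformation of the input values.
#'
#' @param track a \linkS4class{BinTrack}.
#' @return a \linkS4class{BinTrack} at stage \code{"rank"}.
#' @export
rankTransform <- function(track) {
    all <- unlist(as.list(track@values), use.names = FALSE)
    r <- rank(all, ties.method = "average") / length(all)
    splitIdx <- rep(seq_along(track@values), lengths(track@values))
    vals <- split(r, splitIdx)
    names(vals) <- names(track@values)
    new("BinTrack", sample = track@sample, binWidth = track@binWidth,
        stage = "rank", values = S4Vectors::SimpleList(vals),
        chromLengths = track@chromLengths)
}
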