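.bandLabel <- function(absDistance, bandWidth = 500L) {
    k <- absDistance %/% bandWidth
    sprintf("%g-%g kb", k * bandWidth / 1000, (k + 1L) * bandWidth / 1000)
}

#' Assign peaks to genes by closest TSS
#'
#' Every peak summit is assigned to the gene whose TSS minimizes
#' \code{|summit - tss|} (ties broken lexicographically by gene id, with
#' the number of ties reported).  The signed distance is expressed in
#' transcription orientation: negative means the summit lies upstream
#' of the TSS.  A peak is inside the promoter window when its distance
#' lies in \code{[-upstreamWindow, +downstreamWindow]} (defaults 2.5 kb
#' upstream, 300 bp downstream).  Peaks beyond the window are retained
#' with \code{in_promoter_window = FALSE}; peaks on chromosomes without
#' genes get an \code{NA} assignment and \code{no_gene = TRUE}.
#'
#' @param peaks a peaks \code{GRanges} (see \code{\link{readPeaks}}).
#' @param genes a genes \code{GRanges} (see \code{\link{readAnnotation}}).
#' @param upstreamWindow,downstreamWindow promoter window in bp.
#' @param bandWidth width of the distance bands in bp.
#' @return a \code{DataFrame} with one row per peak: \code{peak_id},
#'   \code{gene_id}, \code{signed_distance}, \code{band},
#'   \code{in_promoter_window}, \code{no_gene}.
#' @export
assignPeaks <- function(peaks, genes, upstreamWindow = 2500L,
                        downstreamWindow = 300L, bandWidth = 500L) {
    if (length(genes) == 0L)
        stop("genes must be non-empty")
    geneChrom <- as.character(seqnames(genes))
    geneTss <- mcols(genes)$tss
    geneId <- mcols(genes)$gene_id
    geneSign <- ifelse(as.character(strand(genes)) == "+", 1L, -1L)

    n <- length(peaks)
    outGene <- rep(NA_character_, n)
    outDist <- rep(NA_integer_, n)
    nTies <- 0L
    peakChrom <- as.character(seqnames(peaks))
    summit <- mcols(peaks)$summit
    for (ch in unique(peakChrom)) {
        gidx <- which(geneChrom == ch)
        pidx <- which(peakChrom == ch)
        if (length(gidx) == 0L) next
        ord <- gidx[order(geneTss[gidx], geneId[gidx])]
        tssSorted <- geneTss[ord]
        for (i in pidx) {
            d <- abs(summit[i] - geneTss[gidx])
            best <- min(d)
            cand <- gidx[d == best]
            if (length(cand) > 1L) {
                nTies <- nTies + 1L
                cand <- cand[order(geneId[cand])][1L]
            }
            outGene[i] <- geneId[cand]
            outDist[i] <- (summit[i] - geneTss[cand]) * geneSign[cand]
        }
    }
    if (nTies > 0L)
        message(nTies, " equidistant-TSS tie(s) broken lexicographically by gene id")
    inWin <- !is.na(outDist) & outDist >= -upstreamWindow &
        outDist <= downstreamWindow
    DataFrame(
        peak_id = mcols(peaks)$peak_id,
        gene_id = outGene,
        signed_distance = outDist,
        band = ifelse(is.na(outDist), NA_character_,
                      .bandLabel(abs(outDist), bandWidth)),
        in_promoter_window = inWin,
        no_gene = is.na(outGene))
}

#' Per-gene band and proximal-peak summary
#'
#' For every gene with at least one assigned peak: the closest absolute
#' summit-to-TSS distance, its distance band, and the number of peaks
#' within the proximal cutoff (default 0.5 kb), supporting single- vs
#' multi-peak analyses.
#'
#' @param assignments output of \code{\link{assignPeaks}}.
#' @param bandWidth band width in bp.
#' @param proximalCutoff absolute distance cutoff for the proximal peak
#'   count, in bp.
#' @return a \code{DataFrame}: \code{gene_id}, \code{closest_distance}
#'   (signed), \code{band}, \code{n_proximal}.
#' @export
bandAndCount <- function(assignments, bandWidth = 500L,
                         proximalCutoff = 500L) {
    a <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
    genes <- sort(unique(a$gene_id))
    closest <- integer(length(genes))
    nprox <- integer(length(genes))
    for (j in seq_along(genes)) {
        d <- a$signed_distance[a$gene_id == genes[j]]
        closest[j] <- d[which.min(abs(d))]
        nprox[j] <- sum(abs(d) <= proximalCutoff)
    }
    DataFrame(gene_id = genes,
              closest_distance = closest,
              band = .bandLabel(abs(closest), bandWidth),
              n_proximal = nprox)
}

#' Compare peak sets between two conditions
#'
#' Peaks are paired across conditions when their intervals intersect by
#' at least 1 bp, greedily by maximal overlap with each peak used at
#' most once.  The three resulting sets (common pairs, exclusive to A,
#' exclusive to B) partition both inputs.  For common pairs the summit
#' shift (summit in B minus summit in A) is reported, signed by the
#' assigned gene's strand when assignments are supplied.
#'
#' @param peaksA,peaksB peaks \code{GRanges}.
#' @param assignmentsA optional \code{\link{assignPeaks}} output for
#'   \code{peaksA}, used together with \code{genes} to orient summit
#'   shifts in transcription direction.
#' @param genes optional genes \code{GRanges}.
#' @return a list: \code{common} (a \code{DataFrame} with
#'   \code{peak_a}, \code{peak_b}, \code{overlap_bp},
#'   \code{summit_shift}), \code{exclusive_a}, \code{exclusive_b}
#'   (character vectors of peak ids).
#' @export
compareConditions <- function(peaksA, peaksB, assignmentsA = NULL,
                              genes = NULL) {
    hits <- findOverlaps(peaksA, peaksB, minoverlap = 1L)
    ov <- width(pintersect(peaksA[queryHits(hits)], peaksB[subjectHits(hits)]))
    ord <- order(ov, decreasing = TRUE)
    usedA <- logical(length(peaksA))
    usedB <- logical(length(peaksB))
    pa <- integer(0); pb <- integer(0); po <- integer(0)
    for (k in ord) {
        i <- queryHits(hits)[k]; j <- subjectHits(hits)[k]
        if (usedA[i] || usedB[j]) next
        usedA[i] <- TRUE; usedB[j] <- TRUE
        pa <- c(pa, i); pb <- c(pb, j); po <- c(po, ov[k])
    }
    sign <- rep(1L, length(pa))
    if (!is.null(assignmentsA) && !is.null(genes) && length(pa)) {
        strandOf <- stats::setNames(
            ifelse(as.character(strand(genes)) == "+", 1L, -1L),
            mcols(genes)$gene_id)
        gid <- assignmentsA$gene_id[match(mcols(peaksA)$peak_id[pa],
                                          assignmentsA$peak_id)]
        s <- strandOf[gid]
        sign <- ifelse(is.na(s), 1L, s)
    }
    shift <- (mcols(peaksB)$summit[pb] - mcols(peaksA)$summit[pa]) * sign
    list(
        common = DataFrame(
            peak_a = mcols(peaksA)$peak_id[pa],
            peak_b = mcols(peaksB)$peak_id[pb],
            overlap_bp = po,
            summit_shift = as.integer(shift)),
        exclusive_a = mcols(peaksA)$peak_id[!usedA],
        exclusive_b = mcols(peaksB)$peak_id[!usedB])
}
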