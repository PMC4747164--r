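#' @importFrom stats runif cor t.test setNames
NULL

.BASES <- c("A", "C", "G", "T")

.encodeSeq <- function(s) {
    match(strsplit(toupper(as.character(s)), "")[[1L]], .BASES)
}

.revcompCodes <- function(codes) rev(5L - codes)

#' Build a PSSM from a count matrix
#'
#' Adds the pseudocount to every cell and normalizes each column to
#' sum to 1.
#'
#' @param counts 4 x L non-negative matrix, rows A, C, G, T (row names
#'   optional, this order assumed).
#' @param name motif name.
#' @param pseudocount added to every cell before normalization
#'   (default 0.25).
#' @return a \linkS4class{PSSM}.
#' @export
pssmFromCounts <- function(counts, name = "motif", pseudocount = 0.25) {
    counts <- as.matrix(counts)
    if (nrow(counts) != 4L)
        stop("counts must have 4 rows (A, C, G, T)")
    m <- counts + pseudocount
    m <- sweep(m, 2L, colSums(m), "/")
    rownames(m) <- .BASES
    consensus <- paste(.BASES[apply(m, 2L, which.max)], collapse = "")
    new("PSSM", name = name, matrix = m, consensus = consensus)
}

#' Build a sharp PSSM from a consensus string
#'
#' Each column gets \code{strength} pseudo-observations of the
#' consensus base and one of each alternative, then the standard
#' pseudocount; with the defaults the consensus base has frequency
#' about 0.83 per column.
#'
#' @param consensus DNA string over A, C, G, T.
#' @param name motif name (defaults to the consensus).
#' @param strength consensus pseudo-observations per column.
#' @param pseudocount see \code{\link{pssmFromCounts}}.
#' @return a \linkS4class{PSSM}.
#' @export
pssmFromConsensus <- function(consensus, name = consensus, strength = 17,
                              pseudocount = 0.25) {
    codes <- .encodeSeq(consensus)
    if (anyNA(codes))
        stop("consensus must be over A, C, G, T")
    counts <- matrix(1, 4L, length(codes), dimnames = list(.BASES, NULL))
    counts[cbind(codes, seq_along(codes))] <- strength
    pssmFromCounts(counts, name = name, pseudocount = pseudocount)
}

#' Read a position frequency matrix (JASPAR-style text)
#'
#' Expects a \code{>name} header followed by four lines of the form
#' \code{A [ 4 19 0 ... ]} (brackets optional), rows in any order.
#'
#' @param path PFM text file.
#' @param pseudocount see \code{\link{pssmFromCounts}}.
#' @return a \linkS4class{PSSM}.
#' @export
readPssm <- function(path, pseudocount = 0.25) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    name <- if (grepl("^>", lines[1L]))
        sub("^>\\s*", "", lines[1L]) else "motif"
    rows <- grep("^[ACGT]\\b", lines, value = TRUE)
    if (length(rows) != 4L)
        stop("expected one count row per base (A, C, G, T) in ", path)
    base <- substr(rows, 1L, 1L)
    nums <- lapply(rows, function(l)
        as.numeric(strsplit(trimws(gsub("^[ACGT]|\\[|\\]", "", l)),
                            "\\s+")[[1L]]))
    if (length(unique(lengths(nums))) != 1L)
        stop("count rows of unequal length in ", path)
    counts <- do.call(rbind, nums)[match(.BASES, base), , drop = FALSE]
    pssmFromCounts(counts, name = name, pseudocount = pseudocount)
}

.contextNames <- function(order) {
    if (order == 0L) return("")
    g <- do.call(expand.grid,
                 rev(replicate(order, .BASES, simplify = FALSE)))
    apply(g[, rev(seq_len(order)), drop = FALSE], 1L, paste, collapse = "")
}

#' Train an order-m Markov background model
#'
#' Conditional base frequencies given the previous \code{order} bases,
#' with a +1 pseudocount per context cell, estimated from the supplied
#' sequences (typically the reference genome).
#'
#' @param sequences a \code{DNAStringSet} (or character vector).
#' @param order Markov order m >= 0 (default 2).
#' @param label training-set label.
#' @return a \linkS4class{MarkovBackground}.
#' @export
trainBackground <- function(sequences, order = 2L, label = "background") {
    order <- as.integer(order)
    if (order < 0L) stop("order must be >= 0")
    if (is.character(sequences)) sequences <- DNAStringSet(sequences)
    kmerCounts <- function(width) {
        m <- oligonucleotideFrequency(sequences, width = width)
        if (is.matrix(m)) colSums(m) else m
    }
    c1 <- kmerCounts(1L) + 1
    marginal <- c1 / sum(c1)
    if (order == 0L) {
        conditional <- matrix(marginal, 1L, 4L,
                              dimnames = list("", .BASES))
        contextProbs <- setNames(1, "")
    } else {
        ck1 <- kmerCounts(order + 1L)
        ctxNames <- .contextNames(order)
        conditional <- matrix(0, 4L^order, 4L,
                              dimnames = list(ctxNames, .BASES))
        for (b in .BASES)
            conditional[, b] <- ck1[paste0(ctxNames, b)] + 1
        contextProbs <- rowSums(conditional) / sum(conditional)
        conditional <- sweep(conditional, 1L, rowSums(conditional), "/")
    }
    new("MarkovBackground", order = order, conditional = conditional,
        contextProbs = as.numeric(contextProbs),
        marginal = setNames(as.numeric(marginal), .BASES), label = label)
}

# Per-window weight score (bits) and discretized integer key for every
# start position of `codes`, forward orientation only.  The background
# probability of base i in a window uses the order-m context of the
# preceding bases *within the window*; the first min(m, L) bases fall
# back to the marginal composition, so a window's score depends only on
# its own content (and matches the null model used for p-values).
.windowScores <- function(codes, pssm, bg, binWidth) {
    L <- ncol(pssm@matrix)
    n <- length(codes)
    if (n < L)
        return(list(score = numeric(0), key = integer(0)))
    m <- bg@order
    lf <- log2(pssm@matrix)
    lmarg <- log2(bg@marginal)
    lcond <- log2(bg@conditional)
    nW <- n - L + 1L
    ctxIdx <- NULL
    if (m > 0L && n > m) {
        ctxIdx <- rep(NA_integer_, n)
        acc <- rep(0L, n - m)
        for (j in seq_len(m))  # base at t - j contributes 4^(j-1)
            acc <- acc + (codes[(m + 1L - j):(n - j)] - 1L) * 4L^(j - 1L)
        ctxIdx[(m + 1L):n] <- acc + 1L
    }
    score <- numeric(nW)
    key <- numeric(nW)
    for (i in seq_len(L)) {
        tpos <- i:(nW + i - 1L)
        b <- codes[tpos]
        num <- lf[cbind(b, i)]
        if (i <= m) {
            den <- lmarg[b]
        } else if (m == 0L) {
            den <- lcond[cbind(1L, b)]
        } else {
            den <- lcond[cbind(ctxIdx[tpos], b)]
        }
        contrib <- num - den
        score <- score + contrib
        key <- key + round(contrib / binWidth)
    }
    list(score = score, key = as.integer(key))
}

#' Score one window against a PSSM and background
#'
#' The weight score is the log2 likelihood ratio
#' \eqn{\sum_i \log_2 f_i(b_i) - \log_2 P_{bg}(b_i | context)}; the
#' reverse-strand score is the forward score of the reverse complement.
#' Windows containing N are undefined (\code{NA}) and skipped by the
#' scanners.
#'
#' @param window DNA string of the PSSM's length.
#' @param pssm a \linkS4class{PSSM}.
#' @param bg a \linkS4class{MarkovBackground}.
#' @param strand \code{"+"} or \code{"-"}.
#' @return the weight score in bits.
#' @export
scoreWindow <- function(window, pssm, bg, strand = "+") {
    codes <- .encodeSeq(window)
    if (length(codes) != ncol(pssm@matrix))
        stop("window length must equal the PSSM length")
    if (anyNA(codes)) return(NA_real_)
    if (strand == "-") codes <- .revcompCodes(codes)
    .windowScores(codes, pssm, bg, binWidth = 0.01)$score
}

#' Null distribution of the discretized window score
#'
#' Distribution of the window score of a random L-mer under the
#' background model, on an integer grid of \code{binWidth}-bit steps.
#' Exact for order 0 (dynamic programming: convolution of the
#' discretized per-column score distributions); a seeded Monte-Carlo
#' estimate (window sequences generated from the Markov chain started
#' at its stationary context distribution) for order >= 1.
#'
#' @param pssm a \linkS4class{PSSM}.
#' @param bg a \linkS4class{MarkovBackground}.
#' @param binWidth score grid resolution in bits (default 0.01).
#' @param mcDraws Monte-Carlo sample size for order >= 1 (default 1e6).
#' @param seed seed for the Monte-Carlo draw.
#' @return a \linkS4class{ScoreNull}.
#' @export
scoreNull <- function(pssm, bg, binWidth = 0.01, mcDraws = 1e6L, seed = 1L) {
    L <- ncol(pssm@matrix)
    lf <- log2(pssm@matrix)
    if (bg@order == 0L) {
        p0 <- bg@marginal
        keyCol <- round(sweep(lf, 1L, log2(p0)) / binWidth)
        curLo <- 0L
        vec <- 1
        for (i in seq_len(L)) {
            ks <- keyCol[, i]
            newLo <- curLo + min(ks)
            newHi <- curLo + length(vec) - 1L + max(ks)
            newVec <- numeric(newHi - newLo + 1L)
            for (b in 1:4) {
                off <- curLo + ks[b] - newLo
                idx <- (off + 1L):(off + length(vec))
                newVec[idx] <- newVec[idx] + vec * p0[b]
            }
            vec <- newVec
            curLo <- newLo
        }
        keys <- seq.int(curLo, curLo + length(vec) - 1L)
        keep <- vec > 0
        keys <- keys[keep]
        probs <- vec[keep]
        tail <- rev(cumsum(rev(probs)))
        return(new("ScoreNull", type = "exact", binWidth = binWidth,
                   keys = as.integer(keys), tailProbs = tail, draws = 0L))
    }
    set.seed(seed)
    m <- bg@order
    lmarg <- log2(bg@marginal)
    lcond <- log2(bg@conditional)
    cumcond <- t(apply(bg@conditional, 1L, cumsum))
    ctx <- sample.int(nrow(bg@conditional), mcDraws, replace = TRUE,
                      prob = bg@contextProbs)
    keySum <- numeric(mcDraws)
    for (i in seq_len(L)) {
        u <- runif(mcDraws)
        b <- 1L + (u > cumcond[ctx, 1L]) + (u > cumcond[ctx, 2L]) +
            (u > cumcond[ctx, 3L])
        den <- if (i <= m) lmarg[b] else lcond[cbind(ctx, b)]
        keySum <- keySum + round((lf[cbind(b, i)] - den) / binWidth)
        # slide the context window: drop the oldest base, append b
        ctx <- ((ctx - 1L) %% 4L^(m - 1L)) * 4L + b
    }
    tab <- table(keySum)
    keys <- as.integer(names(tab))
    tail <- rev(cumsum(rev(as.numeric(tab)))) / mcDraws
    new("ScoreNull", type = "mc", binWidth = binWidth, keys = keys,
        tailProbs = tail, draws = as.integer(mcDraws))
}

#' Match p-value for a window score
#'
#' \eqn{P(\mathrm{score\ of\ a\ random\ L\mbox{-}mer} \ge s)} under the
#' background model, looked up in a precomputed
#' \code{\link{scoreNull}} distribution on its discretized grid.
#' Scores below the minimum achievable give p = 1; scores above the
#' maximum give p = 0 (i.e. below the grid / Monte-Carlo resolution).
#'
#' @param score weight score(s) in bits, or integer grid keys when
#'   \code{isKey = TRUE}.
#' @param null a \linkS4class{ScoreNull}.
#' @param isKey interpret \code{score} as pre-discretized integer keys.
#' @return p-value(s).
#' @export
matchPvalue <- function(score, null, isKey = FALSE) {
    key <- if (isKey) as.integer(score) else
        as.integer(round(score / null@binWidth))
    idx <- findInterval(key - 1L, null@keys) + 1L  # first stored key >= key
    p <- numeric(length(key))
    inRange <- idx <= length(null@keys)
    p[inRange] <- null@tailProbs[idx[inRange]]
    p[!inRange] <- 0
    p[is.na(key)] <- NA_real_
    p
}

#' Scan sequences for best PSSM matches
#'
#' Scores every window on both strands of every sequence.  With
#' \code{bestOnly = TRUE} (the default, matching the assumption of at
#' most one true site per sequence) each sequence reports exactly one
#' row -- its best match (ties broken deterministically: leftmost
#' center, then \code{+} strand), flagged \code{significant} when its
#' p-value passes the threshold.  With \code{bestOnly = FALSE} all
#' threshold-passing matches are returned.
#'
#' @param seqs a \code{DNAStringSet} or named character vector.
#' @param pssm a \linkS4class{PSSM}.
#' @param bg a \linkS4class{MarkovBackground}.
#' @param pThreshold match p-value threshold (default 1e-5).
#' @param bestOnly report only the best match per sequence.
#' @param null optional precomputed \code{\link{scoreNull}}; built on
#'   the fly otherwise.
#' @return a \code{DataFrame}: \code{seq_id}, \code{center} (1-based
#'   position of the match's central coordinate within the sequence),
#'   \code{strand}, \code{score}, \code{pvalue}, \code{significant}.
#' @export
scanSequences <- function(seqs, pssm, bg, pThreshold = 1e-5,
                          bestOnly = TRUE, null = NULL) {
    if (is.null(null))
        null <- scoreNull(pssm, bg)
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("seq_%04d", seq_along(seqs))
    L <- ncol(pssm@matrix)
    centerOff <- (L - 1L) %/% 2L
    res <- lapply(names(seqs), function(id) {
        codes <- .encodeSeq(seqs[[id]])
        n <- length(codes)
        fwd <- .windowScores(codes, pssm, bg, null@binWidth)
        rev <- .windowScores(.revcompCodes(codes), pssm, bg, null@binWidth)
        nF <- length(fwd$score)
        revStart <- n - seq_len(nF) - L + 2L  # original start of rev window
        cand <- DataFrame(
            seq_id = id,
            center = c(seq_len(nF) + centerOff, revStart + centerOff),
            strand = rep(c("+", "-"), each = nF),
            score = c(fwd$score, rev$score),
            key = c(fwd$key, rev$key))
        cand <- cand[!is.na(cand$score), , drop = FALSE]
        if (nrow(cand) == 0L)
            return(DataFrame(seq_id = id, center = NA_integer_,
                             strand = NA_character_, score = NA_real_,
                             key = NA_integer_))
        if (bestOnly) {
            ord <- order(-cand$score, cand$center, cand$strand)
            cand[ord[1L], , drop = FALSE]
        } else {
            cand
        }
    })
    out <- do.call(rbind, res)
    out$pvalue <- matchPvalue(out$key, null, isKey = TRUE)
    out$significant <- !is.na(out$pvalue) & out$pvalue <= pThreshold
    if (!bestOnly)
        out <- out[out$significant, , drop = FALSE]
    out$key <- NULL
    out
}

#' Scan peak sequences (summit +/- halfWidth) for a motif
#'
#' Extracts each peak's summit-centered window from the genome and
#' delegates to \code{\link{scanSequences}}.  Reported centers are
#' converted to genomic coordinates (\code{genomic_center}) and each
#' peak carries its height for downstream correlation.
#'
#' @param genome a \code{DNAStringSet}.
#' @param peaks a peaks \code{GRanges} (see \code{\link{readPeaks}}).
#' @param pssm,bg,pThreshold,bestOnly,null see
#'   \code{\link{scanSequences}}.
#' @param halfWidth half-window around the summit in bp (default 250).
#' @return a \code{DataFrame} as from \code{scanSequences} plus
#'   \code{genomic_center} and \code{height}.
#' @export
scanPeaks <- function(genome, peaks, pssm, bg, halfWidth = 250L,
                      pThreshold = 1e-5, bestOnly = TRUE, null = NULL) {
    chrom <- as.character(seqnames(peaks))
    summit <- mcols(peaks)$summit
    lens <- setNames(Biostrings::width(genome), names(genome))
    if (any(summit - halfWidth < 1L | summit + halfWidth > lens[chrom]))
        stop("summit +/- halfWidth outside chromosome bounds")
    seqs <- DNAStringSet(vapply(seq_along(peaks), function(i)
        as.character(subseq(genome[[chrom[i]]],
                            summit[i] - halfWidth, summit[i] + halfWidth)),
        ""))
    names(seqs) <- mcols(peaks)$peak_id
    out <- scanSequences(seqs, pssm, bg, pThreshold = pThreshold,
                         bestOnly = bestOnly, null = null)
    i <- match(out$seq_id, mcols(peaks)$peak_id)
    out$genomic_center <- as.integer(summit[i] - halfWidth - 1L + out$center)
    out$height <- mcols(peaks)$height[i]
    out
}

#' Sample random promoter windows as a motif-scan control
#'
#' Draws windows of the same width as the peak windows, centered at a
#' uniformly chosen distance upstream of the TSS of randomly sampled
#' genes (seeded).  Serves as the matched random-promoter control for
#' \code{\link{enrichmentCurve}}.
#'
#' @param genome a \code{DNAStringSet}.
#' @param genes a genes \code{GRanges}.
#' @param n number of windows.
#' @param halfWidth half-window in bp (default 250).
#' @param distanceRange upstream TSS distances to draw centers from.
#' @param seed RNG seed.
#' @return a \code{DNAStringSet} of 2*halfWidth+1 windows.
#' @export
randomPromoterWindows <- function(genome, genes, n, halfWidth = 250L,
                                  distanceRange = c(250L, 1250L),
                                  seed = 1L) {
    set.seed(seed)
    lens <- setNames(Biostrings::width(genome), names(genome))
    idx <- sample(seq_along(genes), n, replace = n > length(genes))
    d <- sample(seq.int(distanceRange[1L], distanceRange[2L]), n,
                replace = TRUE)
    sign <- ifelse(as.character(strand(genes))[idx] == "+", 1L, -1L)
    center <- mcols(genes)$tss[idx] - d * sign
    chrom <- as.character(seqnames(genes))[idx]
    center <- pmax(halfWidth + 1L, pmin(center,
                                        as.integer(lens[chrom]) - halfWidth))
    seqs <- DNAStringSet(vapply(seq_len(n), function(i)
        as.character(subseq(genome[[chrom[i]]],
                            center[i] - halfWidth, center[i] + halfWidth)),
        ""))
    names(seqs) <- sprintf("random_%04d", seq_len(n))
    seqs
}

#' Motif enrichment in peaks versus random promoters
#'
#' Over a grid of score thresholds (0.5-bit steps from 0 to the PSSM
#' maximum), the fraction of peak and of random sequences whose best
#' score reaches each threshold; the enrichment ratio r = (peak match
#' frequency) / (random match frequency) at the match p-value
#' threshold; the Pearson correlation of per-peak best score with peak
#' height; and an unpaired two-sample t-test comparing the two
#' frequency profiles.
#'
#' @param peakScan best-only \code{\link{scanPeaks}} output (must carry
#'   \code{height}).
#' @param randomScan best-only \code{\link{scanSequences}} output for
#'   the matched random windows.
#' @param null the \code{\link{scoreNull}} used for both scans.
#' @param pThreshold match p-value threshold defining r (default 1e-5).
#' @param gridStep threshold grid step in bits (default 0.5).
#' @return a \linkS4class{MotifEnrichment}.
#' @export
enrichmentCurve <- function(peakScan, randomScan, null, pThreshold = 1e-5,
                            gridStep = 0.5) {
    ps <- peakScan$score[!is.na(peakScan$score)]
    rs <- randomScan$score[!is.na(randomScan$score)]
    top <- max(c(ps, rs, 1))
    thresholds <- seq(0, ceiling(top / gridStep) * gridStep, by = gridStep)
    peakFreq <- vapply(thresholds, function(t) mean(ps >= t), 0)
    randomFreq <- vapply(thresholds, function(t) mean(rs >= t), 0)
    sigKeys <- null@keys[null@tailProbs <= pThreshold]
    matchThreshold <- if (length(sigKeys))
        min(sigKeys) * null@binWidth else Inf
    fp <- mean(peakScan$significant, na.rm = TRUE)
    fr <- mean(randomScan$significant, na.rm = TRUE)
    r <- if (fr == 0) {
        if (fp == 0) NaN else Inf
    } else fp / fr
    pear <- if (length(unique(peakScan$height)) > 1L &&
                sum(!is.na(peakScan$score)) > 2L)
        cor(peakScan$score, peakScan$height, use = "complete.obs")
    else NA_real_
    tp <- tryCatch(t.test(peakFreq, randomFreq)$p.value,
                   error = function(e) NA_real_)
    new("MotifEnrichment", thresholds = thresholds, peakFreq = peakFreq,
        randomFreq = randomFreq, r = r, matchThreshold = matchThreshold,
        pearsonRVsHeight = pear, tTestP = tp)
}

#' Strand-aware inter-motif distances
#'
#' For every sequence carrying a match for both motifs, the signed
#' distance of the other motif's central coordinate from the reference
#' motif's, in promoter (transcription) orientation:
#' \eqn{d = (c_{other} - c_{ref}) \times s} where s is +1/-1 for
#' promoters of +/- strand genes.  Also usable with summit positions as
#' the reference.  Distances are histogrammed in fixed-width bins.
#'
#' @param refMatches,otherMatches \code{DataFrame}s with \code{seq_id}
#'   and a center column (\code{genomic_center} preferred,
#'   \code{center} otherwise).
#' @param promoterStrand named vector of \code{"+"}/\code{"-"} per
#'   \code{seq_id} (default all \code{"+"}).
#' @param binWidth histogram bin width in bp (default 10).
#' @return a list: \code{distances} (named numeric), \code{histogram}
#'   (a data.frame of bin lower edges, centers and counts),
#'   \code{mode} (center of the modal bin; \code{NA} when empty).
#' @export
intermotifDistances <- function(refMatches, otherMatches,
                                promoterStrand = NULL, binWidth = 10L) {
    centerOf <- function(df) {
        v <- if ("genomic_center" %in% colnames(df)) df$genomic_center
        else df$center
        setNames(v, df$seq_id)
    }
    cr <- centerOf(refMatches)
    co <- centerOf(otherMatches)
    shared <- intersect(names(cr)[!is.na(cr)], names(co)[!is.na(co)])
    if (length(shared) == 0L)
        return(list(distances = numeric(0),
                    histogram = data.frame(lower = numeric(0),
                                           center = numeric(0),
                                           count = integer(0)),
                    mode = NA_real_))
    sign <- rep(1L, length(shared))
    if (!is.null(promoterStrand))
        sign <- ifelse(promoterStrand[shared] == "-", -1L, 1L)
    d <- (co[shared] - cr[shared]) * sign
    lower <- floor(d / binWidth) * binWidth
    tab <- table(lower)
    hist <- data.frame(lower = as.numeric(names(tab)),
                       center = as.numeric(names(tab)) + binWidth / 2,
                       count = as.integer(tab))
    mode <- hist$center[which.max(hist$count)]
    list(distances = d, histogram = hist, mode = mode)
}
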