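suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(S4Vectors)
})

# peaks GRanges in the package's layout
makePeaks <- function(chrom, start, end, summit,
                      height = 1, pvalue = 1e-6,
                      condition = "daf2",
                      ids = sprintf("pk%03d", seq_along(start))) {
    gr <- GRanges(chrom, IRanges::IRanges(start, end))
    mcols(gr)$peak_id <- ids
    mcols(gr)$summit <- as.integer(summit)
    mcols(gr)$height <- rep_len(as.numeric(height), length(gr))
    mcols(gr)$pvalue <- rep_len(pvalue, length(gr))
    mcols(gr)$condition <- rep_len(condition, length(gr))
    gr
}

# single-exon gene models
makeGenes <- function(chrom, start, end, strand,
                      ids = sprintf("g%03d", seq_along(start)),
                      coding = TRUE) {
    gr <- GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
    mcols(gr)$gene_id <- ids
    mcols(gr)$tss <- as.integer(ifelse(strand == "+", start, end))
    mcols(gr)$coding <- rep_len(coding, length(gr))
    mcols(gr)$exons <- IRanges::IRangesList(lapply(seq_along(start), function(i)
        IRanges::IRanges(start[i], end[i])))
    gr
}

makeReads <- function(chrom, start, end, strand, sample = "s") {
    gr <- GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
    mcols(gr)$sample <- rep_len(sample, length(gr))
    gr
}

makeTrack <- function(values, binWidth = 25L, stage = "per_million",
                      sample = "s") {
    if (!is.list(values)) values <- list(chrT = values)
    new("BinTrack", sample = sample, binWidth = as.integer(binWidth),
        stage = stage,
        values = S4Vectors::SimpleList(values),
        chromLengths = stats::setNames(
            lengths(values) * as.integer(binWidth), names(values)))
}

# exactly uniform order-0 background (handy for closed-form checks)
uniformBg <- function() {
    new("MarkovBackground", order = 0L,
        conditional = matrix(0.25, 1L, 4L,
                             dimnames = list("", c("A", "C", "G", "T"))),
        contextProbs = 1,
        marginal = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
        label = "uniform")
}

randomDna <- function(n, seed = NULL,
                      probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(names(probs), n, replace = TRUE, prob = probs),
          collapse = "")
}

revcompStr <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# small, fast simulation settings for unit tests
tinyConfig <- function(...) {
    args <- list(seed = 7L, nChroms = 1L, chromLength = 250000L,
                 nGenes = 40L, readsPerSample = 40000L)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(simulationConfig, args)
}
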