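#' @importFrom GenomicRanges GRanges seqnames start end strand width mcols
#'   mcols<- strand<- findOverlaps pintersect
#' @importFrom IRanges IRanges IRangesList ranges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   reverseComplement oligonucleotideFrequency subseq
#' @importFrom utils read.table write.table
NULL

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return an uppercase \code{DNAStringSet}, one entry per chromosome,
#'   with unique names (the first whitespace-delimited token of each
#'   FASTA header).
#' @export
readGenome <- function(path) {
    seqs <- readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stop("duplicate chromosome names in ", path)
    Biostrings::DNAStringSet(toupper(seqs))
}

#' Write a genome to FASTA
#'
#' @param genome a \code{DNAStringSet}.
#' @param path output file.
#' @export
writeGenome <- function(genome, path) {
    writeXStringSet(genome, path)
    invisible(path)
}

.gffAttr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

#' Read gene models from GFF3
#'
#' Parses \code{gene} and \code{exon} features (all other feature types
#' are ignored).  Exons are attached to their gene via the \code{Parent}
#' attribute; genes without explicit exons get a single exon spanning
#' the gene.  The TSS is derived from strand: the leftmost exon start on
#' \code{+}, the rightmost exon end on \code{-} (1-based).  A gene is
#' flagged coding unless its \code{biotype} attribute says otherwise.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param chromLengths optional named vector of chromosome lengths; when
#'   given, exons outside chromosome bounds raise a validation error.
#' @return a \code{GRanges} of gene spans with metadata columns
#'   \code{gene_id}, \code{tss} (1-based), \code{coding} (logical) and
#'   \code{exons} (an \code{IRangesList} aligned with the genes).
#' @export
readAnnotation <- function(path, chromLengths = NULL) {
    lines <- readLines(path)
    body <- !grepl("^#", lines) & nzchar(lines)
    nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (any(nfield != 9L)) {
        bad <- which(body)[which(nfield != 9L)[1L]]
        stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields, found %d",
                     bad, path, nfield[which(nfield != 9L)[1L]]))
    }
    if (!any(body))
        stop("no feature lines in ", path)
    tab <- read.table(text = lines[body], sep = "\t", quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      col.names = c("seqid", "source", "type", "start", "end",
                                    "score", "strand", "phase", "attributes"))
    genes <- tab[tab$type == "gene", , drop = FALSE]
    exons <- tab[tab$type == "exon", , drop = FALSE]
    if (nrow(genes) == 0L)
        stop("no gene features in ", path)
    gene_id <- .gffAttr(genes$attributes, "ID")
    if (anyNA(gene_id))
        stop("gene feature without ID attribute in ", path)
    if (anyDuplicated(gene_id))
        stop("duplicate gene IDs in ", path)
    biotype <- .gffAttr(genes$attributes, "biotype")
    coding <- is.na(biotype) | biotype == "protein_coding"
    parent <- .gffAttr(exons$attributes, "Parent")

    exon_list <- vector("list", nrow(genes))
    names(exon_list) <- gene_id
    for (i in seq_len(nrow(genes))) {
        idx <- which(parent == gene_id[i])
        if (length(idx)) {
            ir <- IRanges(start = exons$start[idx], end = exons$end[idx])
            ir <- ir[order(IRanges::start(ir))]
            if (length(ir) > 1L &&
                any(IRanges::start(ir)[-1L] <= IRanges::end(ir)[-length(ir)]))
                stop("overlapping exons for gene ", gene_id[i])
        } else {
            ir <- IRanges(start = genes$start[i], end = genes$end[i])
        }
        exon_list[[i]] <- ir
    }
    exons_irl <- IRangesList(exon_list)
    span_start <- vapply(exon_list, function(ir) min(IRanges::start(ir)), 0)
    span_end <- vapply(exon_list, function(ir) max(IRanges::end(ir)), 0)
    if (!all(genes$strand %in% c("+", "-")))
        stop("gene strand must be + or - in ", path)
    tss <- ifelse(genes$strand == "+", span_start, span_end)
    if (!is.null(chromLengths)) {
        lim <- chromLengths[genes$seqid]
        if (anyNA(lim))
            stop("genes on chromosomes absent from the genome: ",
                 paste(unique(genes$seqid[is.na(lim)]), collapse = ", "))
        if (any(span_end > lim) || any(span_start < 1))
            stop("exon outside chromosome bounds for gene(s): ",
                 paste(gene_id[span_end > lim | span_start < 1], collapse = ", "))
    }
    gr <- GRanges(genes$seqid, IRanges(span_start, span_end),
                  strand = genes$strand)
    mcols(gr)$gene_id <- gene_id
    mcols(gr)$tss <- as.integer(tss)
    mcols(gr)$coding <- coding
    mcols(gr)$exons <- exons_irl
    gr
}

#' Write gene models to GFF3
#'
#' Inverse of \code{\link{readAnnotation}}: emits one \code{gene} line
#' and one \code{exon} line per exon, with 1-based inclusive
#' coordinates.
#'
#' @param genes a \code{GRanges} as returned by \code{readAnnotation}.
#' @param path output file.
#' @export
writeAnnotation <- function(genes, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (i in seq_along(genes)) {
        gid <- mcols(genes)$gene_id[i]
        bio <- if (mcols(genes)$coding[i]) "protein_coding" else "ncRNA"
        writeLines(sprintf("%s\tFoxoChIP\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                           as.character(seqnames(genes)[i]), start(genes)[i],
                           end(genes)[i], as.character(strand(genes)[i]),
                           gid, bio), con)
        ex <- mcols(genes)$exons[[i]]
        for (j in seq_along(ex)) {
            writeLines(sprintf("%s\tFoxoChIP\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                               as.character(seqnames(genes)[i]),
                               IRanges::start(ex)[j], IRanges::end(ex)[j],
                               as.character(strand(genes)[i]), gid), con)
        }
    }
    invisible(path)
}

#' Read called peaks from narrowPeak or BED
#'
#' narrowPeak column 10 is the summit offset from the interval start; an
#' offset of \code{-1} means the summit is unknown and the interval
#' midpoint (rounded down) is used.  Plain BED input always uses the
#' midpoint rule, with the score column as the peak height.
#'
#' @param path narrowPeak or BED file (0-based half-open, as BED).
#' @param format \code{"narrowPeak"} or \code{"bed"}; default guessed
#'   from the file extension.
#' @param condition sample label stored in the \code{condition} column.
#' @return a \code{GRanges} with metadata columns \code{peak_id},
#'   \code{summit} (1-based), \code{height}, \code{pvalue},
#'   \code{condition}.
#' @export
readPeaks <- function(path, format = c("auto", "narrowPeak", "bed"),
                      condition = NA_character_) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.narrowPeak$", path)) "narrowPeak" else "bed"
    if (format == "narrowPeak") {
        gr <- rtracklayer::import(path, format = "BED",
            extraCols = c(signalValue = "numeric", pValue = "numeric",
                          qValue = "numeric", peak = "integer"))
        offset <- mcols(gr)$peak
        summit <- ifelse(offset >= 0L,
                         start(gr) + offset,
                         start(gr) + (width(gr) - 1L) %/% 2L)
        height <- mcols(gr)$signalValue
        lp <- mcols(gr)$pValue
        pvalue <- ifelse(is.na(lp) | lp < 0, 1, pmin(1, 10^(-lp)))
    } else {
        gr <- rtracklayer::import(path, format = "BED")
        summit <- start(gr) + (width(gr) - 1L) %/% 2L
        height <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else
            rep(0, length(gr))
        pvalue <- rep(1, length(gr))
    }
    if (any(summit < start(gr) | summit > end(gr)))
        stop("summit outside peak interval in ", path)
    if (any(height < 0, na.rm = TRUE))
        stop("negative peak height in ", path)
    nm <- mcols(gr)$name
    if (is.null(nm) || anyNA(nm))
        nm <- sprintf("peak_%05d", seq_along(gr))
    out <- GRanges(seqnames(gr), ranges(gr))
    mcols(out)$peak_id <- nm
    mcols(out)$summit <- as.integer(summit)
    mcols(out)$height <- as.numeric(height)
    mcols(out)$pvalue <- as.numeric(pvalue)
    mcols(out)$condition <- rep(condition, length(out))
    out
}

#' Write peaks to narrowPeak
#'
#' Inverse of \code{\link{readPeaks}} (narrowPeak flavour): 0-based
#' half-open intervals, summit written as an offset from the start,
#' p-value written as \eqn{-\log_{10} p}.
#'
#' @param peaks a peaks \code{GRanges} (see \code{\link{readPeaks}}).
#' @param path output file.
#' @export
writePeaks <- function(peaks, path) {
    df <- data.frame(
        chrom = as.character(seqnames(peaks)),
        start = start(peaks) - 1L,
        end = end(peaks),
        name = mcols(peaks)$peak_id,
        score = 0L,
        strand = ".",
        signalValue = mcols(peaks)$height,
        pValue = -log10(pmax(mcols(peaks)$pvalue, 1e-300)),
        qValue = -1,
        peak = mcols(peaks)$summit - start(peaks)
    )
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

.cigarRefWidth <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
    vapply(ops, function(o) {
        n <- as.integer(sub("[MIDNSHP=X]", "", o))
        type <- sub("[0-9]+", "", o)
        sum(n[type %in% c("M", "D", "N", "=", "X")])
    }, 0L)
}

#' Read aligned reads from BED6 or SAM text
#'
#' BED6 is the primary path; every record must carry a \code{+}/\code{-}
#' strand (required downstream for read shifting).  SAM text support is
#' limited to mapped primary records: unmapped (FLAG 0x4), secondary
#' (0x100) and supplementary (0x800) records are skipped and the skip
#' count reported via \code{message()} and the \code{"skipped"}
#' attribute.
#'
#' @param path BED6 or SAM file.
#' @param format \code{"bed"} or \code{"sam"}; default guessed from the
#'   extension.
#' @param sample sample label stored in the \code{sample} column.
#' @return a \code{GRanges} (1-based closed) with strand and a
#'   \code{sample} metadata column.
#' @export
readReads <- function(path, format = c("auto", "bed", "sam"),
                      sample = NA_character_) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.sam$", path)) "sam" else "bed"
    if (format == "bed") {
        gr <- rtracklayer::import(path, format = "BED")
        if (any(!as.character(strand(gr)) %in% c("+", "-")))
            stop("missing strand in ", path,
                 ": strand is required for read shifting")
        skipped <- 0L
    } else {
        lines <- readLines(path)
        lines <- lines[!grepl("^@", lines) & nzchar(lines)]
        fields <- strsplit(lines, "\t", fixed = TRUE)
        flag <- vapply(fields, function(f) as.integer(f[2]), 0L)
        drop <- bitwAnd(flag, 4L) > 0L | bitwAnd(flag, 256L) > 0L |
            bitwAnd(flag, 2048L) > 0L
        skipped <- sum(drop)
        fields <- fields[!drop]
        flag <- flag[!drop]
        if (length(fields) == 0L) {
            gr <- GRanges()
        } else {
            chrom <- vapply(fields, `[`, "", 3L)
            pos <- vapply(fields, function(f) as.integer(f[4]), 0L)
            cigar <- vapply(fields, `[`, "", 6L)
            w <- .cigarRefWidth(cigar)
            gr <- GRanges(chrom, IRanges(pos, width = pmax(w, 1L)),
                          strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"))
        }
        if (skipped > 0L)
            message(skipped, " unmapped/secondary/supplementary SAM record(s) skipped")
    }
    mcols(gr)$sample <- rep(sample, length(gr))
    attr(gr, "skipped") <- skipped
    gr
}

#' Write reads to BED6
#'
#' @param reads a reads \code{GRanges}.
#' @param path output file.
#' @export
writeReadsBed <- function(reads, path) {
    nm <- mcols(reads)$name
    if (is.null(nm)) nm <- sprintf("read_%07d", seq_along(reads))
    df <- data.frame(
        chrom = as.character(seqnames(reads)),
        start = start(reads) - 1L,
        end = end(reads),
        name = nm,
        score = 0L,
        strand = as.character(strand(reads))
    )
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Export a BinTrack as fixed-step wiggle
#'
#' One \code{fixedStep} block per chromosome, 1-based starts, step and
#' span equal to the bin width.
#'
#' @param track a \linkS4class{BinTrack}.
#' @param path output file.
#' @export
exportWig <- function(track, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=wiggle_0 name=\"%s\"", track@sample), con)
    for (chrom in names(track@values)) {
        writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                           chrom, track@binWidth, track@binWidth), con)
        writeLines(format(track@values[[chrom]], trim = TRUE,
                          scientific = FALSE), con)
    }
    invisible(path)
}

#' Cross-file chromosome consistency check
#'
#' Verifies that every chromosome referenced by the annotation, peaks or
#' reads exists in the genome; mismatches are a hard error listing the
#' offending names (never silently dropped).
#'
#' @param genome a \code{DNAStringSet}.
#' @param ... any number of \code{GRanges} objects to check.
#' @return invisibly \code{TRUE}.
#' @export
validateChromosomes <- function(genome, ...) {
    known <- names(genome)
    for (gr in list(...)) {
        used <- unique(as.character(seqnames(gr)))
        bad <- setdiff(used, known)
        if (length(bad))
            stop("chromosome name(s) absent from the genome: ",
                 paste(bad, collapse = ", "))
    }
    invisible(TRUE)
}
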