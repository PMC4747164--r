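#' @importFrom stats rnorm runif rnbinom rlnorm
NULL

.CONDITIONS <- c("WT", "daf2", "daf16daf2")

#' Construct a simulation configuration
#'
#' Defines the synthetic study: a toy genome with tiled gene models, a
#' planted primary motif (the FOXO/DAF-16 binding element, consensus
#' \code{GTAAACAA}) and a co-motif at a fixed strand-aware offset in a
#' subset of bound promoters, ChIP fragments piled around the planted
#' summits over a uniform background (with a matched uniform input
#' library) for three conditions -- wild type, the low-insulin-signalling
#' \code{daf2} mutant (full enrichment) and the \code{daf16daf2} double
#' mutant (no factor, background only) -- and negative-binomial
#' expression counts in which activation is coupled to promoter-proximal
#' binding.
#'
#' @param seed integer root seed; all randomness in the generator flows
#'   from it.
#' @param nChroms,chromLength genome shape.
#' @param nGenes number of gene models tiled across the genome.
#' @param gcContent background GC fraction.
#' @param motifConsensus,comotifConsensus planted consensus strings.
#' @param comotifOffset signed bp offset of the co-motif center from the
#'   primary motif center, in promoter (transcription) orientation.
#' @param comotifFraction fraction of bound promoters that also get the
#'   co-motif.
#' @param fractionBoundGenes fraction of genes given a planted
#'   promoter-proximal summit plus motif.
#' @param fractionActivated fraction of bound genes transcriptionally
#'   activated in \code{daf2}.
#' @param backgroundActivatedFraction fraction of unbound genes
#'   activated (indirect targets).
#' @param fractionRepressed fraction of unbound, non-activated genes
#'   repressed in \code{daf2}.
#' @param plantedSummitDistanceBands upstream TSS distances (bp) cycled
#'   over the bound genes.
#' @param fragmentLength,readLength ChIP fragment and read lengths (bp).
#' @param chipEnrichment fold enrichment over background at planted
#'   summits in \code{daf2}; the \code{daf16daf2} condition is forced to
#'   background only.
#' @param wtEnrichmentRatio fraction of the \code{daf2} excess
#'   enrichment retained in wild type.
#' @param readsPerSample single-end reads per library.
#' @param totalMappedReads total mapped reads per RNA-seq library.  The
#'   simulated genes are a small subset of a transcriptome, so the
#'   library total is fixed at a transcriptome-scale depth rather than
#'   at the column sum of the simulated genes; this keeps proportion-
#'   and RPKM-based fold changes free of compositional bias.
#' @param nbMean,nbDispersion negative-binomial expression model (mean
#'   of the per-gene lognormal baseline; dispersion alpha with
#'   \code{size = 1/alpha}).
#' @param activationFold expression effect size in \code{daf2}.
#' @param nReplicates RNA-seq replicates per condition.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nChroms = 2L,
                             chromLength = 800000L,
                             nGenes = 300L,
                             gcContent = 0.36,
                             motifConsensus = "TTGTAAACAA",
                             comotifConsensus = "ACTGATAAGA",
                             comotifOffset = 35L,
                             comotifFraction = 0.6,
                             fractionBoundGenes = 0.3,
                             fractionActivated = 0.8,
                             backgroundActivatedFraction = 0.05,
                             fractionRepressed = 0.1,
                             plantedSummitDistanceBands = c(250L, 750L),
                             fragmentLength = 175L,
                             readLength = 36L,
                             chipEnrichment = 10,
                             wtEnrichmentRatio = 0.5,
                             readsPerSample = 200000L,
                             totalMappedReads = 2000000L,
                             nbMean = 100,
                             nbDispersion = 0.02,
                             activationFold = 4,
                             nReplicates = 3L) {
    new("SimulationConfig",
        seed = as.integer(seed),
        nChroms = as.integer(nChroms),
        chromLength = as.integer(chromLength),
        nGenes = as.integer(nGenes),
        gcContent = gcContent,
        motifConsensus = motifConsensus,
        comotifConsensus = comotifConsensus,
        comotifOffset = as.integer(comotifOffset),
        comotifFraction = comotifFraction,
        fractionBoundGenes = fractionBoundGenes,
        fractionActivated = fractionActivated,
        backgroundActivatedFraction = backgroundActivatedFraction,
        fractionRepressed = fractionRepressed,
        plantedSummitDistanceBands = as.integer(plantedSummitDistanceBands),
        fragmentLength = as.integer(fragmentLength),
        readLength = as.integer(readLength),
        chipEnrichment = chipEnrichment,
        wtEnrichmentRatio = wtEnrichmentRatio,
        readsPerSample = as.integer(readsPerSample),
        totalMappedReads = as.integer(totalMappedReads),
        nbMean = nbMean,
        nbDispersion = nbDispersion,
        activationFold = activationFold,
        nReplicates = as.integer(nReplicates))
}

.GENE_LENGTH <- 1500L
.EXONS_REL <- IRanges::IRanges(start = c(1L, 901L), end = c(600L, 1500L))

#' Simulate a toy genome with planted motifs and ground truth
#'
#' Background bases are i.i.d. at the configured GC content; genes are
#' tiled at fixed spacing (>= 5 kb) with alternating random strand.
#' Each bound gene gets the primary motif planted with its central
#' coordinate at the configured upstream distance from the TSS (motif
#' strand uniform), and a configured subset additionally gets the
#' co-motif at \code{comotifOffset} from the primary motif center (in
#' transcription orientation).  Deterministic under the config seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a list with elements \code{genome} (\code{DNAStringSet}),
#'   \code{genes} (a \code{GRanges} as from
#'   \code{\link{readAnnotation}}) and \code{truth} (a list of two
#'   \code{DataFrame}s, \code{genes} and \code{motifs}).
#' @export
simulateGenome <- function(config) {
    validObject(config)
    set.seed(config@seed)
    chromNames <- sprintf("chrS%d", seq_len(config@nChroms))
    gc <- config@gcContent
    baseProbs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chromChars <- lapply(seq_len(config@nChroms), function(i)
        sample(names(baseProbs), config@chromLength, replace = TRUE,
               prob = baseProbs))

    genesPerChrom <- ceiling(config@nGenes / config@nChroms)
    margin <- 4000L
    spacing <- (config@chromLength - 2L * margin) %/% genesPerChrom
    if (spacing < 5000L || spacing - .GENE_LENGTH < 2600L)
        stop("genes do not fit in genome: increase chromLength or reduce nGenes")

    n <- config@nGenes
    idx <- seq_len(n) - 1L
    chromI <- idx %/% genesPerChrom + 1L
    posI <- idx %% genesPerChrom
    geneStart <- margin + posI * spacing + 1L
    strandSign <- sample(c(1L, -1L), n, replace = TRUE)
    geneStrand <- ifelse(strandSign == 1L, "+", "-")
    geneEnd <- geneStart + .GENE_LENGTH - 1L
    tss <- ifelse(strandSign == 1L, geneStart, geneEnd)
    geneId <- sprintf("gene%04d", seq_len(n))

    exonList <- lapply(seq_len(n), function(i)
        IRanges::shift(.EXONS_REL, geneStart[i] - 1L))
    genes <- GRanges(chromNames[chromI], IRanges(geneStart, geneEnd),
                     strand = geneStrand)
    mcols(genes)$gene_id <- geneId
    mcols(genes)$tss <- as.integer(tss)
    mcols(genes)$coding <- rep(TRUE, n)
    mcols(genes)$exons <- IRangesList(exonList)

    nBound <- round(n * config@fractionBoundGenes)
    boundIdx <- sort(sample.int(n, nBound))
    bound <- logical(n)
    bound[boundIdx] <- TRUE
    bands <- config@plantedSummitDistanceBands
    bandDist <- rep(NA_integer_, n)
    if (nBound > 0)
        bandDist[boundIdx] <- bands[(seq_len(nBound) - 1L) %% length(bands) + 1L]

    plant <- function(chars, center, consensus, motifStrand) {
        L <- nchar(consensus)
        s <- center - (L - 1L) %/% 2L
        seqc <- if (motifStrand == "+") consensus else
            as.character(reverseComplement(Biostrings::DNAString(consensus)))
        chars[s:(s + L - 1L)] <- strsplit(seqc, "")[[1]]
        chars
    }

    summit <- rep(NA_integer_, n)
    motifCenter <- rep(NA_integer_, n)
    motifStrand <- rep(NA_character_, n)
    comotifCenter <- rep(NA_integer_, n)
    comotifStrand <- rep(NA_character_, n)
    nCo <- round(nBound * config@comotifFraction)
    coIdx <- if (nCo > 0) boundIdx[sort(sample.int(nBound, nCo))] else integer(0)
    if (abs(config@comotifOffset) <= max(nchar(config@motifConsensus),
                                         nchar(config@comotifConsensus)))
        stop("comotifOffset too small: planted motifs would overlap")
    for (i in boundIdx) {
        center <- tss[i] - bandDist[i] * strandSign[i]
        ms <- sample(c("+", "-"), 1L)
        chromChars[[chromI[i]]] <- plant(chromChars[[chromI[i]]], center,
                                         config@motifConsensus, ms)
        summit[i] <- center
        motifCenter[i] <- center
        motifStrand[i] <- ms
        if (i %in% coIdx) {
            center2 <- center + config@comotifOffset * strandSign[i]
            ms2 <- sample(c("+", "-"), 1L)
            chromChars[[chromI[i]]] <- plant(chromChars[[chromI[i]]], center2,
                                             config@comotifConsensus, ms2)
            comotifCenter[i] <- center2
            comotifStrand[i] <- ms2
        }
    }

    exprClass <- rep("unchanged", n)
    nActBound <- round(nBound * config@fractionActivated)
    if (nActBound > 0)
        exprClass[boundIdx[sample.int(nBound, nActBound)]] <- "activated"
    unbound <- which(!bound)
    nActBg <- round(length(unbound) * config@backgroundActivatedFraction)
    if (nActBg > 0)
        exprClass[unbound[sample.int(length(unbound), nActBg)]] <- "activated"
    pool <- which(!bound & exprClass == "unchanged")
    nRep <- round(length(pool) * config@fractionRepressed)
    if (nRep > 0)
        exprClass[pool[sample.int(length(pool), nRep)]] <- "repressed"

    truthGenes <- DataFrame(
        gene_id = geneId,
        chrom = chromNames[chromI],
        strand = geneStrand,
        tss = as.integer(tss),
        bound = bound,
        summit = summit,
        band_distance = bandDist,
        expr_class = exprClass)
    hasMotif <- !is.na(motifCenter)
    hasCo <- !is.na(comotifCenter)
    truthMotifs <- DataFrame(
        gene_id = c(geneId[hasMotif], geneId[hasCo]),
        motif = c(rep("primary", sum(hasMotif)), rep("comotif", sum(hasCo))),
        chrom = c(chromNames[chromI][hasMotif], chromNames[chromI][hasCo]),
        center = c(motifCenter[hasMotif], comotifCenter[hasCo]),
        strand = c(motifStrand[hasMotif], comotifStrand[hasCo]),
        promoter_strand = c(geneStrand[hasMotif], geneStrand[hasCo]))

    genome <- DNAStringSet(vapply(chromChars, paste, "", collapse = ""))
    names(genome) <- chromNames
    list(genome = genome, genes = genes,
         truth = list(genes = truthGenes, motifs = truthMotifs))
}

.enrichmentMultiplier <- function(config, condition) {
    switch(condition,
        WT = 1 + (config@chipEnrichment - 1) * config@wtEnrichmentRatio,
        daf2 = config@chipEnrichment,
        daf16daf2 = 1)
}

.readsFromMidpoints <- function(mid, chrom, chromLen, config) {
    h <- as.integer(round(config@fragmentLength / 2))
    side <- sample(c("+", "-"), length(mid), replace = TRUE)
    start <- ifelse(side == "+", mid - h, mid + h - config@readLength + 1L)
    lim <- chromLen[chrom] - config@readLength + 1L
    start <- pmax(1L, pmin(as.integer(start), as.integer(lim)))
    GRanges(chrom, IRanges(start, width = config@readLength), strand = side)
}

#' Simulate ChIP and input reads plus called peaks
#'
#' For each condition, enriched fragment midpoints are drawn as
#' Normal(planted summit, sd = fragmentLength / 4) and background
#' midpoints uniformly over the genome; each fragment is reported as a
#' single-end read from a uniformly chosen end, with strand set
#' accordingly.  The number of enriched fragments per summit is chosen
#' so that local coverage at a summit is \code{chipEnrichment}-fold the
#' genome-wide background (scaled by \code{wtEnrichmentRatio} in WT); in
#' \code{daf16daf2} the multiplier is forced to 1, i.e. background
#' only.  Matched input libraries are purely uniform.  Emitted peaks
#' carry the planted summit and the enrichment multiplier as height.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param sim the result of \code{\link{simulateGenome}}.
#' @return a list with per-condition lists \code{chip}, \code{input}
#'   (reads \code{GRanges}) and \code{peaks} (peaks \code{GRanges};
#'   empty for \code{daf16daf2}).
#' @export
simulateChip <- function(config, sim) {
    truth <- sim$truth$genes
    chromLen <- stats::setNames(Biostrings::width(sim$genome),
                                names(sim$genome))
    genomeSize <- sum(chromLen)
    summits <- truth$summit[truth$bound]
    summitChrom <- truth$chrom[truth$bound]
    chip <- list(); input <- list(); peaks <- list()
    for (k in seq_along(.CONDITIONS)) {
        cond <- .CONDITIONS[k]
        set.seed(config@seed + 100L + k)
        mult <- .enrichmentMultiplier(config, cond)
        nPerPeak <- round((mult - 1) * config@readsPerSample *
                          config@fragmentLength / genomeSize)
        nEnriched <- nPerPeak * length(summits)
        nBackground <- config@readsPerSample - nEnriched

        bgChrom <- sample(names(chromLen), nBackground, replace = TRUE,
                          prob = chromLen / genomeSize)
        bgMid <- as.integer(ceiling(runif(nBackground) * chromLen[bgChrom]))
        if (nEnriched > 0) {
            enChrom <- rep(summitChrom, each = nPerPeak)
            enMid <- as.integer(round(rnorm(nEnriched,
                                            mean = rep(summits, each = nPerPeak),
                                            sd = config@fragmentLength / 4)))
            enMid <- pmax(1L, pmin(enMid, as.integer(chromLen[enChrom])))
            mid <- c(bgMid, enMid); chrom <- c(bgChrom, enChrom)
        } else {
            mid <- bgMid; chrom <- bgChrom
        }
        gr <- .readsFromMidpoints(mid, chrom, chromLen, config)
        mcols(gr)$sample <- paste0("chip_", cond)
        chip[[cond]] <- gr

        inChrom <- sample(names(chromLen), config@readsPerSample,
                          replace = TRUE, prob = chromLen / genomeSize)
        inMid <- as.integer(ceiling(runif(config@readsPerSample) *
                                    chromLen[inChrom]))
        gri <- .readsFromMidpoints(inMid, inChrom, chromLen, config)
        mcols(gri)$sample <- paste0("input_", cond)
        input[[cond]] <- gri

        if (mult > 1 && length(summits)) {
            pk <- GRanges(summitChrom,
                          IRanges(pmax(1L, summits - config@fragmentLength),
                                  pmin(as.integer(chromLen[summitChrom]),
                                       summits + config@fragmentLength)))
            mcols(pk)$peak_id <- sprintf("%s_peak_%04d", cond,
                                         seq_along(summits))
            mcols(pk)$summit <- as.integer(summits)
            mcols(pk)$height <- rep(mult, length(summits))
            mcols(pk)$pvalue <- rep(1e-10, length(summits))
            mcols(pk)$condition <- rep(cond, length(summits))
        } else {
            pk <- GRanges()
        }
        peaks[[cond]] <- pk
    }
    list(chip = chip, input = input, peaks = peaks)
}

#' Simulate negative-binomial expression counts
#'
#' Per-gene lognormal baselines around \code{nbMean}; counts are
#' negative binomial with \code{size = 1/nbDispersion}.  Activated
#' genes get \code{activationFold} times the baseline in \code{daf2}
#' only; repressed genes \code{1/activationFold}; every gene is at
#' baseline in WT and in \code{daf16daf2} (the factor-null condition),
#' making the planted response strictly factor-dependent.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param sim the result of \code{\link{simulateGenome}}.
#' @return a \code{SummarizedExperiment} count table (see
#'   \code{\link{countTable}}) with \code{nReplicates} columns per
#'   condition.
#' @export
simulateExpression <- function(config, sim) {
    set.seed(config@seed + 200L)
    truth <- sim$truth$genes
    n <- nrow(truth)
    baseline <- rlnorm(n, meanlog = log(config@nbMean), sdlog = 0.8)
    size <- 1 / config@nbDispersion
    conds <- rep(.CONDITIONS, each = config@nReplicates)
    samples <- sprintf("%s_rep%d", conds,
                       rep(seq_len(config@nReplicates), times = 3L))
    effect <- matrix(1, n, length(conds))
    effect[truth$expr_class == "activated", conds == "daf2"] <-
        config@activationFold
    effect[truth$expr_class == "repressed", conds == "daf2"] <-
        1 / config@activationFold
    counts <- matrix(rnbinom(n * length(conds), size = size,
                             mu = baseline * effect),
                     nrow = n, dimnames = list(truth$gene_id, samples))
    exonLength <- vapply(mcols(sim$genes)$exons, function(ir)
        sum(IRanges::width(ir)), 0L)
    totals <- pmax(colSums(counts), config@totalMappedReads)
    countTable(counts, condition = conds, exonLength = exonLength,
               totals = totals)
}

#' Write a full synthetic data set to disk
#'
#' Emits \code{genome.fa}, \code{genes.gff3},
#' \code{reads_<cond>.bed}, \code{input_<cond>.bed},
#' \code{peaks_<cond>.narrowPeak}, \code{counts.tsv},
#' \code{samples.tsv} and \code{truth.json} under \code{dir}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated in-memory objects
#'   (\code{sim}, \code{chip}, \code{counts}).
#' @export
writeSimulation <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateGenome(config)
    chip <- simulateChip(config, sim)
    counts <- simulateExpression(config, sim)
    writeGenome(sim$genome, file.path(dir, "genome.fa"))
    writeAnnotation(sim$genes, file.path(dir, "genes.gff3"))
    for (cond in .CONDITIONS) {
        writeReadsBed(chip$chip[[cond]],
                      file.path(dir, sprintf("reads_%s.bed", cond)))
        writeReadsBed(chip$input[[cond]],
                      file.path(dir, sprintf("input_%s.bed", cond)))
        if (length(chip$peaks[[cond]]))
            writePeaks(chip$peaks[[cond]],
                       file.path(dir, sprintf("peaks_%s.narrowPeak", cond)))
    }
    writeCountTable(counts, file.path(dir, "counts.tsv"),
                    file.path(dir, "samples.tsv"))
    truth <- sim$truth
    jsonlite::write_json(
        list(genes = as.data.frame(truth$genes),
             motifs = as.data.frame(truth$motifs)),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
    invisible(list(sim = sim, chip = chip, counts = counts))
}
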