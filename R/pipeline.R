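#' Run the full synthetic-study pipeline
#'
#' Orchestrates the fixed stage order: simulate (genome, ChIP/input
#' reads, peaks, expression counts) -> metaprofile (shift, bin,
#' per-million, input-subtract, quantile-normalize, summit matrices) ->
#' peak-to-gene annotation -> differential-expression classification ->
#' motif scan and enrichment -> binding-by-expression integration.
#' Every source of randomness derives from the config seed, so two runs
#' with the same config produce identical results (and byte-identical
#' summary JSON).
#'
#' Mean-read-density (MRD) summit statistics (profile peakedness of the
#' enriched condition, flatness of the factor-null condition) are
#' computed on the reads-per-million ChIP tracks, whose values are
#' non-negative, so that ratios of column means are well defined; the
#' input-subtracted and quantile-normalized tracks (genome-wide mean
#' ~ 0) are still produced and exported for cross-sample comparison.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir optional output directory; when given, all stage
#'   outputs (simulated files, assignments, DE table, summit matrix,
#'   wiggle tracks, \code{summary.json}) are written there.
#' @param upstreamWindow,downstreamWindow,bandWidth,proximalCutoff
#'   annotation settings (bp).
#' @param fcThreshold,pThreshold DE classification settings.
#' @param bgOrder Markov background order for motif scanning.
#' @param scanPThreshold motif match p-value threshold.
#' @param halfWidth summit half-window for motif scanning (bp).
#' @param flankBins summit-matrix flank (bins).
#' @param binWidth profile bin width (bp).
#' @return (invisibly) a list with elements \code{sim}, \code{chip},
#'   \code{counts}, \code{tracks}, \code{mrd}, \code{assignments},
#'   \code{perGene}, \code{de}, \code{comparison}, \code{scan},
#'   \code{enrichment}, \code{spacing}, \code{integration} and
#'   \code{summary} (a flat named list of the headline statistics).
#' @export
runPipeline <- function(config = simulationConfig(), outDir = NULL,
                        upstreamWindow = 2500L, downstreamWindow = 300L,
                        bandWidth = 500L, proximalCutoff = 500L,
                        fcThreshold = 2, pThreshold = 0.05,
                        bgOrder = 2L, scanPThreshold = 1e-5,
                        halfWidth = 250L, flankBins = 20L, binWidth = 25L) {
    ## stage 1: simulate
    sim <- simulateGenome(config)
    chip <- simulateChip(config, sim)
    counts <- simulateExpression(config, sim)
    chromLen <- stats::setNames(Biostrings::width(sim$genome),
                                names(sim$genome))
    peaks <- chip$peaks$daf2

    ## stage 2: metaprofiles
    perMillion <- list(); subtracted <- list()
    for (cond in .CONDITIONS) {
        cp <- shiftReads(chip$chip[[cond]], config@fragmentLength, chromLen)
        ip <- shiftReads(chip$input[[cond]], config@fragmentLength, chromLen)
        ct <- binAndNormalize(cp, chromLen, binWidth,
                              sample = paste0("chip_", cond))
        it <- binAndNormalize(ip, chromLen, binWidth,
                              sample = paste0("input_", cond))
        perMillion[[cond]] <- ct
        subtracted[[cond]] <- subtractInput(ct, it)
    }
    quantiled <- quantileNormalizeTracks(subtracted)
    names(quantiled) <- .CONDITIONS
    mrd <- lapply(perMillion, summitMatrix, peaks = peaks,
                  flankBins = flankBins)

    ## stage 3: annotation
    assignments <- assignPeaks(peaks, sim$genes,
                               upstreamWindow = upstreamWindow,
                               downstreamWindow = downstreamWindow,
                               bandWidth = bandWidth)
    perGene <- bandAndCount(assignments, bandWidth = bandWidth,
                            proximalCutoff = proximalCutoff)
    comparison <- compareConditions(chip$peaks$WT, peaks)

    ## stage 4: differential expression
    de <- classifyGenes(counts, fcThreshold = fcThreshold,
                        pThreshold = pThreshold)

    ## stage 5: motif scan
    bg <- trainBackground(sim$genome, order = bgOrder, label = "toy genome")
    pssm <- pssmFromConsensus(config@motifConsensus, name = "primary")
    coPssm <- pssmFromConsensus(config@comotifConsensus, name = "comotif")
    null <- scoreNull(pssm, bg, seed = config@seed + 51L)
    coNull <- scoreNull(coPssm, bg, seed = config@seed + 52L)
    peakScan <- scanPeaks(sim$genome, peaks, pssm, bg,
                          halfWidth = halfWidth,
                          pThreshold = scanPThreshold, null = null)
    coScan <- scanPeaks(sim$genome, peaks, coPssm, bg,
                        halfWidth = halfWidth,
                        pThreshold = scanPThreshold, null = coNull)
    randomSeqs <- randomPromoterWindows(sim$genome, sim$genes,
                                        n = length(peaks),
                                        halfWidth = halfWidth,
                                        seed = config@seed + 41L)
    randomScan <- scanSequences(randomSeqs, pssm, bg,
                                pThreshold = scanPThreshold, null = null)
    enrichment <- enrichmentCurve(peakScan, randomScan, null,
                                  pThreshold = scanPThreshold)
    promStrand <- stats::setNames(
        ifelse(as.character(strand(sim$genes)) == "+", "+", "-")[
            match(assignments$gene_id, mcols(sim$genes)$gene_id)],
        assignments$peak_id)
    sigPrimary <- peakScan[peakScan$significant, , drop = FALSE]
    sigCo <- coScan[coScan$significant, , drop = FALSE]
    spacing <- intermotifDistances(sigPrimary, sigCo,
                                   promoterStrand = promStrand)
    summitRef <- DataFrame(seq_id = mcols(peaks)$peak_id,
                           genomic_center = mcols(peaks)$summit)
    motifVsSummit <- intermotifDistances(summitRef, sigPrimary,
                                         promoterStrand = promStrand)

    ## stage 6: integration
    boundGenes <- unique(assignments$gene_id[assignments$in_promoter_window &
                                             !is.na(assignments$gene_id)])
    ovAct <- overlapSummary(de, boundGenes, class = "activated")
    ovRep <- overlapSummary(de, boundGenes, class = "repressed")
    strat <- stratifiedFoldChange(perGene, de, class = "activated")
    byClass <- profilesByClass(mrd$daf2, assignments, de)

    cmDaf2 <- columnMeans(mrd$daf2)
    cmNull <- columnMeans(mrd$daf16daf2)
    edge <- as.character(c(-flankBins, flankBins))
    summary <- list(
        seed = config@seed,
        n_genes = config@nGenes,
        n_peaks = length(peaks),
        n_bound_promoter_genes = length(boundGenes),
        n_activated = sum(de$class == "activated"),
        n_repressed = sum(de$class == "repressed"),
        n_direct_targets = ovAct$overlap,
        representation_score_activated = ovAct$R,
        hypergeom_p_activated = ovAct$p,
        representation_score_repressed = ovRep$R,
        hypergeom_p_repressed = ovRep$p,
        mrd_argmax_offset = as.integer(
            names(cmDaf2)[which.max(cmDaf2)]),
        mrd_center_edge_ratio = unname(cmDaf2["0"] / mean(cmDaf2[edge])),
        mrd_null_flatness = unname(max(cmNull) / min(cmNull)),
        motif_match_fraction = mean(peakScan$significant),
        motif_enrichment_r = enrichment@r,
        motif_score_height_cor = enrichment@pearsonRVsHeight,
        intermotif_mode = spacing$mode,
        motif_vs_summit_mode = motifVsSummit$mode,
        n_common_peaks_wt_daf2 = nrow(comparison$common),
        mean_summit_shift = if (nrow(comparison$common))
            mean(comparison$common$summit_shift) else NA_real_)

    result <- list(sim = sim, chip = chip, counts = counts,
                   tracks = list(per_million = perMillion,
                                 subtracted = subtracted,
                                 quantile = quantiled),
                   mrd = mrd, assignments = assignments, perGene = perGene,
                   de = de, comparison = comparison,
                   scan = list(primary = peakScan, comotif = coScan,
                               random = randomScan),
                   enrichment = enrichment,
                   spacing = list(intermotif = spacing,
                                  motif_vs_summit = motifVsSummit),
                   integration = list(activated = ovAct, repressed = ovRep,
                                      stratified = strat,
                                      by_class = byClass),
                   summary = summary)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeSimulation(config, file.path(outDir, "simulated"))
        write.table(as.data.frame(assignments),
                    file.path(outDir, "assignments.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(as.data.frame(de), file.path(outDir, "de_results.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        writeSummitMatrix(mrd$daf2, file.path(outDir, "summit_matrix_daf2.tsv"))
        exportWig(quantiled$daf2, file.path(outDir, "track_daf2.wig"))
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, na = "null")
    }
    invisible(result)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain a \code{simulation:} block (arguments to
#' \code{\link{simulationConfig}}) and an \code{analysis:} block
#' (arguments to \code{\link{runPipeline}}); missing entries keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a list with elements \code{config}
#'   (\linkS4class{SimulationConfig}) and \code{analysis} (named list).
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    simArgs <- if (!is.null(y$simulation)) y$simulation else list()
    config <- do.call(simulationConfig, simArgs)
    analysis <- if (!is.null(y$analysis)) y$analysis else list()
    list(config = config, analysis = analysis)
}
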