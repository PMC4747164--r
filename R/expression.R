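#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom stats pt p.adjust
NULL

#' Build a count table
#'
#' Wraps a gene x sample matrix of non-negative integer read counts in
#' a \code{SummarizedExperiment} carrying the sample-to-condition map,
#' per-sample total mapped reads and per-gene exon model lengths -- the
#' inputs RPKM and the differential-expression test need.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param condition character vector mapping each column to a
#'   condition.
#' @param exonLength per-gene exon model length in bp (>= 1).
#' @param totals per-sample total mapped reads; defaults to column
#'   sums, and must be >= them.
#' @return a \code{SummarizedExperiment}.
#' @export
countTable <- function(counts, condition, exonLength,
                       totals = colSums(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers")
    if (length(condition) != ncol(counts))
        stop("condition must map every sample")
    if (length(exonLength) != nrow(counts) || any(exonLength < 1))
        stop("exonLength must give a length >= 1 bp for every gene")
    if (any(totals < colSums(counts)))
        stop("totals must be >= column sums")
    SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(condition = condition, total = as.numeric(totals),
                            row.names = colnames(counts)),
        rowData = DataFrame(exon_length = as.numeric(exonLength),
                            row.names = rownames(counts)))
}

#' Write / read a count table as TSV
#'
#' \code{counts.tsv} holds \code{gene_id}, \code{exon_length} and one
#' column per sample; \code{samples.tsv} holds \code{sample},
#' \code{condition}, \code{total}.
#'
#' @param se a count table from \code{\link{countTable}}.
#' @param countsPath,samplesPath file paths.
#' @return \code{readCountTable} returns a \code{SummarizedExperiment}.
#' @export
writeCountTable <- function(se, countsPath, samplesPath) {
    df <- data.frame(gene_id = rownames(se),
                     exon_length = rowData(se)$exon_length,
                     assay(se, "counts"), check.names = FALSE)
    write.table(df, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    sm <- data.frame(sample = colnames(se),
                     condition = colData(se)$condition,
                     total = colData(se)$total)
    write.table(sm, samplesPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(countsPath)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(countsPath, samplesPath) {
    df <- read.table(countsPath, header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
    sm <- read.table(samplesPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    counts <- as.matrix(df[, sm$sample, drop = FALSE])
    rownames(counts) <- df$gene_id
    countTable(counts, condition = sm$condition,
               exonLength = df$exon_length, totals = sm$total)
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' \code{rpkm = count * 1e9 / (exon_length_bp * total_mapped)}.
#'
#' @param se a count table from \code{\link{countTable}}.
#' @return a numeric matrix of the same shape as the counts.
#' @export
computeRpkm <- function(se) {
    totals <- colData(se)$total
    if (any(totals <= 0))
        stop("total mapped reads must be > 0 for every sample")
    len <- rowData(se)$exon_length
    sweep(assay(se, "counts") * 1e9 / len, 2L, totals, "/")
}

.groupStats <- function(counts, totals) {
    counts <- as.matrix(counts)
    k <- ncol(counts)
    N <- sum(totals)
    phat <- rowSums(counts) / N
    within <- phat * (1 - phat) / N
    if (k >= 2L) {
        pij <- sweep(counts, 2L, totals, "/")
        pbar <- rowMeans(pij)
        s2 <- rowSums((pij - pbar)^2) / (k - 1L)
        meanWithin <- phat * (1 - phat) * mean(1 / totals)
        tau2 <- pmax(0, s2 - meanWithin)
        between <- tau2 * sum(totals^2) / N^2
    } else {
        tau2 <- rep(0, nrow(counts))
        between <- rep(0, nrow(counts))
    }
    list(phat = phat, V = within + between,
         nu = ifelse(tau2 > 0, k - 1L, Inf))
}

#' Beta-binomial (Baggerley-style) two-group proportion test
#'
#' Per gene, each replicate's count is treated as a proportion of its
#' library total; the group proportion is the inverse-variance
#' (library-size) weighted combination, i.e. the pooled proportion.
#' The group variance is the within-replicate binomial variance plus a
#' between-replicate (beta) component estimated by moments from the
#' spread of the replicate proportions (truncated at zero).  The
#' statistic \eqn{t = (\hat p_a - \hat p_b) / \sqrt{V_a + V_b}} is
#' referred to a t distribution with Satterthwaite-style degrees of
#' freedom, where a group whose variance is purely binomial contributes
#' infinite df.  With single replicates the between term vanishes and
#' the test reduces to the unpooled two-proportion z-test.  Genes with
#' zero counts in both groups get p = 1.
#'
#' @param countsA,countsB gene x replicate count matrices (vectors are
#'   treated as one replicate).
#' @param totalsA,totalsB per-replicate library totals.
#' @return a \code{DataFrame}: \code{prop_a}, \code{prop_b},
#'   \code{statistic}, \code{df}, \code{p} (two-sided).
#' @export
baggerleyTest <- function(countsA, totalsA, countsB, totalsB) {
    if (is.vector(countsA)) countsA <- matrix(countsA, ncol = 1L)
    if (is.vector(countsB)) countsB <- matrix(countsB, ncol = 1L)
    if (ncol(countsA) != length(totalsA) || ncol(countsB) != length(totalsB))
        stop("one library total per replicate column is required")
    a <- .groupStats(countsA, totalsA)
    b <- .groupStats(countsB, totalsB)
    V <- a$V + b$V
    diff <- a$phat - b$phat
    stat <- diff / sqrt(V)
    df <- V^2 / (ifelse(is.finite(a$nu), a$V^2 / a$nu, 0) +
                 ifelse(is.finite(b$nu), b$V^2 / b$nu, 0))
    p <- 2 * pt(-abs(stat), df)
    zeroVar <- V == 0
    p[zeroVar & diff == 0] <- 1
    p[zeroVar & diff != 0] <- 0
    stat[zeroVar] <- ifelse(diff[zeroVar] == 0, 0, Inf * sign(diff[zeroVar]))
    DataFrame(prop_a = a$phat, prop_b = b$phat,
              statistic = stat, df = df, p = p)
}

#' Classify genes as activated, repressed or unchanged
#'
#' A gene is \emph{activated} when it goes up at least
#' \code{fcThreshold}-fold in the test condition relative to the
#' reference (p <= \code{pThreshold}) \emph{and} relative to the
#' factor-null condition (p <= \code{pThreshold}) -- i.e. the response
#' is factor-dependent.  \emph{Repressed} mirrors this with reciprocal
#' folds.  Everything else is \emph{unchanged}.  Fold changes are
#' ratios of mean RPKM; p-values come from
#' \code{\link{baggerleyTest}} and are raw by default
#' (\code{adjust = "BH"} enables Benjamini-Hochberg).  A gene is
#' flagged \emph{expressed} when its RPKM is > 0 in every test- and
#' null-condition sample.
#'
#' @param se a count table from \code{\link{countTable}} containing the
#'   three conditions.
#' @param fcThreshold fold-change threshold (>= 1; default 2).
#' @param pThreshold p-value threshold (default 0.05).
#' @param testCondition,refCondition,nullCondition condition labels for
#'   the low-signalling mutant, wild type and the factor-null double
#'   mutant.
#' @param adjust multiple-testing adjustment passed to
#'   \code{p.adjust} (\code{"none"} by default: the classification
#'   rule is defined on raw p-values).
#' @return a \code{DataFrame}: \code{gene_id}, mean RPKM per condition,
#'   \code{fold_change}, \code{p_primary}, \code{fold_dependence},
#'   \code{p_dependence}, \code{class}, \code{expressed}.
#' @export
classifyGenes <- function(se, fcThreshold = 2, pThreshold = 0.05,
                          testCondition = "daf2", refCondition = "WT",
                          nullCondition = "daf16daf2", adjust = "none") {
    cond <- colData(se)$condition
    for (cc in c(testCondition, refCondition, nullCondition))
        if (!cc %in% cond)
            stop("condition absent from the count table: ", cc)
    rpkm <- computeRpkm(se)
    counts <- assay(se, "counts")
    totals <- colData(se)$total
    sel <- function(cc) which(cond == cc)
    mRpkm <- vapply(c(testCondition, refCondition, nullCondition),
                    function(cc) rowMeans(rpkm[, sel(cc), drop = FALSE]),
                    numeric(nrow(se)))

    fcRatio <- function(num, den) {
        fc <- num / den
        fc[num == 0 & den == 0] <- 1
        fc
    }
    fcPrimary <- fcRatio(mRpkm[, 1L], mRpkm[, 2L])
    fcDep <- fcRatio(mRpkm[, 1L], mRpkm[, 3L])
    pPrimary <- baggerleyTest(counts[, sel(testCondition), drop = FALSE],
                              totals[sel(testCondition)],
                              counts[, sel(refCondition), drop = FALSE],
                              totals[sel(refCondition)])$p
    pDep <- baggerleyTest(counts[, sel(testCondition), drop = FALSE],
                          totals[sel(testCondition)],
                          counts[, sel(nullCondition), drop = FALSE],
                          totals[sel(nullCondition)])$p
    pPrimary <- p.adjust(pPrimary, method = adjust)
    pDep <- p.adjust(pDep, method = adjust)

    activated <- fcPrimary >= fcThreshold & pPrimary <= pThreshold &
        fcDep >= fcThreshold & pDep <= pThreshold
    repressed <- fcPrimary <= 1 / fcThreshold & pPrimary <= pThreshold &
        fcDep <= 1 / fcThreshold & pDep <= pThreshold
    cls <- ifelse(activated, "activated",
                  ifelse(repressed, "repressed", "unchanged"))
    exprCols <- c(sel(testCondition), sel(nullCondition))
    expressed <- rowSums(rpkm[, exprCols, drop = FALSE] > 0) ==
        length(exprCols)

    DataFrame(gene_id = rownames(se),
              rpkm_test = unname(mRpkm[, 1L]),
              rpkm_ref = unname(mRpkm[, 2L]),
              rpkm_null = unname(mRpkm[, 3L]),
              fold_change = unname(fcPrimary),
              p_primary = unname(pPrimary),
              fold_dependence = unname(fcDep),
              p_dependence = unname(pDep),
              class = unname(cls), expressed = unname(expressed))
}
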