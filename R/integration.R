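#' @importFrom stats phyper sd wilcox.test
NULL

#' Representation score of bound differentially expressed genes
#'
#' Fold enrichment of factor-bound genes among differentially
#' expressed genes over the expressed-gene background:
#' \deqn{R = \frac{n_{DDEG} / n_{DEG}}{n_{bound\,expressed} / n_{expressed}}}
#' where a DDEG is a differentially expressed gene that also carries a
#' promoter-window peak.  R = 1 means binding is independent of
#' differential expression.
#'
#' @param nDdeg number of bound differentially expressed genes.
#' @param nDeg number of differentially expressed genes.
#' @param nBoundExpressed number of bound expressed genes.
#' @param nExpressed number of expressed genes.
#' @return the representation score R.
#' @export
representationScore <- function(nDdeg, nDeg, nBoundExpressed, nExpressed) {
    if (nDeg <= 0 || nExpressed <= 0 || nBoundExpressed <= 0)
        stop("nDeg, nExpressed and nBoundExpressed must be > 0")
    (nDdeg / nDeg) / (nBoundExpressed / nExpressed)
}

#' Hypergeometric overlap p-value
#'
#' Upper-tail probability \eqn{P(X \ge \mathrm{overlap})} for
#' \eqn{X \sim} Hypergeometric(universe, nA, nB): the chance of seeing
#' at least the observed overlap between two gene sets drawn from a
#' common universe.  Computed through \code{phyper} (log-gamma based,
#' overflow-safe).
#'
#' @param nA,nB sizes of the two sets.
#' @param overlap observed intersection size.
#' @param universe size of the common universe.
#' @return the upper-tail p-value.
#' @export
hypergeomOverlap <- function(nA, nB, overlap, universe) {
    if (nA > universe || nB > universe ||
        overlap > min(nA, nB) || universe < nA + nB - overlap ||
        any(c(nA, nB, overlap, universe) < 0))
        stop("inconsistent counts for the hypergeometric test")
    phyper(overlap - 1, nA, universe - nA, nB, lower.tail = FALSE)
}

#' Distance- or peak-count-stratified mRNA fold changes
#'
#' Mean and SD of the (linear-scale) expression fold change among
#' genes of one class, stratified either by the distance band of the
#' gene's closest peak or by its proximal peak count (1 vs >= 2).
#'
#' @param perGene output of \code{\link{bandAndCount}}.
#' @param deResults output of \code{\link{classifyGenes}}.
#' @param class gene class to summarize (\code{"activated"},
#'   \code{"repressed"} or \code{"unchanged"}).
#' @param by \code{"band"} or \code{"peak_count"}.
#' @param logScale average log2 fold changes instead of linear ones.
#' @return a \code{DataFrame}: \code{stratum}, \code{n},
#'   \code{mean_fold_change}, \code{sd_fold_change} (mean/sd are
#'   \code{NA} with \code{n = 0}).
#' @export
stratifiedFoldChange <- function(perGene, deResults, class = "activated",
                                 by = c("band", "peak_count"),
                                 logScale = FALSE) {
    by <- match.arg(by)
    de <- deResults[deResults$class == class, , drop = FALSE]
    merged <- merge(as.data.frame(perGene), as.data.frame(de),
                    by = "gene_id")
    strat <- if (by == "band") merged$band else
        ifelse(merged$n_proximal >= 2L, ">=2 peaks", "1 peak")
    fc <- merged$fold_change
    if (logScale) fc <- log2(fc)
    levs <- sort(unique(strat))
    DataFrame(
        stratum = levs,
        n = vapply(levs, function(s) sum(strat == s), 0L),
        mean_fold_change = vapply(levs, function(s) {
            v <- fc[strat == s & is.finite(fc)]
            if (length(v)) mean(v) else NA_real_
        }, 0),
        sd_fold_change = vapply(levs, function(s) {
            v <- fc[strat == s & is.finite(fc)]
            if (length(v) > 1L) sd(v) else NA_real_
        }, 0))
}

#' Paired Wilcoxon signed-rank test, degenerate-safe
#'
#' \code{wilcox.test(x, y, paired = TRUE)} with the all-differences-zero
#' case (which the stock test cannot handle) defined as statistic 0,
#' p = 1.
#'
#' @param x,y paired numeric vectors.
#' @return a list: \code{statistic}, \code{p}.
#' @export
pairedWilcoxon <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must be paired")
    d <- x - y
    if (all(d == 0))
        return(list(statistic = 0, p = 1))
    w <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
    list(statistic = unname(w$statistic), p = w$p.value)
}

#' Binding profiles stratified by expression class
#'
#' Splits the rows of a summit-centered matrix by the expression class
#' of the gene each peak is assigned to, reports the mean profile per
#' class, and compares the summit-bin (offset 0) values between
#' classes with two-sided Mann-Whitney U tests (exact for small
#' samples, normal approximation with tie correction otherwise, as
#' implemented by \code{wilcox.test}).
#'
#' @param mat a \linkS4class{SummitMatrix}.
#' @param assignments output of \code{\link{assignPeaks}} mapping the
#'   matrix's peaks to genes.
#' @param deResults output of \code{\link{classifyGenes}}.
#' @return a list: \code{classMeans} (class x offset matrix),
#'   \code{n} (peaks per class), \code{pairwiseP} (symmetric matrix of
#'   Mann-Whitney p-values on the summit bin; \code{NA} when a class
#'   has fewer than 2 members).
#' @export
profilesByClass <- function(mat, assignments, deResults) {
    gid <- assignments$gene_id[match(rownames(mat@values),
                                     assignments$peak_id)]
    cls <- deResults$class[match(gid, deResults$gene_id)]
    keep <- !is.na(cls)
    vals <- mat@values[keep, , drop = FALSE]
    cls <- cls[keep]
    levs <- sort(unique(cls))
    classMeans <- do.call(rbind, lapply(levs, function(cc)
        colMeans(vals[cls == cc, , drop = FALSE])))
    rownames(classMeans) <- levs
    center <- mat@flankBins + 1L
    n <- vapply(levs, function(cc) sum(cls == cc), 0L)
    pw <- matrix(NA_real_, length(levs), length(levs),
                 dimnames = list(levs, levs))
    for (i in seq_along(levs)) for (j in seq_along(levs)) {
        if (i >= j) next
        xi <- vals[cls == levs[i], center]
        xj <- vals[cls == levs[j], center]
        if (length(xi) >= 2L && length(xj) >= 2L) {
            pw[i, j] <- suppressWarnings(
                wilcox.test(xi, xj, alternative = "two.sided")$p.value)
            pw[j, i] <- pw[i, j]
        }
    }
    list(classMeans = classMeans, n = setNames(n, levs), pairwiseP = pw)
}

#' Binding-by-expression overlap summary
#'
#' Convenience wrapper computing, for one expression class, the
#' DDEG overlap counts, the representation score and the
#' hypergeometric p-value, with the expressed-gene set as the default
#' universe.
#'
#' @param deResults output of \code{\link{classifyGenes}}.
#' @param boundGenes character vector of genes with a promoter-window
#'   peak.
#' @param class expression class to test.
#' @param universe \code{"expressed"} (default) or \code{"all"}.
#' @return a list: \code{n_deg}, \code{n_bound}, \code{overlap},
#'   \code{universe}, \code{R}, \code{p}.
#' @export
overlapSummary <- function(deResults, boundGenes, class = "activated",
                           universe = c("expressed", "all")) {
    universe <- match.arg(universe)
    uniGenes <- if (universe == "expressed")
        deResults$gene_id[deResults$expressed] else deResults$gene_id
    deg <- intersect(
        deResults$gene_id[deResults$class == class], uniGenes)
    bound <- intersect(boundGenes, uniGenes)
    ddeg <- intersect(deg, bound)
    R <- if (length(deg) && length(bound))
        representationScore(length(ddeg), length(deg), length(bound),
                            length(uniGenes))
    else NA_real_
    p <- if (length(deg) && length(bound))
        hypergeomOverlap(length(deg), length(bound), length(ddeg),
                         length(uniGenes))
    else NA_real_
    list(n_deg = length(deg), n_bound = length(bound),
         overlap = length(ddeg), universe = length(uniGenes),
         R = R, p = p)
}
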