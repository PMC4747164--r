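test_that("summit at the TSS gives distance 0, inside the window", {
    g <- makeGenes("chrT", 5000L, 6500L, "+")
    p <- makePeaks("chrT", 4900L, 5100L, 5000L)
    a <- assignPeaks(p, g)
    expect_identical(a$signed_distance, 0L)
    expect_true(a$in_promoter_window)
    expect_identical(a$band, "0-0.5 kb")
})

test_that("promoter window boundaries: 2.5 kb upstream, 300 bp downstream", {
    g <- makeGenes("chrT", 10000L, 11500L, "+")
    mk <- function(s) makePeaks("chrT", s - 50L, s + 50L, s)
    # 2600 bp upstream falls outside the window
    expect_false(assignPeaks(mk(10000L - 2600L), g)$in_promoter_window)
    expect_true(assignPeaks(mk(10000L - 2500L), g)$in_promoter_window)
    expect_true(assignPeaks(mk(10000L + 300L), g)$in_promoter_window)
    expect_false(assignPeaks(mk(10000L + 301L), g)$in_promoter_window)
    # on a - strand gene, upstream lies to the right of the TSS
    gm <- makeGenes("chrT", 10000L, 11500L, "-")
    am <- assignPeaks(mk(11500L + 2000L), gm)
    expect_identical(am$signed_distance, -2000L)
    expect_true(am$in_promoter_window)
})

test_that("assignment matches the exhaustive nearest-TSS search", {
    set.seed(11)
    g <- makeGenes("chrT", c(2000L, 9000L, 20000L), c(3500L, 10500L, 21500L),
                   c("+", "-", "+"))
    summits <- sort(sample(1500:23000, 10))
    p <- makePeaks("chrT", summits - 50L, summits + 50L, summits)
    a <- assignPeaks(p, g)
    tss <- mcols(g)$tss
    sign <- ifelse(as.character(strand(g)) == "+", 1L, -1L)
    for (i in seq_along(summits)) {
        d <- abs(summits[i] - tss)
        j <- which.min(d)
        expect_identical(a$gene_id[i], mcols(g)$gene_id[j])
        expect_identical(a$signed_distance[i],
                         (summits[i] - tss[j]) * sign[j])
    }
})

test_that("equidistant TSS ties break lexicographically by gene id", {
    g <- makeGenes("chrT", c(1000L, 3000L), c(1900L, 3900L), c("+", "+"),
                   ids = c("zzz", "aaa"))
    p <- makePeaks("chrT", 1950L, 2050L, 2000L)  # 1000 bp from both TSSs
    expect_message(a <- assignPeaks(p, g), "tie")
    expect_identical(a$gene_id, "aaa")
})

test_that("peaks on gene-free chromosomes are flagged, not dropped", {
    g <- makeGenes("chrT", 1000L, 2500L, "+")
    p <- makePeaks(c("chrT", "chrU"), c(900L, 900L), c(1100L, 1100L),
                   c(1000L, 1000L))
    a <- assignPeaks(p, g)
    expect_identical(nrow(a), 2L)
    expect_true(a$no_gene[2])
    expect_true(is.na(a$gene_id[2]))
})

test_that("banding and proximal counting match brute-force binning", {
    g <- makeGenes("chrT", 50000L, 51500L, "+")
    d <- c(-250L, -100L, -400L, -750L, -1300L, 200L)
    s <- 50000L + d
    p <- makePeaks("chrT", s - 20L, s + 20L, s)
    a <- assignPeaks(p, g)
    expect_identical(a$band[1], "0-0.5 kb")
    expect_identical(a$band[4], "0.5-1 kb")
    expect_identical(a$band[5], "1-1.5 kb")
    pg <- bandAndCount(a)
    expect_identical(pg$n_proximal, sum(abs(d) <= 500L))
    expect_identical(pg$closest_distance, d[which.min(abs(d))])
    # histogram over bands equals direct binning of |d|
    oracleBands <- sprintf("%g-%g kb", abs(d) %/% 500L * 0.5,
                           (abs(d) %/% 500L + 1) * 0.5)
    expect_identical(as.vector(table(a$band)), as.vector(table(oracleBands)))
})

.bandLabelForDistance <- function(d)
    sprintf("%g-%g kb", d %/% 500L * 0.5, (d %/% 500L + 1) * 0.5)

test_that("condition comparison partitions peaks and matches optimal pairing", {
    # identical lists: all common, zero shifts
    p <- makePeaks("chrT", c(100L, 900L), c(300L, 1100L), c(200L, 1000L))
    cmpSame <- compareConditions(p, p)
    expect_identical(nrow(cmpSame$common), 2L)
    expect_true(all(cmpSame$common$summit_shift == 0L))
    expect_identical(length(cmpSame$exclusive_a), 0L)

    # disjoint lists: all exclusive
    q <- makePeaks("chrT", c(5000L, 9000L), c(5200L, 9200L), c(5100L, 9100L))
    cmpDis <- compareConditions(p, q)
    expect_identical(nrow(cmpDis$common), 0L)
    expect_identical(length(cmpDis$exclusive_a), 2L)
    expect_identical(length(cmpDis$exclusive_b), 2L)

    # constructed 6-peak case: compare against exhaustive optimal matching
    a <- makePeaks("chrT", c(100L, 220L, 500L), c(200L, 320L, 600L),
                   c(150L, 270L, 550L), ids = c("a1", "a2", "a3"))
    b <- makePeaks("chrT", c(150L, 260L, 900L), c(250L, 360L, 1000L),
                   c(200L, 310L, 950L), ids = c("b1", "b2", "b3"))
    cmp <- compareConditions(a, b)
    # exhaustive search over all one-to-one pairings for max total overlap
    ovl <- function(i, j)
        max(0L, min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L)
    best <- -1L; bestPairs <- NULL
    perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
    for (pm in perms) {
        tot <- sum(vapply(1:3, function(i) ovl(i, pm[i]), 0L))
        if (tot > best) { best <- tot; bestPairs <- pm }
    }
    got <- cmp$common[order(cmp$common$peak_a), ]
    keep <- vapply(1:3, function(i) ovl(i, bestPairs[i]) > 0L, TRUE)
    expect_identical(got$peak_a, mcols(a)$peak_id[which(keep)])
    expect_identical(got$peak_b, mcols(b)$peak_id[bestPairs[keep]])
    expect_identical(sum(got$overlap_bp), best)
})

test_that("assignment distances are translation invariant", {
    g <- makeGenes("chrT", c(2000L, 9000L), c(3500L, 10500L), c("+", "-"))
    s <- c(1800L, 2600L, 10900L)
    p <- makePeaks("chrT", s - 50L, s + 50L, s)
    a1 <- assignPeaks(p, g)
    gShift <- makeGenes("chrT", c(2000L, 9000L) + 5000L,
                        c(3500L, 10500L) + 5000L, c("+", "-"))
    pShift <- makePeaks("chrT", s - 50L + 5000L, s + 50L + 5000L, s + 5000L)
    a2 <- assignPeaks(pShift, gShift)
    expect_identical(a1$signed_distance, a2$signed_distance)
})

test_that("planted bound genes are recovered with the correct band", {
    run <- defaultRun()
    truth <- run$sim$truth$genes
    bound <- truth[truth$bound, ]
    a <- run$assignments
    idx <- match(a$peak_id, mcols(run$chip$peaks$daf2)$peak_id)
    expect_false(anyNA(idx))
    # peak order tracks the bound-gene order in the generator
    okGene <- a$gene_id == bound$gene_id
    okBand <- a$band == .bandLabelForDistance(bound$band_distance)
    expect_gte(mean(okGene & okBand), 0.95)
})
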