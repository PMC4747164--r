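test_that("the representation score follows its defining formula", {
    expect_equal(representationScore(30, 100, 150, 1000), 2.0)
    # independence fixed point: bound fraction equal in DE and expressed sets
    expect_equal(representationScore(15, 100, 150, 1000), 1.0)
    expect_equal(representationScore(0, 100, 150, 1000), 0)
    expect_error(representationScore(10, 0, 150, 1000), "> 0")
    expect_error(representationScore(10, 100, 0, 1000), "> 0")
})

test_that("hypergeometric overlap matches closed forms and rejects nonsense", {
    # C(5,5) C(5,0) / C(10,5) = 1/252
    expect_equal(hypergeomOverlap(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
    # forced overlap: set A is the whole universe
    expect_equal(hypergeomOverlap(10, 4, 4, 10), 1)
    expect_error(hypergeomOverlap(5, 5, 6, 10), "inconsistent")
    expect_error(hypergeomOverlap(12, 5, 2, 10), "inconsistent")
})

test_that("hypergeometric upper tails match exhaustive sums (small universes)", {
    for (u in c(6, 9, 12)) {
        for (na in 0:u) for (nb in 0:u) {
            lo <- max(0, na + nb - u)
            for (ov in lo:min(na, nb)) {
                k <- ov:min(na, nb)
                oracle <- sum(choose(na, k) * choose(u - na, nb - k)) /
                    choose(u, nb)
                expect_lt(abs(hypergeomOverlap(na, nb, ov, u) - oracle),
                          1e-10)
            }
        }
    }
})

test_that("R and the hypergeometric p are consistent under independence", {
    set.seed(41)
    u <- 2000; na <- 500; nb <- 500
    Rs <- numeric(300); ps <- numeric(300)
    for (i in 1:300) {
        A <- sample.int(u, na); B <- sample.int(u, nb)
        ov <- length(intersect(A, B))
        Rs[i] <- representationScore(ov, na, nb, u)
        ps[i] <- hypergeomOverlap(na, nb, ov, u)
    }
    expect_lt(abs(mean(Rs) - 1), 0.05)
    # p-values approximately uniform under the null
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
})

mockAssignments <- function(n, dist) {
    S4Vectors::DataFrame(peak_id = sprintf("p%03d", 1:n),
                         gene_id = sprintf("g%03d", 1:n),
                         signed_distance = as.integer(-dist),
                         band = sprintf("%g-%g kb", dist %/% 500 * 0.5,
                                        (dist %/% 500 + 1) * 0.5),
                         in_promoter_window = TRUE, no_gene = FALSE)
}

mockDe <- function(n, fc, class = "activated") {
    S4Vectors::DataFrame(gene_id = sprintf("g%03d", 1:n),
                         fold_change = fc,
                         class = rep_len(class, n),
                         expressed = TRUE)
}

test_that("stratified fold changes: constancy and planted gradients", {
    n <- 90
    dist <- rep(c(250, 750, 1250), each = 30)
    a <- mockAssignments(n, dist)
    pg <- bandAndCount(a)
    # constant fold everywhere -> every band mean is that fold
    s1 <- stratifiedFoldChange(pg, mockDe(n, 2))
    expect_true(all(abs(s1$mean_fold_change - 2) < 1e-12))
    # fold decaying with distance -> strictly decreasing band means
    set.seed(42)
    fc <- c(rnorm(30, 6, .2), rnorm(30, 4, .2), rnorm(30, 2, .2))
    s2 <- stratifiedFoldChange(pg, mockDe(n, fc))
    ord <- order(s2$stratum)  # "0-0.5 kb" < "0.5-1 kb" < "1-1.5 kb"
    expect_true(all(diff(s2$mean_fold_change[ord]) < 0))
})

test_that("single- vs multi-peak stratification is fair under symmetry", {
    n <- 80
    a1 <- mockAssignments(n, rep(200, n))
    # give half the genes a second proximal peak
    extra <- a1[1:(n / 2), ]
    extra$peak_id <- sprintf("px%03d", 1:(n / 2))
    a <- rbind(a1, extra)
    pg <- bandAndCount(a)
    expect_identical(sort(unique(pg$n_proximal)), c(1L, 2L))
    set.seed(43)
    s <- stratifiedFoldChange(pg, mockDe(n, rnorm(n, 3, .3)),
                              by = "peak_count")
    expect_identical(s$stratum, c("1 peak", ">=2 peaks"))
    expect_lt(abs(diff(s$mean_fold_change)), 0.3)
})

test_that("per-class profiles separate planted binding differences", {
    set.seed(44)
    nper <- 100
    mk <- function(mu) matrix(rnorm(nper * 9, rep(c(1, mu, 1), each = 3 * nper),
                                    0.5), nper, 9)
    vals <- rbind(mk(10), mk(5))
    rownames(vals) <- sprintf("p%03d", 1:(2 * nper))
    colnames(vals) <- as.character(-4:4)
    m <- new("SummitMatrix", values = vals, columnMeans = colMeans(vals),
             flankBins = 4L, binWidth = 25L, nDropped = 0L, sample = "s")
    a <- mockAssignments(2 * nper, rep(100, 2 * nper))
    de <- mockDe(2 * nper, 4, class = rep(c("activated", "unchanged"),
                                          each = nper))
    out <- profilesByClass(m, a, de)
    expect_gt(out$classMeans["activated", "0"],
              out$classMeans["unchanged", "0"])
    expect_lt(out$pairwiseP["activated", "unchanged"], 0.01)
    expect_identical(unname(out$n), c(100L, 100L))
})

test_that("identical class distributions give a null Mann-Whitney", {
    set.seed(45)
    nper <- 40
    base <- matrix(rnorm(nper * 5), nper, 5)
    vals <- rbind(base, base)  # both classes see the same values
    rownames(vals) <- sprintf("p%03d", 1:(2 * nper))
    colnames(vals) <- as.character(-2:2)
    m <- new("SummitMatrix", values = vals, columnMeans = colMeans(vals),
             flankBins = 2L, binWidth = 25L, nDropped = 0L, sample = "s")
    a <- mockAssignments(2 * nper, rep(100, 2 * nper))
    de <- mockDe(2 * nper, 4, class = rep(c("activated", "unchanged"),
                                          each = nper))
    out <- profilesByClass(m, a, de)
    expect_gt(out$pairwiseP["activated", "unchanged"], 0.9)
    # classes below 2 members get an undefined-p flag
    de1 <- mockDe(2 * nper, 4, class = c("activated",
                                         rep("unchanged", 2 * nper - 1)))
    out1 <- profilesByClass(m, a, de1)
    expect_true(is.na(out1$pairwiseP["activated", "unchanged"]))
})

test_that("the paired signed-rank wrapper handles degenerate input", {
    x <- c(1, 2, 3, 4)
    r <- pairedWilcoxon(x, x)
    expect_identical(r$statistic, 0)
    expect_identical(r$p, 1)
    set.seed(46)
    a <- rnorm(30); b <- a + 1
    expect_lt(pairedWilcoxon(b, a)$p, 0.01)
    expect_error(pairedWilcoxon(1:3, 1:4), "paired")
})

test_that("overlap summaries wire counts, R and p together", {
    de <- mockDe(100, 4, class = c(rep("activated", 30), rep("unchanged", 70)))
    bound <- sprintf("g%03d", 1:40)  # genes g001..g040 bound
    out <- overlapSummary(de, bound, class = "activated")
    expect_identical(out$overlap, 30L)
    expect_identical(out$n_deg, 30L)
    expect_identical(out$n_bound, 40L)
    expect_identical(out$universe, 100L)
    expect_equal(out$R, (30 / 30) / (40 / 100))
    expect_lt(out$p, 1e-6)
})
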