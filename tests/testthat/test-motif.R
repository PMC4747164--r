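toyPssm <- function()
    pssmFromCounts(matrix(c(8, 1, 1, 1,
                            1, 8, 1, 1,
                            1, 1, 8, 1,
                            1, 1, 1, 8), 4), name = "toy")

test_that("PSSM construction normalizes columns and finds the consensus", {
    p <- toyPssm()
    expect_equal(colSums(pssmMatrix(p)), rep(1, 4))
    expect_identical(pssmConsensus(p), "ACGT")
    expect_identical(pssmLength(p), 4L)
    pc <- pssmFromConsensus("TTGTAAACAA")
    expect_identical(pssmConsensus(pc), "TTGTAAACAA")
    expect_error(pssmFromCounts(matrix(1, 4, 3)), "length")
})

test_that("JASPAR-style PFM text round-trips into a PSSM", {
    f <- withr::local_tempfile(fileext = ".pfm")
    writeLines(c(">MA0001 test",
                 "A [ 8 1 1 1 ]",
                 "C [ 1 8 1 1 ]",
                 "G [ 1 1 8 1 ]",
                 "T [ 1 1 1 8 ]"), f)
    p <- readPssm(f)
    expect_equal(pssmMatrix(p), pssmMatrix(toyPssm()))
    expect_identical(p@name, "MA0001 test")
})

test_that("order-0 background equals base composition with pseudocount", {
    s <- "AACCAAGT"  # A:4 C:2 G:1 T:1, +1 each -> 5/12, 3/12, 2/12, 2/12
    bg <- trainBackground(s, order = 0)
    expect_equal(unname(bg@marginal), c(5, 3, 2, 2) / 12)
    expect_equal(unname(bg@conditional[1, ]), c(5, 3, 2, 2) / 12)
})

test_that("higher-order conditionals are proper distributions", {
    bg <- trainBackground(randomDna(20000, seed = 31), order = 2)
    expect_equal(unname(rowSums(bg@conditional)), rep(1, 16))
    expect_equal(sum(bg@contextProbs), 1)
    expect_true(all(bg@conditional > 0))
    expect_error(trainBackground("ACGT", order = -1), ">= 0")
})

test_that("window scores: identity, maximality and strand symmetry", {
    # uniform PSSM against uniform background scores 0 everywhere
    uni <- pssmFromCounts(matrix(1, 4, 4))
    expect_equal(scoreWindow("ACGT", uni, uniformBg()), 0)
    expect_equal(scoreWindow("TTTT", uni, uniformBg()), 0)

    # the consensus window maximizes the score over all L-mers
    p <- toyPssm()
    bg <- uniformBg()
    combos <- expand.grid(rep(list(c("A", "C", "G", "T")), 4))
    words <- apply(combos, 1, paste, collapse = "")
    scores <- vapply(words, scoreWindow, 0, pssm = p, bg = bg)
    expect_identical(names(which.max(scores)), "ACGT")

    # minus-strand score equals the plus-strand score of the complement
    for (w in sample(words, 20)) {
        expect_equal(scoreWindow(revcompStr(w), p, bg, strand = "-"),
                     scoreWindow(w, p, bg, strand = "+"))
    }

    # windows containing N are undefined
    expect_true(is.na(scoreWindow("ACNT", p, bg)))
})

test_that("exact DP p-values match full enumeration", {
    p <- toyPssm()
    bg <- trainBackground(randomDna(4000, seed = 32), order = 0)
    null <- scoreNull(p, bg)
    expect_identical(null@type, "exact")
    bw <- null@binWidth
    lf <- log2(pssmMatrix(p)); lb <- log2(bg@marginal)
    combos <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
    keys <- apply(combos, 1, function(b)
        sum(round((lf[cbind(b, 1:4)] - lb[b]) / bw)))
    probs <- apply(combos, 1, function(b) prod(bg@marginal[b]))
    enumTail <- vapply(keys, function(k) sum(probs[keys >= k]), 0)
    expect_lt(max(abs(matchPvalue(keys, null, isKey = TRUE) - enumTail)),
              1e-9)
})

test_that("p-values floor at 1, ceil at 0, and decrease with score", {
    p <- toyPssm()
    bg <- uniformBg()
    null <- scoreNull(p, bg)
    expect_equal(matchPvalue(min(null@keys) * null@binWidth - 5, null), 1)
    expect_equal(matchPvalue(max(null@keys) * null@binWidth + 5, null), 0)
    grid <- seq(min(null@keys), max(null@keys)) * null@binWidth
    pv <- matchPvalue(grid, null)
    expect_true(all(diff(pv) <= 1e-12))
})

test_that("Monte-Carlo nulls are seeded and deterministic", {
    p <- pssmFromConsensus("TTGTAAACAA")
    bg <- trainBackground(randomDna(50000, seed = 33), order = 2)
    n1 <- scoreNull(p, bg, mcDraws = 1e5, seed = 9)
    n2 <- scoreNull(p, bg, mcDraws = 1e5, seed = 9)
    expect_identical(n1@keys, n2@keys)
    expect_identical(n1@tailProbs, n2@tailProbs)
    expect_identical(n1@type, "mc")
})

test_that("the scanner recovers a planted consensus to the base", {
    set.seed(34)
    p <- pssmFromConsensus("TTGTAAACAA")
    bg <- trainBackground(randomDna(50000), order = 0)
    null <- scoreNull(p, bg)
    s <- randomDna(501)
    plantAt <- 220L  # start; center = 220 + 4
    substr(s, plantAt, plantAt + 9L) <- "TTGTAAACAA"
    sc <- scanSequences(c(pk = s), p, bg, null = null)
    expect_identical(sc$center, plantAt + 4L)
    expect_identical(sc$strand, "+")
    expect_true(sc$significant)
    # planted on the minus strand: same center, other strand
    s2 <- randomDna(501)
    substr(s2, plantAt, plantAt + 9L) <- revcompStr("TTGTAAACAA")
    sc2 <- scanSequences(c(pk = s2), p, bg, null = null)
    expect_identical(sc2$center, plantAt + 4L)
    expect_identical(sc2$strand, "-")
})

test_that("false positives on random sequence respect the binomial bound", {
    set.seed(35)
    p <- pssmFromConsensus("TTGTAAACAA")
    bg <- trainBackground(randomDna(50000), order = 0)
    null <- scoreNull(p, bg)
    seqs <- setNames(vapply(1:100, function(i) randomDna(501), ""),
                     sprintf("s%03d", 1:100))
    all <- scanSequences(seqs, p, bg, bestOnly = FALSE, null = null)
    # ~1000 windows x 1e-5 expected ~ 1 threshold-passing match
    expect_lte(nrow(all), 5)
    # every significant best hit appears in the all-matches superset
    best <- scanSequences(seqs, p, bg, bestOnly = TRUE, null = null)
    sig <- best[best$significant, , drop = FALSE]
    if (nrow(sig))
        expect_true(all(paste(sig$seq_id, sig$center, sig$strand) %in%
                        paste(all$seq_id, all$center, all$strand)))
})

test_that("null enrichment hovers near 1, planted signal drives r up", {
    set.seed(36)
    p <- pssmFromConsensus("TTGTAAACAA")
    bg <- trainBackground(randomDna(50000), order = 0)
    null <- scoreNull(p, bg)
    mkSeqs <- function(n, prefix) setNames(
        vapply(seq_len(n), function(i) randomDna(301), ""),
        sprintf("%s%03d", prefix, seq_len(n)))
    # permissive threshold so both frequencies are well off zero
    a <- scanSequences(mkSeqs(200, "a"), p, bg, pThreshold = 1e-4,
                       null = null)
    b <- scanSequences(mkSeqs(200, "b"), p, bg, pThreshold = 1e-4,
                       null = null)
    e <- enrichmentCurve(a, b, null, pThreshold = 1e-4)
    expect_gt(e@r, 0.5); expect_lt(e@r, 2)
    expect_true(all(diff(e@peakFreq) <= 1e-12))
    expect_true(all(diff(e@randomFreq) <= 1e-12))

    # plant the motif in 80% of the "peak" set
    planted <- mkSeqs(200, "p")
    for (i in 1:160) {
        s <- planted[[i]]
        substr(s, 100, 109) <- "TTGTAAACAA"
        planted[[i]] <- s
    }
    ps <- scanSequences(planted, p, bg, null = null)
    rs <- scanSequences(mkSeqs(200, "r"), p, bg, null = null)
    ep <- enrichmentCurve(ps, rs, null)
    expect_gte(ep@r, 3)
})

test_that("best scores correlate with heights when heights track the motif", {
    set.seed(37)
    p <- pssmFromConsensus("TTGTAAACAA")
    bg <- trainBackground(randomDna(50000), order = 0)
    null <- scoreNull(p, bg)
    # strong sites in high peaks, degraded sites in low peaks
    n <- 60
    seqs <- character(n); height <- numeric(n)
    for (i in seq_len(n)) {
        s <- randomDna(301)
        site <- "TTGTAAACAA"
        nmut <- (i - 1) %% 4  # 0..3 mutations
        if (nmut > 0)
            for (j in sample(10, nmut))
                substr(site, j, j) <- c(A = "C", C = "A", G = "T",
                                        T = "G")[substr(site, j, j)]
        substr(s, 140, 149) <- site
        seqs[i] <- s
        height[i] <- 10 - 2 * nmut + rnorm(1, 0, 0.3)
    }
    names(seqs) <- sprintf("q%03d", seq_len(n))
    sc <- scanSequences(seqs, p, bg, null = null)
    sc$height <- height
    e <- enrichmentCurve(sc, sc, null)
    expect_gt(e@pearsonRVsHeight, 0.5)
})

test_that("inter-motif distances are strand-aware with a clean mode", {
    ref <- S4Vectors::DataFrame(seq_id = c("s1", "s2", "s3"),
                                center = c(100L, 200L, 300L))
    oth <- S4Vectors::DataFrame(seq_id = c("s1", "s2", "s3"),
                                center = c(100L, 235L, 265L))
    # s1: coincident -> 0; s2: +35 on a + promoter; s3: -35 on a - promoter
    d <- intermotifDistances(ref, oth,
                             promoterStrand = c(s1 = "+", s2 = "+", s3 = "-"))
    expect_equal(unname(d$distances), c(0, 35, 35))
    expect_equal(d$mode, 35)
    # histogram mode sits within one 10-bp bin of the planted offset
    expect_lte(abs(d$mode - 35), 10)
})
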