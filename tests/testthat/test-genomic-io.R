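gff3Text <- function() c(
    "##gff-version 3",
    "chrI\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=ga;biotype=protein_coding",
    "chrI\tsrc\texon\t1001\t1400\t.\t+\t.\tParent=ga",
    "chrI\tsrc\texon\t1601\t2000\t.\t+\t.\tParent=ga",
    "chrI\tsrc\tgene\t5001\t6000\t.\t-\t.\tID=gb;biotype=ncRNA",
    "chrI\tsrc\texon\t5001\t6000\t.\t-\t.\tParent=gb",
    "chrII\tsrc\tgene\t101\t700\t.\t+\t.\tID=gc",
    "chrII\tsrc\texon\t101\t700\t.\t+\t.\tParent=gc",
    "chrII\tsrc\tmRNA\t101\t700\t.\t+\t.\tID=ignored")

test_that("GFF3 genes: TSS follows strand, coding from biotype, exons kept", {
    f <- withr::local_tempfile(fileext = ".gff3")
    writeLines(gff3Text(), f)
    g <- readAnnotation(f)
    expect_identical(mcols(g)$gene_id, c("ga", "gb", "gc"))
    # + strand: TSS at the leftmost exon start (1-based)
    expect_identical(mcols(g)$tss[1], 1001L)
    # - strand: TSS at the rightmost exon end
    expect_identical(mcols(g)$tss[2], 6000L)
    expect_identical(mcols(g)$coding, c(TRUE, FALSE, TRUE))
    expect_identical(IRanges::start(mcols(g)$exons[[1]]), c(1001L, 1601L))
    # unknown feature types are ignored
    expect_false("ignored" %in% mcols(g)$gene_id)
})

test_that("annotation writer and reader are inverses", {
    f <- withr::local_tempfile(fileext = ".gff3")
    writeLines(gff3Text(), f)
    g <- readAnnotation(f)
    f2 <- withr::local_tempfile(fileext = ".gff3")
    writeAnnotation(g, f2)
    g2 <- readAnnotation(f2)
    expect_identical(as.character(seqnames(g)), as.character(seqnames(g2)))
    expect_identical(start(g), start(g2))
    expect_identical(end(g), end(g2))
    expect_identical(mcols(g)$tss, mcols(g2)$tss)
    expect_identical(mcols(g)$coding, mcols(g2)$coding)
    expect_identical(as.list(mcols(g)$exons), as.list(mcols(g2)$exons))
})

test_that("malformed GFF3 lines are reported with their line number", {
    f <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chrI\tsrc\tgene\t1\t100\t.\t+\t.\tID=ga",
                 "chrI\tsrc\tgene\t200"), f)
    expect_error(readAnnotation(f), "line 3")
})

test_that("exons beyond chromosome bounds are a validation error", {
    f <- withr::local_tempfile(fileext = ".gff3")
    writeLines(gff3Text(), f)
    expect_error(readAnnotation(f, chromLengths = c(chrI = 10000, chrII = 500)),
                 "bounds")
})

test_that("narrowPeak summits: offset rule and midpoint fallback", {
    f <- withr::local_tempfile(fileext = ".narrowPeak")
    writeLines(c("chrI\t100\t300\tp1\t0\t.\t7.5\t8\t-1\t50",
                 "chrI\t100\t301\tp2\t0\t.\t3\t-1\t-1\t-1"), f)
    p <- readPeaks(f, condition = "daf2")
    # 0-based start 100 + offset 50 -> 0-based summit 150 == 1-based 151
    expect_identical(mcols(p)$summit[1], 151L)
    # offset -1 -> midpoint rounded down: 0-based 200 == 1-based 201
    expect_identical(mcols(p)$summit[2], 201L)
    expect_equal(mcols(p)$height, c(7.5, 3))
    expect_equal(mcols(p)$pvalue[1], 1e-8)
    expect_equal(mcols(p)$pvalue[2], 1)

    f2 <- withr::local_tempfile(fileext = ".narrowPeak")
    writePeaks(p, f2)
    p2 <- readPeaks(f2, condition = "daf2")
    expect_identical(start(p), start(p2))
    expect_identical(end(p), end(p2))
    expect_identical(mcols(p)$summit, mcols(p2)$summit)
    expect_equal(mcols(p)$height, mcols(p2)$height)
    expect_identical(mcols(p)$peak_id, mcols(p2)$peak_id)
})

test_that("a summit outside its peak interval is rejected", {
    f <- withr::local_tempfile(fileext = ".narrowPeak")
    writeLines("chrI\t100\t300\tp1\t0\t.\t7\t8\t-1\t500", f)
    expect_error(readPeaks(f), "summit outside")
})

test_that("BED6 reads parse with 0-based to 1-based conversion", {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines("chrI\t100\t136\tr1\t0\t+", f)
    r <- readReads(f)
    expect_identical(start(r), 101L)
    expect_identical(end(r), 136L)
    expect_identical(as.character(strand(r)), "+")
})

test_that("reads without strand are refused", {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines("chrI\t100\t136", f)
    expect_error(readReads(f), "strand")
})

test_that("SAM text: unmapped/secondary skipped, kept count matches filter", {
    flags <- c(0L, 16L, 4L, 256L, 0L, 2048L, 16L, 4L, 0L, 16L)
    recs <- sprintf("r%d\t%d\tchrI\t%d\t30\t36M\t*\t0\t0\t*\t*",
                    seq_along(flags), flags, 100 * seq_along(flags))
    f <- withr::local_tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrI\tLN:10000", recs), f)
    expect_message(r <- readReads(f), "skipped")
    keepOracle <- sum(!bitwAnd(flags, 4L) & !bitwAnd(flags, 256L) &
                      !bitwAnd(flags, 2048L))
    expect_identical(length(r), keepOracle)
    expect_identical(attr(r, "skipped"), length(flags) - keepOracle)
    expect_identical(as.character(strand(r)),
                     ifelse(bitwAnd(flags, 16L)[!bitwAnd(flags, 4L) &
                                                !bitwAnd(flags, 256L) &
                                                !bitwAnd(flags, 2048L)] > 0,
                            "-", "+"))
    # 36M CIGAR spans 36 reference bases
    expect_identical(end(r)[1] - start(r)[1] + 1L, 36L)
})

test_that("read writer round-trips through the BED6 reader", {
    r <- makeReads("chrI", c(101L, 500L), c(136L, 535L), c("+", "-"))
    f <- withr::local_tempfile(fileext = ".bed")
    writeReadsBed(r, f)
    r2 <- readReads(f)
    expect_identical(start(r), start(r2))
    expect_identical(end(r), end(r2))
    expect_identical(as.character(strand(r)), as.character(strand(r2)))
})

test_that("chromosome mismatches are a hard error naming offenders", {
    genome <- DNAStringSet(c(chrI = "ACGTACGT"))
    bad <- makeReads("chrX", 1L, 4L, "+")
    expect_error(validateChromosomes(genome, bad), "chrX")
    ok <- makeReads("chrI", 1L, 4L, "+")
    expect_true(validateChromosomes(genome, ok))
})

test_that("wiggle export is fixed-step, 1-based, value-faithful", {
    tr <- makeTrack(list(chrA = c(0, 1.5, 3)), binWidth = 25L)
    f <- withr::local_tempfile(fileext = ".wig")
    exportWig(tr, f)
    lines <- readLines(f)
    expect_match(lines[2], "fixedStep chrom=chrA start=1 step=25 span=25")
    expect_equal(as.numeric(lines[3:5]), c(0, 1.5, 3))
})
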