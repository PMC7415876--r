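# GTF parsing, writing, round trips, intron chains.

test_that("exon rows sharing a transcript_id are grouped into one transcript", {
    gtf <- c(
        'chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; cov "7.5";',
        'chr1\tx\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; cov "7.5";')
    tx <- readGtf(gtf)
    expect_equal(length(tx), 1L)
    expect_equal(unname(S4Vectors::elementNROWS(exonRanges(tx))), 2L)
    expect_equal(unname(txCoverage(tx)), 7.5)
    expect_equal(unname(geneIds(tx)), "g1")
})

test_that("coverage falls back through the configured attribute keys", {
    line <- 'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "g"; transcript_id "t"; FPKM "3.2";'
    expect_equal(unname(txCoverage(readGtf(line))), 3.2)
    # not listed -> absent
    expect_true(is.na(txCoverage(readGtf(line, coverageKeys = "cov"))))
    # unquoted values are accepted
    line2 <- "chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id g; transcript_id t; cov 4;"
    expect_equal(unname(txCoverage(readGtf(line2))), 4)
})

test_that("empty input and non-exon feature rows give an empty transcriptome", {
    tmp <- tempfile(fileext = ".gtf")
    writeLines(character(0), tmp)
    expect_equal(length(readGtf(tmp)), 0L)
    expect_equal(length(readGtf("chr1\tx\tCDS\t1\t9\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";")),
                 0L)
})

test_that("write emits transcript plus exon rows and omits absent coverage", {
    tx <- txFromList(list(list(chrom = "chr1", strand = "+",
                               exons = rbind(c(100, 500)), cov = NULL)))
    lines <- writeGtf(tx)
    expect_length(lines, 2L)             # one transcript + one exon row
    expect_false(any(grepl("cov", lines)))
    tx2 <- txFromList(list(list(chrom = "chr1", strand = "+",
                                exons = rbind(c(100, 500)), cov = 3)))
    expect_true(all(grepl('cov "3"', writeGtf(tx2))))
})

test_that("GTF round-trips are lossless on synthetic assemblies", {
    for (seed in 1:3) {
        ref <- generateReference(nGenes = 25, singleExonProb = 0.4,
                                 seed = seed)
        asm <- generateAssembly(ref, tpFraction = 0.6, fpCount = 10,
                                seed = seed + 10)
        f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
        writeGtf(asm, f1)
        rt1 <- readGtf(f1)
        writeGtf(rt1, f2)
        rt2 <- readGtf(f2)
        for (rt in list(rt1, rt2)) {
            expect_setequal(transcriptIds(rt), transcriptIds(asm))
            ids <- transcriptIds(asm)
            expect_equal(txCoverage(rt)[ids], txCoverage(asm)[ids])
            expect_equal(geneIds(rt)[ids], geneIds(asm)[ids])
            cmp <- function(x) {
                df <- as.data.frame(x[ids])
                data.frame(chrom = as.character(df$seqnames),
                           start = df$start, end = df$end,
                           strand = as.character(df$strand))
            }
            expect_identical(cmp(exonRanges(rt)), cmp(exonRanges(asm)))
        }
        # second read is byte-identical to the first written file
        expect_identical(readLines(f1), readLines(f2))
    }
})

test_that("unknown strand is preserved, not coerced", {
    line <- 'chr1\tx\texon\t1\t50\t.\t.\t.\tgene_id "g"; transcript_id "t";'
    tx <- readGtf(line)
    expect_equal(as.character(BiocGenerics::strand(exonRanges(tx)[[1]])), "*")
    out <- writeGtf(tx)
    expect_true(all(vapply(strsplit(out, "\t"), `[`, character(1), 7) == "."))
})

test_that("parse and validation errors name the offending line", {
    good <- 'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "g"; transcript_id "t";'
    expect_error(readGtf(c(good, "chr1\tx\texon\t5\t9")), "line 2")
    expect_error(readGtf(c(good,
        'chr1\tx\texon\t5\t9\t.\t+\t.\tgene_id "g";')),
        "line 2.*transcript_id")
    expect_error(readGtf('chr1\tx\texon\t50\t10\t.\t+\t.\tgene_id "g"; transcript_id "t";'),
                 "start > end")
    expect_error(readGtf(c(good,
        'chr2\tx\texon\t1\t50\t.\t+\t.\tgene_id "g"; transcript_id "t";')),
        "two chromosomes")
})

test_that("non-numeric coverage is treated as absent with a warning", {
    line <- 'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "g"; transcript_id "t"; cov "n/a";'
    expect_warning(tx <- readGtf(line), "non-numeric coverage")
    expect_true(is.na(txCoverage(tx)))
})

test_that("intron chains follow the exon structure", {
    tx <- txFromList(list(
        list(chrom = "chr1", strand = "+", exons = rbind(c(100, 200), c(300, 400))),
        list(chrom = "chr1", strand = "+", exons = rbind(c(100, 500))),
        list(chrom = "chr2", strand = "-",
             exons = rbind(c(1, 10), c(20, 30), c(40, 50)))))
    ic <- intronChains(tx)
    expect_equal(BiocGenerics::start(ic[[1]]), 201)
    expect_equal(BiocGenerics::end(ic[[1]]), 299)
    expect_equal(length(ic[[2]]), 0L)
    expect_equal(BiocGenerics::start(ic[[3]]), c(11, 31))
    expect_equal(BiocGenerics::end(ic[[3]]), c(19, 39))
    # properties on a generated reference
    ref <- generateReference(nGenes = 40, seed = 5)
    ic <- intronChains(ref)
    expect_equal(unname(S4Vectors::elementNROWS(ic)),
                 unname(S4Vectors::elementNROWS(exonRanges(ref))) - 1L)
    expect_true(all(BiocGenerics::width(unlist(ic)) >= 1L))
})

test_that("reader agrees with rtracklayer on written files", {
    ref <- generateReference(nGenes = 15, seed = 3)
    asm <- generateAssembly(ref, tpFraction = 0.5, fpCount = 5, seed = 4)
    f <- tempfile(fileext = ".gtf")
    writeGtf(asm, f)
    gr <- rtracklayer::import(f)
    ex <- gr[gr$type == "exon"]
    mine <- readGtf(f)
    expect_setequal(unique(ex$transcript_id), transcriptIds(mine))
    byTx <- split(ex, ex$transcript_id)[transcriptIds(mine)]
    expect_equal(unname(S4Vectors::elementNROWS(byTx)),
                 unname(S4Vectors::elementNROWS(exonRanges(mine))))
    expect_equal(unname(unlist(lapply(byTx, function(g) sort(BiocGenerics::start(g))))),
                 unname(BiocGenerics::start(unlist(exonRanges(mine)))))
})

test_that("transcriptome validity catches structural violations", {
    expect_error(txFromList(list(list(chrom = "chr1", strand = "+",
                                      exons = rbind(c(100, 200), c(150, 300))))),
                 "sorted|separated")
    expect_error(txFromList(list(list(chrom = "chr1", strand = "+",
                                      exons = rbind(c(100, 200), c(201, 300))))),
                 "separated")
})
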