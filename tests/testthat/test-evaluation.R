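# Matching rules, ROC construction, scaled AUC.

test_that("multi-exon matching requires identical intron chain, chromosome and strand", {
    ref <- txFromList(list(
        list(chrom = "chr1", strand = "+",
             exons = rbind(c(100, 200), c(300, 400)))), ids = "r1")
    # identity
    pred <- txFromList(list(
        list(chrom = "chr1", strand = "+",
             exons = rbind(c(100, 200), c(300, 400)), cov = 5)))
    lab <- matchTranscripts(pred, ref)
    expect_true(lab$matched)
    expect_equal(lab$matched_ref_id, "r1")
    # same chain, different exon termini: still a match (chains define it)
    pred2 <- txFromList(list(
        list(chrom = "chr1", strand = "+",
             exons = rbind(c(80, 200), c(300, 450)), cov = 5)))
    expect_true(matchTranscripts(pred2, ref)$matched)
    # opposite strand: no match
    pred3 <- txFromList(list(
        list(chrom = "chr1", strand = "-",
             exons = rbind(c(100, 200), c(300, 400)), cov = 5)))
    expect_false(matchTranscripts(pred3, ref)$matched)
    # unknown strand may match either
    pred4 <- txFromList(list(
        list(chrom = "chr1", strand = "*",
             exons = rbind(c(100, 200), c(300, 400)), cov = 5)))
    expect_true(matchTranscripts(pred4, ref)$matched)
    # different chromosome: no match (and no error)
    pred5 <- txFromList(list(
        list(chrom = "chr9", strand = "+",
             exons = rbind(c(100, 200), c(300, 400)), cov = 5)))
    expect_false(matchTranscripts(pred5, ref)$matched)
})

test_that("ties resolve to the lexicographically smallest reference id", {
    ref <- txFromList(list(
        list(chrom = "chr1", strand = "+",
             exons = rbind(c(100, 200), c(300, 400))),
        list(chrom = "chr1", strand = "+",
             exons = rbind(c(90, 200), c(300, 410)))),
        ids = c("rB", "rA"))
    pred <- txFromList(list(
        list(chrom = "chr1", strand = "+",
             exons = rbind(c(100, 200), c(300, 400)), cov = 1)))
    expect_equal(matchTranscripts(pred, ref)$matched_ref_id, "rA")
})

test_that("single-exon matching uses reciprocal overlap against the longer transcript", {
    ref <- txFromList(list(
        list(chrom = "chr1", strand = "+", exons = rbind(c(1000, 1999)))),
        ids = "r1")
    mk <- function(s, e) txFromList(list(
        list(chrom = "chr1", strand = "+", exons = rbind(c(s, e)), cov = 1)))
    # identical: overlap 1
    expect_true(matchTranscripts(mk(1000, 1999), ref)$matched)
    # 800/1000 = 0.8 >= 0.8
    expect_true(matchTranscripts(mk(1200, 1999), ref)$matched)
    # 799/1000 < 0.8
    expect_false(matchTranscripts(mk(1201, 1999), ref)$matched)
    # longer prediction dilutes the ratio: overlap 1000, longer 1400
    expect_false(matchTranscripts(mk(800, 2199), ref)$matched)
    # threshold is configurable
    expect_true(matchTranscripts(mk(800, 2199), ref,
                                 singleExonOverlap = 0.5)$matched)
    # a single-exon prediction never matches a multi-exon reference
    refM <- txFromList(list(
        list(chrom = "chr1", strand = "+",
             exons = rbind(c(1000, 1499), c(1600, 1999)))), ids = "rM")
    expect_false(matchTranscripts(mk(1000, 1999), refM)$matched)
})

test_that("matching an empty reference is an error, empty predictions are not", {
    ref <- generateReference(nGenes = 5, seed = 1)
    empty <- Transcriptome(GenomicRanges::GRangesList())
    expect_error(matchTranscripts(ref, empty), "empty reference")
    lab <- matchTranscripts(empty, ref)
    expect_equal(nrow(lab), 0L)
})

test_that("matcher agrees with the all-pairs oracle on random instances", {
    for (seed in seq(101, 160, by = 2)) {
        inst <- randomInstance(seed)
        got <- matchTranscripts(inst$asm, inst$ref)
        want <- oracleMatch(inst$asm, inst$ref)
        o <- order(got$transcript_id)
        ow <- order(want$transcript_id)
        expect_identical(got$matched[o], want$matched[ow])
        expect_identical(got$matched_ref_id[o], want$matched_ref_id[ow])
    }
})

test_that("roc curve reproduces hand-computed examples", {
    # empty labels
    rc <- rocCurve(data.frame(), 10)
    expect_equal(nrow(rocPoints(rc)), 0L)
    expect_equal(aucScaled(rc), 0)
    # constant precision 1, sensitivity 0.05 -> rectangle of area 0.05
    lab <- data.frame(transcript_id = paste0("t", 1:5),
                      coverage = 5:1,
                      matched = TRUE,
                      matched_ref_id = paste0("r", 1:5))
    expect_equal(aucScaled(rocCurve(lab, 100)), 500)
    # mixed case, frozen from the exhaustive-threshold trapezoid oracle
    lab2 <- data.frame(transcript_id = paste0("t", 1:4),
                       coverage = c(10, 8, 5, 2),
                       matched = c(TRUE, TRUE, FALSE, TRUE),
                       matched_ref_id = c("r1", "r2", NA, "r3"))
    rc2 <- rocCurve(lab2, 1000)
    expect_equal(rocPoints(rc2)$sensitivity, c(1, 2, 2, 3) / 1000)
    expect_equal(rocPoints(rc2)$precision, c(1, 1, 2/3, 3/4))
    expect_equal(aucScaled(rc2), 27.0833333333, tolerance = 1e-9)
    expect_equal(aucScaled(rc2), oracleAucFromLabels(lab2, 1000),
                 tolerance = 1e-12)
})

test_that("duplicate matches count toward precision but once toward sensitivity", {
    lab <- data.frame(transcript_id = c("t1", "t2"),
                      coverage = c(5, 4),
                      matched = c(TRUE, TRUE),
                      matched_ref_id = c("r1", "r1"))
    pts <- rocPoints(rocCurve(lab, 10))
    expect_equal(pts$matched_kept, c(1L, 2L))
    expect_equal(pts$distinct_ref_matched, c(1L, 1L))
    expect_equal(pts$sensitivity, c(0.1, 0.1))
})

test_that("absent coverage is swept as zero", {
    lab <- data.frame(transcript_id = c("t1", "t2"),
                      coverage = c(5, NA),
                      matched = c(TRUE, TRUE),
                      matched_ref_id = c("r1", "r2"))
    pts <- rocPoints(rocCurve(lab, 10))
    expect_equal(pts$threshold, c(5, 0))
    expect_equal(rocCurve(lab, 10)@aucScaled,
                 oracleAucFromLabels(lab, 10))
    expect_error(rocCurve(lab, 0), "positive")
})

test_that("roc invariants hold across random instances", {
    for (seed in 201:215) {
        inst <- randomInstance(seed)
        lab <- matchTranscripts(inst$asm, inst$ref)
        rc <- rocCurve(lab, length(inst$ref))
        pts <- rocPoints(rc)
        if (nrow(pts)) {
            expect_true(!is.unsorted(pts$sensitivity))
            expect_lte(aucScaled(rc),
                       1e4 * pts$sensitivity[nrow(pts)] + 1e-9)
        }
        expect_gte(aucScaled(rc), 0)
        expect_lte(aucScaled(rc), 1e4)
        # a new matched prediction above all thresholds never hurts
        unmatchedRefs <- setdiff(transcriptIds(inst$ref),
                                 lab$matched_ref_id)
        if (length(unmatchedRefs)) {
            lab2 <- rbind(lab, data.frame(
                transcript_id = "extra.tp",
                coverage = max(c(lab$coverage, 0), na.rm = TRUE) + 1,
                matched = TRUE, matched_ref_id = unmatchedRefs[1]))
            expect_gte(aucScaled(rocCurve(lab2, length(inst$ref))),
                       aucScaled(rc) - 1e-9)
        }
        # an unmatched prediction below all thresholds never helps
        lab3 <- rbind(lab, data.frame(
            transcript_id = "extra.fp",
            coverage = 0, matched = FALSE,
            matched_ref_id = NA_character_))
        expect_lte(aucScaled(rocCurve(lab3, length(inst$ref))),
                   aucScaled(rc) + 1e-9)
    }
})

test_that("assemblyAUC composes matching and the curve, in memory and from files", {
    ref <- generateReference(nGenes = 10, seed = 7)
    perfect <- generateAssembly(ref, tpFraction = 1, fpCount = 0, seed = 8)
    expect_equal(assemblyAUC(perfect, ref), 1e4)
    # disjoint chromosome names -> 0
    grl <- exonRanges(perfect)
    GenomeInfoDb::seqlevels(grl) <- sub("chr", "scaffold",
                                        GenomeInfoDb::seqlevels(grl))
    moved <- Transcriptome(grl, geneId = geneIds(perfect),
                           coverage = txCoverage(perfect))
    expect_equal(assemblyAUC(moved, ref), 0)
    # path-based entry point equals the in-memory one
    asm <- generateAssembly(ref, tpFraction = 0.5, fpCount = 8, seed = 9)
    fp <- tempfile(fileext = ".gtf"); fr <- tempfile(fileext = ".gtf")
    writeGtf(asm, fp); writeGtf(ref, fr)
    expect_equal(assemblyAUC(fp, fr), assemblyAUC(asm, ref))
    expect_s4_class(assemblyAUC(asm, ref, curve = TRUE), "RocCurve")
})

test_that("quantile binning coarsens the sweep without breaking bounds", {
    inst <- randomInstance(301)
    full <- assemblyAUC(inst$asm, inst$ref, curve = TRUE)
    binned <- assemblyAUC(inst$asm, inst$ref, bins = 5, curve = TRUE)
    expect_lte(nrow(rocPoints(binned)), 5L)
    expect_gte(aucScaled(binned), 0)
    expect_lte(aucScaled(binned), 1e4)
})
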