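# Shared fixture builders for the suite.

# Small mixed-kind space used across advisor tests.
makeSpace <- function() {
    parameterSpace(
        parameterDef("p1", "integer", 4L, 0L, 8L, 1L, flag = "--p1"),
        parameterDef("p2", "integer", 4L, 0L, 8L, 1L, flag = "--p2"),
        parameterDef("p3", "real", 2, 0, 4, 0.5, flag = "--p3"),
        parameterDef("p4", "boolean", FALSE, flag = "--p4"))
}

# Mock landscape on makeSpace() with a small reference (fast objective).
makeLandscape <- function(seed = 1L, sampleShift = FALSE,
                          optimum = NULL, weights = NULL,
                          nGenes = 60) {
    sp <- makeSpace()
    ref <- generateReference(nGenes = nGenes, transcriptsPerGene = 1:2,
                             seed = seed + 1000L)
    mockLandscape(sp, optimum = optimum %||% defaultVector(sp),
                  weights = weights, reference = ref,
                  sampleShift = sampleShift, fpMax = 80L, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a small Transcriptome from a compact description:
# list(list(chrom, strand, exons = rbind(c(s, e), ...), cov), ...)
txFromList <- function(desc, ids = NULL, genes = NULL) {
    grl <- GenomicRanges::GRangesList(lapply(desc, function(d) {
        GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(d$exons[, 1], d$exons[, 2]),
                               strand = d$strand)
    }))
    names(grl) <- ids %||% sprintf("t%d", seq_along(desc))
    Transcriptome(grl,
                  geneId = genes %||% sprintf("g%d", seq_along(desc)),
                  coverage = vapply(desc, function(d)
                      if (is.null(d$cov)) NA_real_ else d$cov, numeric(1)))
}

# Random separable concave integer objective for ascent tests.
makeConcaveObjective <- function(space, seed) {
    defs <- parameterDefs(space)
    set.seed(seed)
    peaks <- lapply(defs, function(p) {
        if (p$kind %in% c("integer", "real"))
            sample(seq(p$lower, p$upper, by = p$step), 1)
        else TRUE
    })
    coef <- runif(length(defs), 0.5, 3)
    function(v) {
        vals <- paramValues(v)
        tot <- 0
        for (k in seq_along(defs)) {
            p <- defs[[k]]
            d <- if (p$kind %in% c("integer", "real"))
                (as.numeric(vals[[p$name]]) - as.numeric(peaks[[k]])) /
                    p$step
            else as.numeric(!identical(vals[[p$name]], peaks[[k]]))
            tot <- tot - coef[k] * d^2
        }
        tot + 100
    }
}
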