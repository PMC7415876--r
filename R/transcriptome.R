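# Transcriptome construction, accessors, intron chains.

#' Construct a Transcriptome
#'
#' @param exons a [GenomicRanges::GRangesList] of exons, one element per
#'   transcript, named by transcript id. Exons may be unsorted; they are
#'   sorted by start position here.
#' @param geneId character vector of gene ids, one per transcript
#'   (recycled if length 1).
#' @param coverage numeric vector of per-transcript coverages; `NA` marks
#'   an absent confidence score (typical for reference transcriptomes).
#' @return a [Transcriptome-class].
#' @examples
#' grl <- GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1",
#'         IRanges::IRanges(c(100, 300), c(200, 400)), "+"))
#' Transcriptome(grl, geneId = "g1", coverage = 7.5)
#' @export
Transcriptome <- function(exons,
                          geneId = rep(NA_character_, length(exons)),
                          coverage = rep(NA_real_, length(exons))) {
    if (!is(exons, "GRangesList"))
        exons <- GRangesList(exons)
    if (length(exons)) {
        o <- order(rep.int(seq_along(exons), elementNROWS(exons)),
                   start(unlist(exons, use.names = FALSE)))
        u <- unlist(exons, use.names = FALSE)[o]
        exons <- relist(u, exons)
    }
    mcols(exons) <- DataFrame(
        gene_id = rep_len(as.character(geneId), length(exons)),
        coverage = rep_len(as.numeric(coverage), length(exons)))
    new("Transcriptome", exons = exons)
}

#' Accessors for Transcriptome objects
#'
#' `transcriptIds()`, `geneIds()`, `txCoverage()` return per-transcript
#' vectors; `exonRanges()` returns the underlying
#' [GenomicRanges::GRangesList]. `length()` is the number of transcripts
#' and `x[i]` subsets by index, id or logical mask.
#'
#' @param x a [Transcriptome-class].
#' @param value replacement coverage vector.
#' @name Transcriptome-accessors
#' @aliases transcriptIds geneIds txCoverage txCoverage<- exonRanges
NULL

#' @rdname Transcriptome-accessors
#' @export
setMethod("transcriptIds", "Transcriptome", function(x) names(x@exons))

#' @rdname Transcriptome-accessors
#' @export
setMethod("geneIds", "Transcriptome", function(x) {
    setNames(mcols(x@exons)$gene_id, names(x@exons))
})

#' @rdname Transcriptome-accessors
#' @export
setMethod("txCoverage", "Transcriptome", function(x) {
    setNames(mcols(x@exons)$coverage, names(x@exons))
})

#' @rdname Transcriptome-accessors
#' @export
setReplaceMethod("txCoverage", "Transcriptome", function(x, value) {
    mcols(x@exons)$coverage <- rep_len(as.numeric(value), length(x@exons))
    validObject(x)
    x
})

#' @rdname Transcriptome-accessors
#' @export
setMethod("exonRanges", "Transcriptome", function(x) x@exons)

#' @rdname Transcriptome-accessors
#' @export
setMethod("length", "Transcriptome", function(x) length(x@exons))

#' @rdname Transcriptome-accessors
#' @param i index, transcript ids, or logical mask.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "Transcriptome", function(x, i, j, ..., drop = FALSE) {
    new("Transcriptome", exons = x@exons[i])
})

setMethod("show", "Transcriptome", function(object) {
    n <- length(object)
    cov <- txCoverage(object)
    ne <- elementNROWS(object@exons)
    cat(sprintf("Transcriptome with %d transcript%s on %d chromosome%s\n",
                n, if (n == 1) "" else "s",
                length(seqlevelsInUse(object@exons)),
                if (length(seqlevelsInUse(object@exons)) == 1) "" else "s"))
    if (n) {
        cat(sprintf("  multi-exon: %d | single-exon: %d | with coverage: %d\n",
                    sum(ne > 1L), sum(ne == 1L), sum(!is.na(cov))))
        ids <- head(transcriptIds(object), 4L)
        cat("  ids: ", paste(ids, collapse = ", "),
            if (n > 4L) ", ..." else "", "\n", sep = "")
    }
    invisible(NULL)
})

#' @rdname intronChains
#' @export
setMethod("intronChains", "Transcriptome", function(x) {
    grl <- x@exons
    n <- elementNROWS(grl)
    u <- unlist(grl, use.names = FALSE)
    lastIdx <- cumsum(n)
    keep <- setdiff(seq_along(u), lastIdx)   # exons with an in-group successor
    introns <- GRanges(seqnames(u)[keep],
                       IRanges(end(u)[keep] + 1L, start(u)[keep + 1L] - 1L),
                       strand = strand(u)[keep])
    part <- PartitioningByEnd(cumsum(pmax(n - 1L, 0L)), names = names(grl))
    relist(introns, part)
})

# Per-transcript metadata vectors: chromosome, strand, and the intron
# chain rendered as "s1-e1,s2-e2,..." ("" for single-exon transcripts).
txMeta <- function(x) {
    grl <- x@exons
    n <- elementNROWS(grl)
    u <- unlist(grl, use.names = FALSE)
    lastIdx <- cumsum(n)
    keep <- setdiff(seq_along(u), lastIdx)
    grp <- rep.int(seq_along(grl), pmax(n - 1L, 0L))
    piece <- if (length(keep))
        paste0(end(u)[keep] + 1L, "-", start(u)[keep + 1L] - 1L)
    else character(0)
    chain <- character(length(grl))
    if (length(piece)) {
        agg <- vapply(unname(split(piece,
                                   factor(grp, levels = seq_along(grl)))),
                      paste, character(1), collapse = ",")
        chain <- agg
    }
    firstIdx <- lastIdx - n + 1L
    list(chrom = as.character(seqnames(u))[firstIdx],
         strand = as.character(strand(u))[firstIdx],
         chain = chain, nExons = n)
}

# Canonical string key per transcript: "chrom|strand|s1-e1,s2-e2,..."
# (introns). Multi-exon matching is equality of these keys, up to the
# strand-compatibility rule handled in matchTranscripts().
chainKeys <- function(x, withStrand = TRUE) {
    m <- txMeta(x)
    key <- if (withStrand) paste0(m$chrom, "|", m$strand, "|", m$chain)
           else paste0(m$chrom, "|", m$chain)
    setNames(key, names(x@exons))
}

# First exon start / last exon end per transcript (transcript span).
txSpans <- function(x) {
    grl <- x@exons
    n <- elementNROWS(grl)
    u <- unlist(grl, use.names = FALSE)
    lastIdx <- cumsum(n)
    firstIdx <- lastIdx - n + 1L
    GRanges(as.character(seqnames(u))[firstIdx],
            IRanges(start(u)[firstIdx], end(u)[lastIdx]),
            strand = as.character(strand(u))[firstIdx])
}
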