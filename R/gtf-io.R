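# GTF reading and writing. Coordinates are 1-based inclusive end-to-end;
# the per-transcript coverage attribute is the confidence score the
# estimator sweeps thresholds over.

#' Read transcript models from a GTF file
#'
#' Parses GTF2.2-like text: `exon` rows (and optionally `transcript`
#' rows) carrying `gene_id` and `transcript_id` attributes are grouped by
#' transcript id; all other feature types are ignored. The per-transcript
#' coverage is taken from the first attribute name in `coverageKeys`
#' found on the transcript row or, failing that, on its exon rows.
#' Scallop and StringTie both write `cov`, but dialects vary, hence the
#' ordered fallback list. Non-numeric coverage values are treated as
#' absent with a warning rather than an error, to tolerate third-party
#' dialects.
#'
#' @param source path to a GTF file, or a character vector of GTF lines.
#' @param coverageKeys ordered attribute names to try for the coverage.
#' @return a [Transcriptome-class].
#' @section Errors: a malformed attribute column raises a parse error
#'   naming the line number; an exon with `start > end`, or a transcript
#'   id spanning two chromosomes, raises a validation error.
#' @examples
#' gtf <- c(
#'  'chr1\tdemo\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; cov "7.5";',
#'  'chr1\tdemo\texon\t300\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; cov "7.5";')
#' readGtf(gtf)
#' @seealso [writeGtf()]
#' @export
readGtf <- function(source, coverageKeys = c("cov", "coverage", "FPKM")) {
    lines <- if (length(source) == 1L && !grepl("\t", source))
        readLines(source) else source
    lineNo <- seq_along(lines)
    keep <- !grepl("^\\s*(#|$)", lines)
    lines <- lines[keep]; lineNo <- lineNo[keep]
    if (!length(lines))
        return(Transcriptome(GRangesList()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9L))
        stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
                     lineNo[which(nf < 9L)[1L]], nf[which(nf < 9L)[1L]]))
    m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
    type <- m[, 3L]
    sel <- type %in% c("exon", "transcript")
    if (!any(sel))
        return(Transcriptome(GRangesList()))
    m <- m[sel, , drop = FALSE]; lineNo <- lineNo[sel]; type <- type[sel]

    attrCol <- m[, 9L]
    txId <- extractGtfAttribute(attrCol, "transcript_id")
    gnId <- extractGtfAttribute(attrCol, "gene_id")
    bad <- is.na(txId) | is.na(gnId)
    if (any(bad))
        stop(sprintf("GTF parse error at line %d: missing %s attribute",
                     lineNo[which(bad)[1L]],
                     if (is.na(txId[which(bad)[1L]])) "transcript_id" else "gene_id"))

    startv <- suppressWarnings(as.integer(m[, 4L]))
    endv <- suppressWarnings(as.integer(m[, 5L]))
    if (anyNA(startv) || anyNA(endv))
        stop(sprintf("GTF parse error at line %d: non-numeric coordinates",
                     lineNo[which(is.na(startv) | is.na(endv))[1L]]))
    if (any(endv < startv))
        stop(sprintf("GTF validation error at line %d: start > end",
                     lineNo[which(endv < startv)[1L]]))
    strandv <- m[, 7L]
    strandv[!strandv %in% c("+", "-")] <- "*"   # "." preserved as unknown

    # coverage: first key present, transcript rows taking precedence
    covStr <- rep(NA_character_, length(attrCol))
    for (k in coverageKeys) {
        v <- extractGtfAttribute(attrCol, k)
        covStr[is.na(covStr)] <- v[is.na(covStr)]
    }
    covNum <- suppressWarnings(as.numeric(covStr))
    if (any(!is.na(covStr) & is.na(covNum))) {
        warning(sprintf("non-numeric coverage value(s), e.g. '%s' at line %d; treated as absent",
                        covStr[which(!is.na(covStr) & is.na(covNum))[1L]],
                        lineNo[which(!is.na(covStr) & is.na(covNum))[1L]]))
    }

    isExon <- type == "exon"
    # coverage per transcript: transcript rows first, then any exon row
    covByTx <- c(split(covNum[!isExon], txId[!isExon]),
                 split(covNum[isExon], txId[isExon]))
    exTx <- txId[isExon]
    if (!length(exTx))
        return(Transcriptome(GRangesList()))
    uTx <- unique(exTx)
    chromOf <- split(m[isExon, 1L], exTx)
    multiChrom <- vapply(chromOf, function(ch) length(unique(ch)) > 1L,
                         logical(1))
    if (any(multiChrom))
        stop(sprintf("GTF validation error: transcript_id '%s' spans two chromosomes",
                     names(chromOf)[which(multiChrom)[1L]]))

    gr <- GRanges(m[isExon, 1L], IRanges(startv[isExon], endv[isExon]),
                  strand = strandv[isExon])
    grl <- unname(split(gr, factor(exTx, levels = uTx)))
    names(grl) <- uTx
    geneOf <- vapply(split(gnId[isExon], factor(exTx, levels = uTx)),
                     `[`, character(1), 1L)
    covOf <- vapply(uTx, function(id) {
        v <- covByTx[names(covByTx) == id]
        v <- unlist(v, use.names = FALSE)
        v <- v[!is.na(v)]
        if (length(v)) v[1L] else NA_real_
    }, numeric(1))
    Transcriptome(grl, geneId = geneOf, coverage = covOf)
}

# Pull one attribute's value out of a vector of GTF attribute columns
# (vectorized). Accepts `key "value"` and unquoted `key value` forms;
# NA where the key is absent.
extractGtfAttribute <- function(attrCol, key) {
    pat <- paste0("(^|;)\\s*", key, '\\s+("([^"]*)"|[^";[:space:]]+)')
    m <- regexpr(pat, attrCol, perl = TRUE)
    out <- rep(NA_character_, length(attrCol))
    hit <- m != -1L
    if (any(hit)) {
        tok <- regmatches(attrCol, m)
        val <- sub(paste0("^(;)?\\s*", key, "\\s+"), "", tok)
        out[hit] <- gsub('^"|"$', "", val)
    }
    out
}

#' Write a Transcriptome as GTF
#'
#' Emits one `transcript` row plus one `exon` row per exon, attributes
#' `gene_id`, `transcript_id` and `cov` (the latter only when coverage is
#' present), double-quoted and semicolon-separated; exons in genomic
#' order. Unknown strand is written as `"."`.
#'
#' @param x a valid [Transcriptome-class].
#' @param path output file path; when `NULL` the GTF lines are returned
#'   as a character vector instead.
#' @param source value for the GTF source column.
#' @return `path`, invisibly (or the lines when `path` is `NULL`).
#' @seealso [readGtf()]
#' @export
writeGtf <- function(x, path = NULL, source = "TranscriptAdvisor") {
    stopifnot(is(x, "Transcriptome"))
    validObject(x)
    grl <- x@exons
    if (!length(grl)) {
        if (is.null(path)) return(character(0))
        writeLines(character(0), path)
        return(invisible(path))
    }
    n <- elementNROWS(grl)
    ids <- names(grl)
    genes <- mcols(grl)$gene_id
    covs <- mcols(grl)$coverage
    spans <- txSpans(x)
    strandChr <- as.character(strand(spans))
    strandChr[strandChr == "*"] <- "."
    covPart <- ifelse(is.na(covs), "",
                      sprintf(' cov "%s";', vapply(covs, formatParamValue,
                                                   character(1))))
    attrTx <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                      genes, ids, covPart)
    txRows <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      as.character(seqnames(spans)), source,
                      start(spans), end(spans), strandChr, attrTx)
    u <- unlist(grl, use.names = FALSE)
    grp <- rep.int(seq_along(grl), n)
    uStrand <- as.character(strand(u))
    uStrand[uStrand == "*"] <- "."
    exRows <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                      as.character(seqnames(u)), source,
                      start(u), end(u), uStrand, attrTx[grp])
    # interleave: transcript row, then its exon rows
    out <- character(length(txRows) + length(exRows))
    pos <- cumsum(c(0L, head(n + 1L, -1L))) + 1L
    out[pos] <- txRows
    out[-pos] <- exRows
    if (is.null(path)) return(out)
    writeLines(out, path)
    invisible(path)
}
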