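# The advisor estimator: intron-chain matching against the reference and
# the scaled AUC of the sensitivity-precision curve over coverage
# thresholds.

#' Match predicted transcripts to a reference transcriptome
#'
#' A multi-exon prediction is matched iff some reference transcript on
#' the same chromosome and a compatible strand has an identical intron
#' chain. A single-exon prediction is matched iff some single-exon
#' reference transcript on the same chromosome and a compatible strand
#' overlaps it with reciprocal overlap at least `singleExonOverlap`
#' (overlap length divided by the longer transcript's length). Strands
#' are compatible when equal or when either is unknown (`"*"`). Ties are
#' broken by the lexicographically smallest reference id. Predictions on
#' chromosomes absent from the reference are simply unmatched.
#'
#' This reimplements the exact-match (intron-chain) equivalence class of
#' reference-based assembly benchmarking; the full class-code taxonomy of
#' tools like GFFCompare is out of scope.
#'
#' @param pred predicted [Transcriptome-class].
#' @param ref reference [Transcriptome-class]; must be non-empty.
#' @param singleExonOverlap reciprocal-overlap threshold in `(0, 1]`.
#' @return a data.frame with one row per prediction: `transcript_id`,
#'   `coverage`, `matched` (logical), `matched_ref_id` (`NA` when
#'   unmatched).
#' @examples
#' ref <- generateReference(nGenes = 10, seed = 1)
#' asm <- generateAssembly(ref, tpFraction = 0.5, fpCount = 5, seed = 2)
#' table(matchTranscripts(asm, ref)$matched)
#' @export
matchTranscripts <- function(pred, ref, singleExonOverlap = 0.8) {
    stopifnot(is(pred, "Transcriptome"), is(ref, "Transcriptome"))
    if (length(ref) == 0L)
        stop("empty reference: sensitivity is undefined")
    stopifnot(singleExonOverlap > 0, singleExonOverlap <= 1)
    np <- length(pred)
    out <- data.frame(transcript_id = transcriptIds(pred) %||% character(0),
                      coverage = unname(txCoverage(pred)) %||% numeric(0),
                      matched = logical(np),
                      matched_ref_id = rep(NA_character_, np),
                      stringsAsFactors = FALSE)
    if (np == 0L)
        return(out)

    metaP <- txMeta(pred)
    metaR <- txMeta(ref)
    refIds <- transcriptIds(ref)

    ## multi-exon: exact intron-chain lookup on string keys
    refMulti <- which(metaR$nExons > 1L)
    predMulti <- which(metaP$nExons > 1L)
    if (length(refMulti) && length(predMulti)) {
        rchrom <- metaR$chrom[refMulti]
        rstr <- metaR$strand[refMulti]
        rchain <- metaR$chain[refMulti]
        rid <- refIds[refMulti]
        # an unknown-strand reference is reachable from either strand
        star <- rstr == "*"
        mapKey <- c(paste0(rchrom, "|", rstr, "|", rchain),
                    if (any(star))
                        paste0(rep(rchrom[star], 2L), "|",
                               rep(c("+", "-"), each = sum(star)), "|",
                               rep(rchain[star], 2L)))
        mapId <- c(rid, if (any(star)) rep(rid[star], 2L))
        o <- order(mapId)                      # smallest id wins per key
        mapKey <- mapKey[o]; mapId <- mapId[o]
        first <- !duplicated(mapKey)
        mapKey <- mapKey[first]; mapId <- mapId[first]

        pchrom <- metaP$chrom[predMulti]
        pstr <- metaP$strand[predMulti]
        pchain <- metaP$chain[predMulti]
        hitId <- rep(NA_character_, length(predMulti))
        known <- pstr != "*"
        if (any(known)) {
            h <- match(paste0(pchrom[known], "|", pstr[known], "|",
                              pchain[known]), mapKey)
            hitId[known] <- mapId[h]
        }
        if (any(!known)) {
            # unknown-strand prediction may match either strand
            hPlus <- mapId[match(paste0(pchrom[!known], "|+|",
                                        pchain[!known]), mapKey)]
            hMinus <- mapId[match(paste0(pchrom[!known], "|-|",
                                         pchain[!known]), mapKey)]
            hitId[!known] <- ifelse(is.na(hPlus), hMinus,
                                    ifelse(is.na(hMinus), hPlus,
                                           pmin(hPlus, hMinus)))
        }
        got <- !is.na(hitId)
        out$matched[predMulti[got]] <- TRUE
        out$matched_ref_id[predMulti[got]] <- hitId[got]
    }

    ## single-exon: reciprocal overlap among single-exon transcripts
    predSingle <- which(metaP$nExons == 1L)
    refSingle <- which(metaR$nExons == 1L)
    if (length(predSingle) && length(refSingle)) {
        pgr <- unlist(pred@exons[predSingle], use.names = FALSE)
        rgr <- unlist(ref@exons[refSingle], use.names = FALSE)
        # disjoint chromosome sets are expected (unmatched, not an error)
        ov <- suppressWarnings(findOverlaps(pgr, rgr, ignore.strand = TRUE))
        if (length(ov)) {
            qh <- queryHits(ov); sh <- subjectHits(ov)
            ps <- as.character(strand(pgr))[qh]
            rs <- as.character(strand(rgr))[sh]
            compat <- ps == rs | ps == "*" | rs == "*"
            ovw <- pmin(end(pgr)[qh], end(rgr)[sh]) -
                pmax(start(pgr)[qh], start(rgr)[sh]) + 1L
            longer <- pmax(width(pgr)[qh], width(rgr)[sh])
            good <- compat & (ovw / longer >= singleExonOverlap)
            if (any(good)) {
                qh <- qh[good]; sh <- sh[good]
                hitRef <- refIds[refSingle][sh]
                best <- tapply(hitRef, qh, min)
                idx <- predSingle[as.integer(names(best))]
                out$matched[idx] <- TRUE
                out$matched_ref_id[idx] <- as.character(best)
            }
        }
    }
    out
}

#' Sensitivity-precision curve and scaled AUC from match labels
#'
#' Thresholds are the distinct coverage values in decreasing order
#' (absent coverage counts as 0). At each threshold `t`, predictions with
#' coverage `>= t` are kept; sensitivity is the number of distinct
#' reference transcripts matched by kept predictions divided by
#' `referenceSize`, and precision the fraction of kept predictions that
#' are matched. The scaled AUC is `1e4` times the trapezoidal area of
#' precision as a function of sensitivity, with an anchor point at
#' sensitivity 0 carrying the first (highest-threshold) point's
#' precision; no extrapolation beyond the lowest threshold. Duplicate
#' sensitivity values contribute zero-width segments. Multiple
#' predictions matching the same reference transcript all count toward
#' precision, but the reference transcript counts once toward
#' sensitivity.
#'
#' @param labels data.frame as returned by [matchTranscripts()].
#' @param referenceSize positive integer, the number of reference
#'   transcripts.
#' @param bins optional positive integer: instead of all distinct
#'   coverage values, use `bins` thresholds at evenly spaced quantiles of
#'   the coverage distribution (a fixed-binning mode for cross-checks
#'   against external threshold-sweep tools).
#' @return a [RocCurve-class].
#' @examples
#' labels <- data.frame(transcript_id = paste0("t", 1:4),
#'                      coverage = c(10, 8, 5, 2),
#'                      matched = c(TRUE, TRUE, FALSE, TRUE),
#'                      matched_ref_id = c("r1", "r2", NA, "r3"))
#' rocCurve(labels, referenceSize = 1000)   # aucScaled ~ 27.083
#' @export
rocCurve <- function(labels, referenceSize, bins = NULL) {
    referenceSize <- as.integer(referenceSize)
    if (length(referenceSize) != 1L || is.na(referenceSize) ||
        referenceSize <= 0L)
        stop("referenceSize must be a positive integer")
    pts <- data.frame(threshold = numeric(0), kept = integer(0),
                      matched_kept = integer(0),
                      distinct_ref_matched = integer(0),
                      sensitivity = numeric(0), precision = numeric(0))
    if (is.null(labels) || nrow(labels) == 0L)
        return(new("RocCurve", points = pts,
                   referenceSize = referenceSize, aucScaled = 0))
    cov <- labels$coverage
    cov[is.na(cov)] <- 0
    o <- order(cov, decreasing = TRUE)
    cov <- cov[o]
    matched <- labels$matched[o]
    refId <- labels$matched_ref_id[o]
    newRef <- matched & !duplicated(refId) & !is.na(refId)
    cumKept <- seq_along(cov)
    cumMatched <- cumsum(matched)
    cumDistinct <- cumsum(newRef)
    # indices of the last prediction at each distinct coverage value
    lastOfValue <- which(!duplicated(cov, fromLast = TRUE))
    thr <- cov[lastOfValue]
    if (!is.null(bins)) {
        bins <- as.integer(bins)
        stopifnot(bins >= 1L)
        if (length(thr) > bins) {
            qs <- quantile(cov, probs = seq(1, 0, length.out = bins),
                           type = 1L)
            keepThr <- vapply(unique(as.numeric(qs)), function(q)
                lastOfValue[which.min(abs(thr - q))], integer(1))
            lastOfValue <- sort(unique(keepThr))
            thr <- cov[lastOfValue]
        }
    }
    pts <- data.frame(threshold = thr,
                      kept = cumKept[lastOfValue],
                      matched_kept = cumMatched[lastOfValue],
                      distinct_ref_matched = cumDistinct[lastOfValue])
    pts$sensitivity <- pts$distinct_ref_matched / referenceSize
    pts$precision <- pts$matched_kept / pts$kept
    s <- c(0, pts$sensitivity)
    p <- c(pts$precision[1L], pts$precision)
    area <- sum(diff(s) * (head(p, -1L) + tail(p, -1L)) / 2)
    new("RocCurve", points = pts, referenceSize = referenceSize,
        aucScaled = 1e4 * area)
}

#' @rdname RocCurve-class
#' @param object a [RocCurve-class].
#' @export
setMethod("show", "RocCurve", function(object) {
    cat(sprintf("RocCurve: %d threshold point%s, reference size %d\n",
                nrow(object@points),
                if (nrow(object@points) == 1) "" else "s",
                object@referenceSize))
    cat(sprintf("  scaled AUC (x 10^4): %.4f\n", object@aucScaled))
    if (nrow(object@points)) {
        last <- object@points[nrow(object@points), ]
        cat(sprintf("  final sensitivity %.4g, final precision %.4g\n",
                    last$sensitivity, last$precision))
    }
    invisible(NULL)
})

#' @rdname RocCurve-class
#' @export
aucScaled <- function(object) {
    stopifnot(is(object, "RocCurve"))
    object@aucScaled
}

#' @rdname RocCurve-class
#' @export
rocPoints <- function(object) {
    stopifnot(is(object, "RocCurve"))
    object@points
}

#' @rdname assemblyAUC
#' @export
setMethod("assemblyAUC", signature("Transcriptome", "Transcriptome"),
          function(pred, ref, singleExonOverlap = 0.8, bins = NULL,
                   curve = FALSE, ...) {
    labels <- matchTranscripts(pred, ref,
                               singleExonOverlap = singleExonOverlap)
    rc <- rocCurve(labels, referenceSize = length(ref), bins = bins)
    if (curve) rc else rc@aucScaled
})

#' @rdname assemblyAUC
#' @export
setMethod("assemblyAUC", signature("character", "character"),
          function(pred, ref, singleExonOverlap = 0.8, bins = NULL,
                   curve = FALSE, ...) {
    assemblyAUC(readGtf(pred), readGtf(ref),
                singleExonOverlap = singleExonOverlap, bins = bins,
                curve = curve)
})

#' @rdname assemblyAUC
#' @export
setMethod("assemblyAUC", signature("character", "Transcriptome"),
          function(pred, ref, singleExonOverlap = 0.8, bins = NULL,
                   curve = FALSE, ...) {
    assemblyAUC(readGtf(pred), ref, singleExonOverlap = singleExonOverlap,
                bins = bins, curve = curve)
})

#' @rdname assemblyAUC
#' @export
setMethod("assemblyAUC", signature("Transcriptome", "character"),
          function(pred, ref, singleExonOverlap = 0.8, bins = NULL,
                   curve = FALSE, ...) {
    assemblyAUC(pred, readGtf(ref), singleExonOverlap = singleExonOverlap,
                bins = bins, curve = curve)
})
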