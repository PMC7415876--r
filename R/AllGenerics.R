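#' @rdname Transcriptome-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname Transcriptome-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname Transcriptome-accessors
#' @export
setGeneric("txCoverage", function(x) standardGeneric("txCoverage"))

#' @rdname Transcriptome-accessors
#' @export
setGeneric("txCoverage<-", function(x, value) standardGeneric("txCoverage<-"))

#' @rdname Transcriptome-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' Intron chains of transcripts
#'
#' The intron chain of a transcript with exons `e1..en` is the ordered
#' list of intervals `(end(ei)+1, start(ei+1)-1)`; single-exon
#' transcripts have an empty chain. Exact intron-chain identity on the
#' same chromosome and strand is the matching criterion for multi-exon
#' predictions.
#'
#' @param x a [Transcriptome-class].
#' @return a [GenomicRanges::GRangesList] of introns, named and ordered
#'   like the transcripts (zero-length elements for single-exon
#'   transcripts).
#' @examples
#' ref <- generateReference(nGenes = 5, seed = 1)
#' S4Vectors::elementNROWS(intronChains(ref))  # exon count - 1 per transcript
#' @export
setGeneric("intronChains", function(x) standardGeneric("intronChains"))

#' Compute the scaled sensitivity-precision AUC of an assembly
#'
#' Composition of [readGtf()] (for path arguments), [matchTranscripts()]
#' and [rocCurve()]: the advisor estimator. Returns the scaled AUC
#' (`aucScaled` of the curve), a value in `[0, 1e4]`.
#'
#' @param pred predicted assembly: a GTF path or a
#'   [Transcriptome-class].
#' @param ref reference transcriptome: a GTF path or a
#'   [Transcriptome-class].
#' @param singleExonOverlap reciprocal-overlap threshold for single-exon
#'   matching (see [matchTranscripts()]).
#' @param bins optional fixed number of threshold bins (see [rocCurve()]).
#' @param curve when TRUE return the full [RocCurve-class] instead of the
#'   scalar AUC.
#' @param ... passed through between methods.
#' @return scaled AUC (numeric) or a [RocCurve-class] when `curve = TRUE`.
#' @examples
#' ref <- generateReference(nGenes = 20, seed = 1)
#' asm <- generateAssembly(ref, tpFraction = 1, fpCount = 0, seed = 1)
#' assemblyAUC(asm, ref)   # perfect assembly: 10000
#' @export
setGeneric("assemblyAUC",
           function(pred, ref, ...) standardGeneric("assemblyAUC"))

#' Produce an assembly GTF from a sample and a parameter vector
#'
#' The uniform adapter contract. The output file name encodes a stable
#' hash of the parameter vector, so concurrent runs over a set never
#' collide. Invocation, exit status and duration are logged via
#' `message()`. Failures (nonzero exit, timeout, missing or unparseable
#' output) raise an error carrying the captured process output.
#'
#' @param adapter an [AssemblerAdapter-class].
#' @param sample input path: a coordinate-sorted BAM for the external
#'   adapters, a token file holding an integer sample seed for the mock.
#' @param vector a valid [ParameterVector-class].
#' @param outDir directory where the assembly GTF is written.
#' @param ... adapter-specific options.
#' @return path to the assembly GTF.
#' @export
setGeneric("runAssembler",
           function(adapter, sample, vector, outDir, ...)
               standardGeneric("runAssembler"))
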