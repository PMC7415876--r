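# Advising: run the assembler once per vector in the advisor set and
# return the assembly that maximizes the estimator.

#' Advise a parameter vector for one sample
#'
#' Invokes the assembler once per vector in the advisor set (invocations
#' are independent; the result is identical regardless of execution
#' order), scores every produced assembly with [assemblyAUC()] against
#' the reference, and returns the vector attaining the maximum. Ties are
#' broken by the earliest position in the set — so placing the default
#' vector first guarantees the advised AUC is never below the default's.
#' A failed assembler invocation excludes that vector with a warning; if
#' every invocation fails, an error is raised.
#'
#' @param sample input path (BAM for external adapters, token file for
#'   the mock adapter).
#' @param set an [AdvisorSet-class].
#' @param adapter an [AssemblerAdapter-class].
#' @param ref reference transcriptome ([Transcriptome-class] or GTF
#'   path).
#' @param singleExonOverlap passed to the estimator.
#' @param workDir where candidate assemblies are written.
#' @return an [AdvisingResult-class].
#' @examples
#' sp <- parameterSpace(parameterDef("k", "integer", 5, 0, 10, 1))
#' l <- mockLandscape(sp, seed = 3)
#' ad <- mockAssemblerAdapter(l)
#' s <- writeSampleToken(1)
#' res <- advise(s, advisorSet(list(defaultVector(sp))), ad, l@reference)
#' chosenAuc(res)
#' @export
advise <- function(sample, set, adapter, ref, singleExonOverlap = 0.8,
                   workDir = tempfile("advise-")) {
    stopifnot(is(set, "AdvisorSet"), is(adapter, "AssemblerAdapter"))
    validObject(set)
    if (is.character(ref))
        ref <- readGtf(ref)
    dir.create(workDir, recursive = TRUE, showWarnings = FALSE)
    n <- length(set)
    aucs <- rep(NA_real_, n)
    paths <- rep(NA_character_, n)
    for (i in seq_len(n)) {
        path <- tryCatch(
            runAssembler(adapter, sample, set@vectors[[i]], workDir),
            error = function(e) {
                warning(sprintf("vector %d excluded, assembler failed: %s",
                                i, conditionMessage(e)), call. = FALSE)
                NA_character_
            })
        if (is.na(path))
            next
        paths[i] <- path
        aucs[i] <- assemblyAUC(readGtf(path), ref,
                               singleExonOverlap = singleExonOverlap)
    }
    if (all(is.na(aucs)))
        stop("all assembler invocations failed; nothing to advise")
    best <- which(aucs == max(aucs, na.rm = TRUE))[1L]   # earliest wins ties
    new("AdvisingResult", chosenIndex = best,
        chosenVector = set@vectors[[best]],
        chosenAuc = aucs[best], perVectorAuc = aucs,
        assemblyPath = paths[best])
}

#' @rdname AdvisingResult-class
#' @param x an [AdvisingResult-class].
#' @export
chosenVector <- function(x) {
    stopifnot(is(x, "AdvisingResult"))
    x@chosenVector
}

#' @rdname AdvisingResult-class
#' @export
chosenAuc <- function(x) {
    stopifnot(is(x, "AdvisingResult"))
    x@chosenAuc
}

#' @rdname AdvisingResult-class
#' @export
perVectorAuc <- function(x) {
    stopifnot(is(x, "AdvisingResult"))
    x@perVectorAuc
}

#' @rdname AdvisingResult-class
#' @export
assemblyPath <- function(x) {
    stopifnot(is(x, "AdvisingResult"))
    x@assemblyPath
}

setMethod("show", "AdvisingResult", function(object) {
    cat(sprintf("AdvisingResult: vector %d of %d chosen, scaled AUC %.4f\n",
                object@chosenIndex, length(object@perVectorAuc),
                object@chosenAuc))
    cat(sprintf("  provenance: %s\n", provenance(object@chosenVector)))
    invisible(NULL)
})
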