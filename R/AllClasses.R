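# S4 classes for transcript models, the estimator, parameter spaces,
# advisor sets, and assembler adapters.

#' Transcriptome: a collection of transcript models
#'
#' A `Transcriptome` holds a set of transcript models, each an ordered run
#' of exons on one chromosome and strand, with an optional per-transcript
#' coverage (the assembler's abundance estimate, used as the confidence
#' score when sweeping thresholds). Exon coordinates are 1-based and
#' inclusive throughout, following the GTF convention.
#'
#' @slot exons a [GenomicRanges::GRangesList], one element per transcript,
#'   named by transcript id; element metadata columns `gene_id`
#'   (character) and `coverage` (numeric, `NA` when absent).
#'
#' @details Validity requires: unique non-empty transcript ids; every
#'   transcript on a single chromosome and strand; exons sorted by start,
#'   non-overlapping, and separated by at least one base (introns have
#'   positive length); coverages non-negative or `NA`. Strand `"*"`
#'   denotes unknown strand and is preserved, never coerced.
#'
#' @seealso [Transcriptome()], [readGtf()], [intronChains()]
#' @export
setClass("Transcriptome", slots = c(exons = "GRangesList"))

setValidity("Transcriptome", function(object) {
    grl <- object@exons
    ids <- names(grl)
    if (length(grl) == 0L)
        return(TRUE)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        return("all transcripts must be named by a transcript id")
    if (anyDuplicated(ids))
        return(sprintf("duplicate transcript_id: %s",
                       ids[anyDuplicated(ids)]))
    md <- mcols(grl)
    if (!all(c("gene_id", "coverage") %in% colnames(md)))
        return("metadata columns 'gene_id' and 'coverage' are required")
    cov <- md$coverage
    if (any(!is.na(cov) & cov < 0))
        return("coverage must be non-negative")
    n <- elementNROWS(grl)
    if (any(n < 1L))
        return("every transcript needs at least one exon")
    u <- unlist(grl, use.names = FALSE)
    grp <- rep.int(seq_along(grl), n)
    # single chromosome and strand per transcript
    chr <- as.character(seqnames(u))
    str <- as.character(strand(u))
    firstIdx <- cumsum(n) - n + 1L
    if (!all(chr == chr[firstIdx][grp]))
        return("a transcript spans multiple chromosomes")
    if (!all(str == str[firstIdx][grp]))
        return("a transcript mixes strands")
    if (any(start(u) > end(u)))
        return("exon with start > end")
    # sorted, non-overlapping, gap >= 1 between consecutive exons
    lastIdx <- cumsum(n)
    inner <- setdiff(seq_along(u), lastIdx)      # has a successor in-group
    if (length(inner) && any(start(u)[inner + 1L] < end(u)[inner] + 2L))
        return("exons must be sorted and separated by at least one base")
    TRUE
})

#' RocCurve: sensitivity-precision curve over coverage thresholds
#'
#' The advisor estimator's curve. Each point corresponds to one coverage
#' threshold; predictions with coverage at or above the threshold are
#' kept. Sensitivity is the fraction of reference transcripts matched by a
#' kept prediction; precision is the fraction of kept predictions that
#' match. `aucScaled` is 10^4 times the trapezoidal area under precision
#' as a function of sensitivity (the x10^4 scale keeps the tiny absolute
#' areas typical of large references readable).
#'
#' @slot points data.frame with columns `threshold`, `kept`,
#'   `matched_kept`, `distinct_ref_matched`, `sensitivity`, `precision`,
#'   ordered by decreasing threshold.
#' @slot referenceSize number of transcripts in the reference.
#' @slot aucScaled scaled AUC in `[0, 1e4]`.
#' @seealso [rocCurve()], [assemblyAUC()]
#' @export
setClass("RocCurve",
         slots = c(points = "data.frame",
                   referenceSize = "integer",
                   aucScaled = "numeric"))

setValidity("RocCurve", function(object) {
    p <- object@points
    need <- c("threshold", "kept", "matched_kept", "distinct_ref_matched",
              "sensitivity", "precision")
    if (!all(need %in% colnames(p)))
        return("points is missing required columns")
    if (length(object@referenceSize) != 1L || object@referenceSize <= 0L)
        return("referenceSize must be a positive integer")
    if (nrow(p)) {
        if (is.unsorted(rev(p$threshold)))
            return("points must be ordered by decreasing threshold")
        if (any(p$matched_kept > p$kept) ||
            any(p$distinct_ref_matched > p$matched_kept))
            return("count invariants violated")
        if (any(p$sensitivity < 0 | p$sensitivity > 1) ||
            any(p$precision < 0 | p$precision > 1))
            return("sensitivity/precision out of [0,1]")
        if (is.unsorted(p$sensitivity))
            return("sensitivity must be non-decreasing")
    }
    if (object@aucScaled < 0 || object@aucScaled > 1e4 + 1e-9)
        return("aucScaled out of [0, 1e4]")
    TRUE
})

#' ParameterSpace: declaration of an assembler's tunable parameters
#'
#' Each parameter is declared with a name, kind (`integer`, `real`,
#' `boolean`, or `categorical`), default, bounds and step (numeric kinds)
#' or choices (categorical), the command-line flag the assembler adapter
#' renders it with, and an optional `scale` (`"additive"` or
#' `"multiplicative"`) controlling how coordinate ascent proposes moves.
#'
#' @slot params named list; each element is a list with fields `name`,
#'   `kind`, `default`, `lower`, `upper`, `step`, `choices`, `flag`,
#'   `scale`.
#' @seealso [parameterSpace()], [parameterDef()], [readParameterSpace()]
#' @export
setClass("ParameterSpace", slots = c(params = "list"))

setValidity("ParameterSpace", function(object) {
    ps <- object@params
    if (length(ps) == 0L)
        return("a parameter space must declare at least one parameter")
    nm <- unname(vapply(ps, function(p) p$name, character(1)))
    if (anyDuplicated(nm))
        return("duplicate parameter names")
    if (!identical(names(ps), nm))
        return("params list must be named by parameter name")
    for (p in ps) {
        if (!p$kind %in% c("integer", "real", "boolean", "categorical"))
            return(sprintf("parameter '%s': unknown kind '%s'", p$name, p$kind))
        if (p$kind %in% c("integer", "real")) {
            if (!is.finite(p$lower) || !is.finite(p$upper) || p$lower > p$upper)
                return(sprintf("parameter '%s': invalid bounds", p$name))
            if (!is.finite(p$step) || p$step <= 0)
                return(sprintf("parameter '%s': step must be positive", p$name))
            if (p$default < p$lower || p$default > p$upper)
                return(sprintf("parameter '%s': default out of bounds", p$name))
        } else if (p$kind == "categorical") {
            if (length(p$choices) < 1L || !p$default %in% p$choices)
                return(sprintf("parameter '%s': default not among choices",
                               p$name))
        } else if (!is.logical(p$default)) {
            return(sprintf("parameter '%s': boolean default must be logical",
                           p$name))
        }
    }
    TRUE
})

#' ParameterVector: one assignment of values to every tunable parameter
#'
#' @slot values named list, one value per declared parameter.
#' @slot provenance free-text label recording where the vector came from
#'   (e.g. `"default"`, `"CA:sample-3"`, `"random"`).
#' @seealso [parameterVector()], [validateVector()]
#' @export
setClass("ParameterVector",
         slots = c(values = "list", provenance = "character"))

#' AdvisorSet: an ordered collection of distinct parameter vectors
#'
#' The advisor runs the assembler once per member vector and keeps the
#' best-scoring assembly. By convention the default vector, when present,
#' sits in position 1 so that tie-breaking by position guarantees the
#' advised AUC is never below the default's.
#'
#' @slot vectors list of [ParameterVector-class] objects, pairwise
#'   distinct, non-empty.
#' @slot includesDefault whether position 1 is the assembler default.
#' @seealso [advisorSet()], [advise()], [buildAdvisorSet()]
#' @export
setClass("AdvisorSet",
         slots = c(vectors = "list", includesDefault = "logical"))

setValidity("AdvisorSet", function(object) {
    vs <- object@vectors
    if (length(vs) == 0L)
        return("an advisor set must contain at least one vector")
    if (!all(vapply(vs, is, logical(1), "ParameterVector")))
        return("all members must be ParameterVector objects")
    keys <- vapply(vs, vectorKey, character(1))
    if (anyDuplicated(keys))
        return("advisor-set vectors must be pairwise distinct")
    if (length(object@includesDefault) != 1L || is.na(object@includesDefault))
        return("includesDefault must be TRUE or FALSE")
    TRUE
})

#' AdvisingResult: outcome of advising one sample
#'
#' @slot chosenIndex position of the winning vector in the advisor set.
#' @slot chosenVector the winning [ParameterVector-class].
#' @slot chosenAuc its scaled AUC (equals the maximum of `perVectorAuc`).
#' @slot perVectorAuc scaled AUC per set member (`NA` where the assembler
#'   invocation failed).
#' @slot assemblyPath path of the winning assembly GTF.
#' @seealso [advise()]
#' @export
setClass("AdvisingResult",
         slots = c(chosenIndex = "integer",
                   chosenVector = "ParameterVector",
                   chosenAuc = "numeric",
                   perVectorAuc = "numeric",
                   assemblyPath = "character"))

#' AscentTrace: record of one coordinate-ascent run
#'
#' @slot steps data.frame of accepted steps: `pass`, `parameter`,
#'   `old_value`, `new_value` (rendered as character), `auc` (scaled AUC
#'   after acceptance).
#' @slot evaluations number of distinct objective evaluations (memoized
#'   repeats are not counted).
#' @slot startAuc,finalAuc scaled AUC at the start vector and at the
#'   returned incumbent; `finalAuc >= startAuc` always.
#' @seealso [coordinateAscent()]
#' @export
setClass("AscentTrace",
         slots = c(steps = "data.frame",
                   evaluations = "integer",
                   startAuc = "numeric",
                   finalAuc = "numeric"))

setValidity("AscentTrace", function(object) {
    if (object@finalAuc < object@startAuc)
        return("finalAuc must be >= startAuc")
    a <- object@steps$auc
    if (length(a) > 1L && any(diff(a) <= 0))
        return("accepted-step AUCs must be strictly increasing")
    TRUE
})

#' AssemblerAdapter: uniform contract for producing an assembly
#'
#' An adapter turns `(sample, parameter vector)` into an assembly GTF via
#' [runAssembler()]. Concrete adapters: [scallopAdapter()],
#' [stringtieAdapter()] (external processes) and [mockAssemblerAdapter()]
#' (fully internal, deterministic; used by the test suite and the
#' experiment harness).
#'
#' @slot name adapter label used in logs and manifests.
#' @slot timeout seconds allowed per invocation (external adapters).
#' @export
setClass("AssemblerAdapter",
         representation("VIRTUAL", name = "character", timeout = "numeric"))

#' MockLandscape: planted-optimum quality landscape for the mock assembler
#'
#' Assembly quality is a separable unimodal function of the parameter
#' vector: `quality(p) = exp(-sum_i w_i d_i(p, p*)^2)` where `d_i` is the
#' per-parameter distance in step units (numeric) or 0/1 (boolean,
#' categorical), so `quality(p*) = 1`. An optional second optimum (behind
#' `optimum2`) yields a bimodal landscape for robustness testing.
#'
#' @slot space the [ParameterSpace-class] the landscape lives on.
#' @slot optimum the planted optimum `p*`.
#' @slot optimum2 optional second mode (list of length 0 or 1).
#' @slot weights named non-negative per-parameter weights.
#' @slot reference the reference [Transcriptome-class] the mock assembler
#'   draws true positives from.
#' @slot maxSensitivity fraction of the reference recovered at quality 1.
#' @slot fpMax number of false-positive transcripts emitted at quality 0;
#'   the count decays linearly to 0 at quality 1.
#' @slot sampleShift when TRUE, each sample seed displaces the effective
#'   optimum deterministically, so different samples favor different
#'   parameter vectors (see [effectiveOptimum()]).
#' @slot seed landscape-level seed for all derived randomness.
#' @seealso [mockLandscape()], [mockAssemble()], [landscapeQuality()]
#' @export
setClass("MockLandscape",
         slots = c(space = "ParameterSpace",
                   optimum = "ParameterVector",
                   optimum2 = "list",
                   weights = "numeric",
                   reference = "Transcriptome",
                   maxSensitivity = "numeric",
                   fpMax = "integer",
                   sampleShift = "logical",
                   seed = "integer"))

setValidity("MockLandscape", function(object) {
    if (object@maxSensitivity <= 0 || object@maxSensitivity > 1)
        return("maxSensitivity must be in (0, 1]")
    if (any(object@weights < 0))
        return("weights must be non-negative")
    if (!identical(sort(names(object@weights)),
                   sort(names(object@space@params))))
        return("weights must be named by the space's parameters")
    if (length(validateVector(object@space, object@optimum)))
        return("optimum is not valid under the space")
    TRUE
})

#' MockAssemblerAdapter: adapter wrapping a mock landscape
#'
#' The `sample` argument of [runAssembler()] is a token file whose first
#' line is an integer sample seed (see [writeSampleToken()]).
#'
#' @slot landscape the [MockLandscape-class].
#' @slot cache internal per-sample cache environment.
#' @seealso [mockAssemblerAdapter()]
#' @export
setClass("MockAssemblerAdapter", contains = "AssemblerAdapter",
         slots = c(landscape = "MockLandscape", cache = "environment"))

#' CommandLineAdapter: external assembler invoked as a subprocess
#'
#' @slot executable program name or path.
#' @slot space the [ParameterSpace-class] whose flags render the vector.
#' @slot argOrder template: `"scallop"` renders `-i sample -o out flags...`,
#'   `"stringtie"` renders `sample -o out flags...`.
#' @slot booleanStyle `"value"` (flag followed by true/false) or
#'   `"presence"` (flag emitted only when TRUE).
#' @export
setClass("CommandLineAdapter", contains = "AssemblerAdapter",
         slots = c(executable = "character",
                   space = "ParameterSpace",
                   argOrder = "character",
                   booleanStyle = "character"))
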