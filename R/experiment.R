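# Experiment harness: advising ratios (advised / default AUC) across
# samples, AUC matrices for subset selection, and run manifests.

#' Advising-ratio experiment across samples
#'
#' For each sample, runs [advise()] with the given advisor set and
#' computes the ratio of the advised scaled AUC over the scaled AUC of
#' the default parameter vector on the same sample. A ratio above 1
#' indicates an improvement over the defaults. The headline summary is
#' the median ratio (means are dominated by a few extreme samples).
#' Samples whose default AUC is 0 have an undefined ratio; they are
#' reported as `NA` and excluded from the median with a warning.
#'
#' @param samples character vector of sample paths.
#' @param set an [AdvisorSet-class].
#' @param adapter an [AssemblerAdapter-class].
#' @param ref reference transcriptome ([Transcriptome-class] or GTF
#'   path).
#' @param space the [ParameterSpace-class]; identifies the default
#'   vector.
#' @param singleExonOverlap passed to the estimator.
#' @param workDir where candidate assemblies are written.
#' @return a data.frame with columns `sample`, `default_auc`,
#'   `advised_auc`, `ratio`, and attribute `medianRatio`.
#' @seealso [advise()], [buildAdvisorSet()], [randomAdvisorSet()]
#' @export
experimentAdvisingRatio <- function(samples, set, adapter, ref, space,
                                    singleExonOverlap = 0.8,
                                    workDir = tempfile("experiment-")) {
    stopifnot(is(set, "AdvisorSet"), is(space, "ParameterSpace"))
    if (is.character(ref))
        ref <- readGtf(ref)
    dir.create(workDir, recursive = TRUE, showWarnings = FALSE)
    dflt <- defaultVector(space)
    rows <- lapply(samples, function(s) {
        res <- advise(s, set, adapter, ref,
                      singleExonOverlap = singleExonOverlap,
                      workDir = file.path(workDir, shortHash(s)))
        dpath <- runAssembler(adapter, s, dflt,
                              file.path(workDir, shortHash(s)))
        dauc <- assemblyAUC(readGtf(dpath), ref,
                            singleExonOverlap = singleExonOverlap)
        data.frame(sample = basename(s), default_auc = dauc,
                   advised_auc = chosenAuc(res),
                   ratio = if (dauc > 0) chosenAuc(res) / dauc else
                       NA_real_,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (anyNA(out$ratio))
        warning(sprintf("%d sample(s) with default AUC 0: ratio undefined, excluded from the median",
                        sum(is.na(out$ratio))), call. = FALSE)
    attr(out, "medianRatio") <- median(out$ratio, na.rm = TRUE)
    out
}

#' Training AUC matrix for subset selection
#'
#' Scores every (sample, vector) pair: entry `[i, j]` is the scaled AUC
#' of the assembly produced on sample `i` under vector `j`. Rows are
#' named by sample, columns by vector provenance. This is the input of
#' [advisingScore()], [greedySubsets()] and [exhaustiveSubset()].
#'
#' @inheritParams experimentAdvisingRatio
#' @return numeric matrix, samples x vectors.
#' @export
computeAucMatrix <- function(samples, set, adapter, ref,
                             singleExonOverlap = 0.8,
                             workDir = tempfile("aucmat-")) {
    stopifnot(is(set, "AdvisorSet"))
    if (is.character(ref))
        ref <- readGtf(ref)
    dir.create(workDir, recursive = TRUE, showWarnings = FALSE)
    m <- matrix(NA_real_, nrow = length(samples), ncol = length(set),
                dimnames = list(basename(samples),
                                vapply(set@vectors, function(v) {
                                    p <- provenance(v)
                                    if (nzchar(p)) p else "?"
                                }, character(1))))
    for (i in seq_along(samples)) {
        sdir <- file.path(workDir, shortHash(samples[i]))
        dir.create(sdir, showWarnings = FALSE)
        for (j in seq_len(length(set))) {
            path <- runAssembler(adapter, samples[i], set@vectors[[j]],
                                 sdir)
            m[i, j] <- assemblyAUC(readGtf(path), ref,
                                   singleExonOverlap = singleExonOverlap)
        }
    }
    m
}

#' Write a run manifest
#'
#' Every pipeline run can record its command, resolved options, input
#' digests (md5), seeds and timestamps as a JSON manifest, so a run is
#' reproducible bit-for-bit from its manifest on synthetic/mock paths.
#'
#' @param path output JSON path.
#' @param command command or function name.
#' @param options named list of resolved options.
#' @param inputs character vector of input file paths (digested with
#'   md5).
#' @param seeds named list or vector of seeds used.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, command, options = list(),
                             inputs = character(0), seeds = list()) {
    digests <- if (length(inputs))
        as.list(md5sum(inputs[file.exists(inputs)])) else list()
    manifest <- list(
        command = command,
        options = options,
        input_digests = digests,
        seeds = seeds,
        tool = list(package = "TranscriptAdvisor",
                    version = as.character(utils::packageVersion("TranscriptAdvisor")),
                    r = R.version.string),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}
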