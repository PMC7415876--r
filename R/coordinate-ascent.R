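# Greedy coordinate ascent over a mixed parameter space, and advisor-set
# construction from per-sample ascent optima.

#' Coordinate-ascent configuration
#'
#' @param maxPasses maximum number of full passes over the parameters
#'   (a pass with no accepted step is the natural stop).
#' @param directionPolicy `"best-of-both"` evaluates every proposal for a
#'   coordinate and takes the best; `"first-improvement"` accepts the
#'   first proposal that improves.
#' @param minImprovement strict-improvement margin on the scaled AUC; a
#'   proposal is accepted only when it exceeds the incumbent by more than
#'   this. The default 0 with strict inequality rejects equal-AUC moves,
#'   which guarantees termination.
#' @param seed used only to order evaluation of equal candidates
#'   reproducibly.
#' @return a list of class settings for [coordinateAscent()].
#' @export
ascentConfig <- function(maxPasses = 20L,
                         directionPolicy = c("best-of-both",
                                             "first-improvement"),
                         minImprovement = 0, seed = 1L) {
    stopifnot(maxPasses >= 1L, minImprovement >= 0)
    list(maxPasses = as.integer(maxPasses),
         directionPolicy = match.arg(directionPolicy),
         minImprovement = minImprovement,
         seed = as.integer(seed))
}

# Candidate values for one coordinate: +/- one step clamped to bounds
# (numeric; multiplicative scale uses *step and /step), flip (boolean),
# or every alternative choice (categorical). Proposals equal to the
# current value are dropped.
coordinateProposals <- function(p, current) {
    if (p$kind %in% c("integer", "real")) {
        cand <- if (p$scale == "multiplicative")
            c(current * p$step, current / p$step)
        else c(current + p$step, current - p$step)
        if (p$kind == "integer")
            cand <- as.integer(round(cand))
        cand <- pmin(pmax(cand, p$lower), p$upper)
        unique(cand[cand != current])
    } else if (p$kind == "boolean") {
        !current
    } else {
        setdiff(p$choices, as.character(current))
    }
}

#' Greedy coordinate ascent over a parameter space
#'
#' Starting from `start` (by convention the assembler's default vector),
#' repeatedly passes over the parameters in declaration order. For each
#' parameter it proposes single-step moves (numeric: current +/- step,
#' clamped; boolean: flip; categorical: each alternative), evaluates them
#' with `objective`, and — under the `best-of-both` policy — accepts the
#' best proposal iff it exceeds the incumbent by more than
#' `minImprovement`. The procedure stops after a full pass with no
#' accepted step, or after `maxPasses`. The objective is memoized so no
#' vector is ever evaluated twice; an objective error on a non-start
#' vector is downgraded to a warning and scored 0 (a failed assembler run
#' is simply a useless candidate), while an error on the start vector
#' propagates.
#'
#' @param start a [ParameterVector-class], valid under `space`.
#' @param space a [ParameterSpace-class].
#' @param objective function mapping a [ParameterVector-class] to a
#'   scaled AUC.
#' @param config an [ascentConfig()].
#' @return list with `vector` (the incumbent [ParameterVector-class]) and
#'   `trace` (an [AscentTrace-class]).
#' @examples
#' sp <- parameterSpace(
#'     parameterDef("a", "integer", 1, 0, 10, 1),
#'     parameterDef("b", "integer", 1, 0, 10, 1))
#' obj <- function(v) with(paramValues(v), -(a - 3)^2 - (b - 7)^2 + 100)
#' res <- coordinateAscent(defaultVector(sp), sp, obj)
#' paramValues(res$vector)   # a = 3, b = 7
#' @export
coordinateAscent <- function(start, space, objective,
                             config = ascentConfig()) {
    viol <- validateVector(space, start)
    if (length(viol))
        stop("invalid start vector: ", paste(viol, collapse = "; "))
    memo <- new.env(parent = emptyenv())
    evals <- 0L
    score <- function(v, isStart = FALSE) {
        key <- vectorKey(v)
        hit <- memo[[key]]
        if (!is.null(hit))
            return(hit)
        val <- if (isStart) {
            objective(v)
        } else {
            tryCatch(objective(v), error = function(e) {
                warning("objective failed (scored 0): ",
                        conditionMessage(e), call. = FALSE)
                0
            })
        }
        if (!is.finite(val))
            val <- 0
        evals <<- evals + 1L
        memo[[key]] <- val
        val
    }
    incumbent <- start
    incAuc <- score(start, isStart = TRUE)
    startAuc <- incAuc
    steps <- list()
    pass <- 0L
    repeat {
        pass <- pass + 1L
        accepted <- FALSE
        for (nm in names(space@params)) {
            p <- space@params[[nm]]
            props <- coordinateProposals(p, incumbent@values[[nm]])
            if (!length(props))
                next
            if (config$directionPolicy == "best-of-both") {
                vals <- vapply(props, function(pv) {
                    cand <- incumbent
                    cand@values[[nm]] <- pv
                    score(cand)
                }, numeric(1))
                best <- which.max(vals)   # ties: first proposal listed
                if (vals[best] > incAuc + config$minImprovement) {
                    old <- incumbent@values[[nm]]
                    incumbent@values[[nm]] <- props[[best]]
                    incAuc <- vals[best]
                    accepted <- TRUE
                    steps[[length(steps) + 1L]] <- data.frame(
                        pass = pass, parameter = nm,
                        old_value = formatParamValue(old),
                        new_value = formatParamValue(props[[best]]),
                        auc = incAuc, stringsAsFactors = FALSE)
                }
            } else {
                for (pv in props) {
                    cand <- incumbent
                    cand@values[[nm]] <- pv
                    val <- score(cand)
                    if (val > incAuc + config$minImprovement) {
                        old <- incumbent@values[[nm]]
                        incumbent <- cand
                        incAuc <- val
                        accepted <- TRUE
                        steps[[length(steps) + 1L]] <- data.frame(
                            pass = pass, parameter = nm,
                            old_value = formatParamValue(old),
                            new_value = formatParamValue(pv),
                            auc = incAuc, stringsAsFactors = FALSE)
                        break
                    }
                }
            }
        }
        if (!accepted || pass >= config$maxPasses)
            break
    }
    stepDf <- if (length(steps)) do.call(rbind, steps) else
        data.frame(pass = integer(0), parameter = character(0),
                   old_value = character(0), new_value = character(0),
                   auc = numeric(0), stringsAsFactors = FALSE)
    incumbent@provenance <- if (nzchar(start@provenance))
        paste0("CA:", start@provenance) else "CA"
    list(vector = incumbent,
         trace = new("AscentTrace", steps = stepDf,
                     evaluations = evals, startAuc = startAuc,
                     finalAuc = incAuc))
}

setMethod("show", "AscentTrace", function(object) {
    cat(sprintf("AscentTrace: %d accepted step%s, %d evaluation%s\n",
                nrow(object@steps),
                if (nrow(object@steps) == 1) "" else "s",
                object@evaluations,
                if (object@evaluations == 1) "" else "s"))
    cat(sprintf("  scaled AUC: %.4f -> %.4f\n", object@startAuc,
                object@finalAuc))
    invisible(NULL)
})

#' @rdname AscentTrace-class
#' @param x an [AscentTrace-class].
#' @export
ascentSteps <- function(x) {
    stopifnot(is(x, "AscentTrace"))
    x@steps
}

#' Build an advisor set by per-sample coordinate ascent
#'
#' Runs [coordinateAscent()] once per training sample, with the objective
#' being the scaled AUC of the assembly the adapter produces under each
#' candidate vector on that sample. The distinct resulting vectors — each
#' tagged with its source sample — form the advisor set, optionally
#' prepended with the default vector so advising can never fall below the
#' default.
#'
#' @param samples character vector of sample paths (BAMs for external
#'   adapters, token files for the mock adapter).
#' @param space a [ParameterSpace-class].
#' @param adapter an [AssemblerAdapter-class].
#' @param ref reference transcriptome ([Transcriptome-class] or GTF
#'   path).
#' @param config an [ascentConfig()].
#' @param includeDefault prepend the default vector (position 1).
#' @param workDir where intermediate assemblies are written.
#' @param singleExonOverlap passed to the estimator.
#' @return an [AdvisorSet-class].
#' @export
buildAdvisorSet <- function(samples, space, adapter, ref,
                            config = ascentConfig(),
                            includeDefault = TRUE,
                            workDir = tempfile("advisor-work-"),
                            singleExonOverlap = 0.8) {
    stopifnot(length(samples) >= 1L)
    if (is.character(ref))
        ref <- readGtf(ref)
    dir.create(workDir, recursive = TRUE, showWarnings = FALSE)
    found <- list()
    for (s in samples) {
        objective <- function(v) {
            path <- runAssembler(adapter, s, v, workDir)
            assemblyAUC(readGtf(path), ref,
                        singleExonOverlap = singleExonOverlap)
        }
        res <- coordinateAscent(defaultVector(space), space, objective,
                                config = config)
        res$vector@provenance <- paste0("CA:", basename(s))
        found[[length(found) + 1L]] <- res$vector
    }
    keys <- vapply(found, vectorKey, character(1))
    found <- found[!duplicated(keys)]
    if (includeDefault) {
        dflt <- defaultVector(space)
        found <- found[vapply(found, vectorKey, character(1)) !=
                           vectorKey(dflt)]
        found <- c(list(dflt), found)
    }
    advisorSet(found, includesDefault = includeDefault)
}
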