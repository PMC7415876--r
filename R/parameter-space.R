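# Parameter-space declarations, parameter vectors, advisor sets, and
# their file formats (YAML space files, TSV advisor-set files).

#' Declare one tunable parameter
#'
#' @param name parameter name (unique within a space).
#' @param kind one of `"integer"`, `"real"`, `"boolean"`, `"categorical"`.
#' @param default default value, of the declared kind.
#' @param lower,upper inclusive bounds (numeric kinds).
#' @param step positive increment used by coordinate ascent and by the
#'   sampling grid (numeric kinds).
#' @param choices value list (categorical kind).
#' @param flag command-line flag the assembler adapter renders this
#'   parameter with.
#' @param scale `"additive"` (proposals are value +/- step) or
#'   `"multiplicative"` (value * step, value / step) for scale-like
#'   parameters.
#' @return a plain list; collect with [parameterSpace()].
#' @export
parameterDef <- function(name, kind, default, lower = NA_real_,
                         upper = NA_real_, step = NA_real_, choices = NULL,
                         flag = paste0("--", name), scale = "additive") {
    stopifnot(is.character(name), length(name) == 1L)
    kind <- match.arg(kind, c("integer", "real", "boolean", "categorical"))
    scale <- match.arg(scale, c("additive", "multiplicative"))
    if (kind == "integer") {
        default <- as.integer(default); lower <- as.integer(lower)
        upper <- as.integer(upper); step <- as.integer(step)
    } else if (kind == "real") {
        default <- as.numeric(default); lower <- as.numeric(lower)
        upper <- as.numeric(upper); step <- as.numeric(step)
    } else if (kind == "boolean") {
        default <- as.logical(default)
    } else {
        choices <- as.character(choices); default <- as.character(default)
    }
    list(name = name, kind = kind, default = default, lower = lower,
         upper = upper, step = step, choices = choices, flag = flag,
         scale = scale)
}

#' Construct a ParameterSpace
#'
#' @param ... [parameterDef()] entries (or one list of them).
#' @return a [ParameterSpace-class].
#' @examples
#' sp <- parameterSpace(
#'     parameterDef("min_coverage", "real", 1, 0, 20, 0.5, flag = "-c"),
#'     parameterDef("min_length", "integer", 200, 50, 1000, 50, flag = "-m"))
#' defaultVector(sp)
#' @export
parameterSpace <- function(...) {
    ps <- list(...)
    if (length(ps) == 1L && is.null(ps[[1]]$name))
        ps <- ps[[1]]
    names(ps) <- vapply(ps, function(p) p$name, character(1))
    new("ParameterSpace", params = ps)
}

#' @rdname ParameterSpace-class
#' @param x a [ParameterSpace-class].
#' @export
setMethod("names", "ParameterSpace", function(x) names(x@params))

#' @rdname ParameterSpace-class
#' @export
setMethod("length", "ParameterSpace", function(x) length(x@params))

#' @rdname ParameterSpace-class
#' @export
parameterDefs <- function(x) {
    stopifnot(is(x, "ParameterSpace"))
    x@params
}

setMethod("show", "ParameterSpace", function(object) {
    cat(sprintf("ParameterSpace with %d parameter%s\n", length(object),
                if (length(object) == 1) "" else "s"))
    for (p in object@params) {
        rng <- switch(p$kind,
                      integer = ,
                      real = sprintf("[%s, %s] step %s", p$lower, p$upper,
                                     p$step),
                      boolean = "TRUE/FALSE",
                      categorical = paste(p$choices, collapse = "|"))
        cat(sprintf("  %-28s %-11s default %-8s %s\n", p$name, p$kind,
                    formatParamValue(p$default), rng))
    }
    invisible(NULL)
})

#' Construct a ParameterVector
#'
#' @param values named list (or vector) with exactly one value per
#'   declared parameter; names must match the space.
#' @param provenance free-text origin label.
#' @return a [ParameterVector-class].
#' @export
parameterVector <- function(values, provenance = "") {
    new("ParameterVector", values = as.list(values),
        provenance = provenance)
}

#' @rdname ParameterVector-class
#' @param x a [ParameterVector-class].
#' @export
paramValues <- function(x) {
    stopifnot(is(x, "ParameterVector"))
    x@values
}

#' @rdname ParameterVector-class
#' @export
provenance <- function(x) {
    stopifnot(is(x, "ParameterVector"))
    x@provenance
}

setMethod("show", "ParameterVector", function(object) {
    cat(sprintf("ParameterVector [%s]\n",
                if (nzchar(object@provenance)) object@provenance else
                    "unlabelled"))
    v <- vapply(object@values, formatParamValue, character(1))
    cat(" ", paste(names(v), v, sep = "=", collapse = " "), "\n")
    invisible(NULL)
})

# Canonical key: values rendered in the vector's own name order after
# sorting, so logically equal vectors compare equal.
vectorKey <- function(v) {
    vals <- v@values[order(names(v@values))]
    paste(names(vals), vapply(vals, formatParamValue, character(1)),
          sep = "=", collapse = ";")
}

#' The default parameter vector of a space
#'
#' @param space a [ParameterSpace-class].
#' @return a [ParameterVector-class] with provenance `"default"`.
#' @export
defaultVector <- function(space) {
    stopifnot(is(space, "ParameterSpace"))
    parameterVector(lapply(space@params, function(p) p$default),
                    provenance = "default")
}

#' Validate a parameter vector against a space
#'
#' @param space a [ParameterSpace-class].
#' @param v a [ParameterVector-class].
#' @return character vector of violation descriptions; empty iff `v` is
#'   valid (missing / extra parameters, wrong kind, out-of-bounds values,
#'   values not among declared choices).
#' @examples
#' sp <- parameterSpace(parameterDef("k", "integer", 5, 0, 10, 1))
#' validateVector(sp, defaultVector(sp))          # character(0)
#' validateVector(sp, parameterVector(list(k = -3)))
#' @export
validateVector <- function(space, v) {
    stopifnot(is(space, "ParameterSpace"), is(v, "ParameterVector"))
    out <- character(0)
    declared <- names(space@params)
    got <- names(v@values)
    for (m in setdiff(declared, got))
        out <- c(out, sprintf("missing parameter '%s'", m))
    for (e in setdiff(got, declared))
        out <- c(out, sprintf("extra parameter '%s'", e))
    for (nm in intersect(declared, got)) {
        p <- space@params[[nm]]
        val <- v@values[[nm]]
        if (length(val) != 1L || is.na(val)) {
            out <- c(out, sprintf("parameter '%s': value must be a single non-missing value", nm))
            next
        }
        if (p$kind %in% c("integer", "real")) {
            if (!is.numeric(val)) {
                out <- c(out, sprintf("parameter '%s': expected %s, got %s",
                                      nm, p$kind, class(val)[1]))
            } else {
                if (p$kind == "integer" && val != round(val))
                    out <- c(out, sprintf("parameter '%s': expected integer, got %s",
                                          nm, formatParamValue(val)))
                if (val < p$lower || val > p$upper)
                    out <- c(out, sprintf("parameter '%s': value %s outside [%s, %s]",
                                          nm, formatParamValue(val),
                                          formatParamValue(p$lower),
                                          formatParamValue(p$upper)))
            }
        } else if (p$kind == "boolean") {
            if (!is.logical(val))
                out <- c(out, sprintf("parameter '%s': expected boolean, got %s",
                                      nm, class(val)[1]))
        } else if (!as.character(val) %in% p$choices) {
            out <- c(out, sprintf("parameter '%s': value '%s' not among choices",
                                  nm, as.character(val)))
        }
    }
    out
}

#' Construct an AdvisorSet
#'
#' @param vectors list of [ParameterVector-class] objects (pairwise
#'   distinct).
#' @param includesDefault whether position 1 holds the assembler default
#'   (the convention that makes advising never worse than the default).
#' @return an [AdvisorSet-class].
#' @export
advisorSet <- function(vectors, includesDefault = FALSE) {
    new("AdvisorSet", vectors = vectors,
        includesDefault = includesDefault)
}

#' @rdname AdvisorSet-class
#' @param x an [AdvisorSet-class].
#' @export
setMethod("length", "AdvisorSet", function(x) length(x@vectors))

#' @rdname AdvisorSet-class
#' @export
advisorVectors <- function(x) {
    stopifnot(is(x, "AdvisorSet"))
    x@vectors
}

#' @rdname AdvisorSet-class
#' @export
includesDefault <- function(x) {
    stopifnot(is(x, "AdvisorSet"))
    x@includesDefault
}

setMethod("show", "AdvisorSet", function(object) {
    cat(sprintf("AdvisorSet with %d parameter vector%s%s\n",
                length(object), if (length(object) == 1) "" else "s",
                if (object@includesDefault) " (default in position 1)" else ""))
    prov <- vapply(object@vectors, provenance, character(1))
    prov[!nzchar(prov)] <- "?"
    cat("  provenance:", paste(head(prov, 8L), collapse = ", "),
        if (length(prov) > 8L) ", ..." else "", "\n")
    invisible(NULL)
})

#' Read / write advisor sets as TSV
#'
#' The format is one header row of parameter names plus a final
#' `provenance` column, and one row per vector. `readAdvisorSet()`
#' validates the header against the space (an error lists the symmetric
#' difference of names), validates every row with [validateVector()], and
#' rejects duplicate rows.
#'
#' @param path TSV file path.
#' @param space the [ParameterSpace-class] the vectors belong to.
#' @return `readAdvisorSet()`: an [AdvisorSet-class] (with
#'   `includesDefault` set when row 1 equals the space default);
#'   `writeAdvisorSet()`: `path`, invisibly.
#' @export
readAdvisorSet <- function(path, space) {
    stopifnot(is(space, "ParameterSpace"))
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE, colClasses = "character")
    declared <- names(space@params)
    got <- setdiff(colnames(df), "provenance")
    if (!setequal(got, declared)) {
        miss <- setdiff(declared, got)
        extra <- setdiff(got, declared)
        stop(sprintf("advisor-set header does not match the parameter space%s%s",
                     if (length(miss)) paste0("; missing: ",
                                              paste(miss, collapse = ", "))
                     else "",
                     if (length(extra)) paste0("; unexpected: ",
                                               paste(extra, collapse = ", "))
                     else ""))
    }
    vectors <- lapply(seq_len(nrow(df)), function(i) {
        vals <- lapply(declared, function(nm) {
            p <- space@params[[nm]]
            raw <- df[[nm]][i]
            switch(p$kind,
                   integer = as.integer(raw),
                   real = as.numeric(raw),
                   boolean = as.logical(raw),
                   categorical = raw)
        })
        names(vals) <- declared
        v <- parameterVector(vals,
                             provenance = if ("provenance" %in% colnames(df))
                                 df$provenance[i] else "")
        viol <- validateVector(space, v)
        if (length(viol))
            stop(sprintf("advisor-set row %d invalid: %s", i,
                         paste(viol, collapse = "; ")))
        v
    })
    keys <- vapply(vectors, vectorKey, character(1))
    if (anyDuplicated(keys))
        stop(sprintf("advisor-set rows %s are duplicates",
                     paste(which(keys == keys[anyDuplicated(keys)]),
                           collapse = " and ")))
    includes <- length(vectors) > 0L &&
        keys[1L] == vectorKey(defaultVector(space))
    advisorSet(vectors, includesDefault = includes)
}

#' @rdname readAdvisorSet
#' @param set an [AdvisorSet-class] to write.
#' @export
writeAdvisorSet <- function(set, path, space) {
    stopifnot(is(set, "AdvisorSet"), is(space, "ParameterSpace"))
    declared <- names(space@params)
    rows <- vapply(set@vectors, function(v) {
        paste(c(vapply(declared, function(nm)
            formatParamValue(v@values[[nm]]), character(1)),
            v@provenance), collapse = "\t")
    }, character(1))
    writeLines(c(paste(c(declared, "provenance"), collapse = "\t"), rows),
               path)
    invisible(path)
}

#' Read / write parameter-space declarations as YAML
#'
#' One entry per parameter with fields `name`, `kind`, `default`,
#' `lower`, `upper`, `step`, `choices`, `flag`, `scale`. Shipped space
#' files for Scallop (18 parameters) and StringTie (9 parameters) live in
#' `system.file("extdata", package = "TranscriptAdvisor")`; their names
#' and bounds are transcribed from each tool's documentation and are
#' versioned per assembler release in the file header.
#'
#' @param path YAML file path.
#' @return `readParameterSpace()`: a [ParameterSpace-class];
#'   `writeParameterSpace()`: `path`, invisibly.
#' @examples
#' sp <- readParameterSpace(system.file("extdata",
#'     "stringtie_parameters.yaml", package = "TranscriptAdvisor"))
#' length(sp)   # 9
#' @export
readParameterSpace <- function(path) {
    y <- yaml::read_yaml(path)
    entries <- y$parameters %||% y
    defs <- lapply(entries, function(e) {
        parameterDef(name = e$name, kind = e$kind, default = e$default,
                     lower = e$lower %||% NA_real_,
                     upper = e$upper %||% NA_real_,
                     step = e$step %||% NA_real_,
                     choices = e$choices,
                     flag = e$flag %||% paste0("--", e$name),
                     scale = e$scale %||% "additive")
    })
    parameterSpace(defs)
}

#' @rdname readParameterSpace
#' @param space a [ParameterSpace-class] to write.
#' @export
writeParameterSpace <- function(space, path) {
    stopifnot(is(space, "ParameterSpace"))
    entries <- lapply(unname(space@params), function(p) {
        e <- list(name = p$name, kind = p$kind, default = p$default,
                  flag = p$flag, scale = p$scale)
        if (p$kind %in% c("integer", "real"))
            e <- c(e, list(lower = p$lower, upper = p$upper, step = p$step))
        if (p$kind == "categorical")
            e <- c(e, list(choices = p$choices))
        e
    })
    yaml::write_yaml(list(parameters = entries), path)
    invisible(path)
}
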