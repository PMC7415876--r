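# Assembler adapters: external Scallop/StringTie processes and the fully
# internal mock assembler with a planted parameter optimum.

#' Construct a mock landscape
#'
#' The mock assembler's output quality is a declared separable unimodal
#' function of the parameter vector (see [MockLandscape-class]), which
#' makes the full advising stack (ascend, build set, select subset,
#' advise) runnable end to end in seconds with no external binaries, and
#' gives every experiment a known ground truth.
#'
#' @param space a [ParameterSpace-class].
#' @param optimum planted optimum `p*`; defaults to the space default.
#' @param weights named per-parameter weights; default 0.3 everywhere.
#' @param reference reference [Transcriptome-class]; default a generated
#'   200-transcript reference.
#' @param maxSensitivity fraction of the reference recovered at quality 1.
#' @param fpMax false-positive count at quality 0 (decays linearly with
#'   quality).
#' @param sampleShift when TRUE the effective optimum is displaced per
#'   sample seed, so different samples favor different vectors.
#' @param optimum2 optional second optimum for a bimodal landscape.
#' @param seed landscape seed.
#' @return a [MockLandscape-class].
#' @export
mockLandscape <- function(space, optimum = defaultVector(space),
                          weights = NULL, reference = NULL,
                          maxSensitivity = 0.8, fpMax = 120L,
                          sampleShift = FALSE, optimum2 = NULL,
                          seed = 1L) {
    if (is.null(weights))
        weights <- setNames(rep(0.3, length(space)), names(space))
    if (is.null(reference))
        reference <- generateReference(nGenes = 100,
                                       transcriptsPerGene = 1:3,
                                       seed = deriveSeed(seed, "ref"))
    new("MockLandscape", space = space, optimum = optimum,
        optimum2 = if (is.null(optimum2)) list() else list(optimum2),
        weights = weights[names(space)], reference = reference,
        maxSensitivity = maxSensitivity, fpMax = as.integer(fpMax),
        sampleShift = sampleShift, seed = as.integer(seed))
}

# Normalized squared distance between two vectors on a space:
# numeric -> (difference / step)^2, boolean/categorical -> 0/1.
vectorDistance2 <- function(space, v, w) {
    vapply(names(space@params), function(nm) {
        p <- space@params[[nm]]
        a <- v@values[[nm]]; b <- w@values[[nm]]
        if (p$kind %in% c("integer", "real"))
            ((as.numeric(a) - as.numeric(b)) / p$step)^2
        else as.numeric(!identical(as.character(a), as.character(b)))
    }, numeric(1))
}

#' Quality of a parameter vector under a mock landscape
#'
#' `quality(p) = exp(-sum_i w_i d_i(p, p*)^2)` with `d_i` the
#' per-parameter distance in step units (numeric) or 0/1 (boolean and
#' categorical); `quality(p*) = 1`. For bimodal landscapes the quality is
#' the larger of the primary mode and 0.9 times the secondary mode.
#'
#' @param landscape a [MockLandscape-class].
#' @param v a valid [ParameterVector-class].
#' @param sampleSeed sample seed; with `sampleShift = TRUE` the distance
#'   is measured from [effectiveOptimum()] for this seed.
#' @return quality in `(0, 1]`.
#' @export
landscapeQuality <- function(landscape, v, sampleSeed = 0L) {
    opt <- effectiveOptimum(landscape, sampleSeed)
    q <- exp(-sum(landscape@weights *
                  vectorDistance2(landscape@space, v, opt)))
    if (length(landscape@optimum2)) {
        q2 <- exp(-sum(landscape@weights *
                       vectorDistance2(landscape@space, v,
                                       landscape@optimum2[[1]])))
        q <- max(q, 0.9 * q2)
    }
    q
}

#' Per-sample effective optimum of a mock landscape
#'
#' With `sampleShift = TRUE`, each sample seed deterministically
#' displaces two numeric coordinates of the planted optimum by 1-2 steps
#' (clamped to bounds), emulating samples that favor different parameter
#' vectors — the premise of parameter advising. With
#' `sampleShift = FALSE` the planted optimum itself is returned.
#'
#' @inheritParams landscapeQuality
#' @return a [ParameterVector-class].
#' @export
effectiveOptimum <- function(landscape, sampleSeed = 0L) {
    if (!landscape@sampleShift)
        return(landscape@optimum)
    space <- landscape@space
    numNames <- names(space@params)[vapply(space@params, function(p)
        p$kind %in% c("integer", "real"), logical(1))]
    vals <- landscape@optimum@values
    if (length(numNames)) {
        withLocalSeed(deriveSeed(landscape@seed, sampleSeed, "shift"), {
            pick <- sample(numNames, min(2L, length(numNames)))
            for (nm in pick) {
                p <- space@params[[nm]]
                delta <- sample(c(-2L, -1L, 1L, 2L), 1L) * p$step
                newVal <- min(max(vals[[nm]] + delta, p$lower), p$upper)
                vals[[nm]] <- if (p$kind == "integer") as.integer(newVal)
                              else newVal
            }
        })
    }
    parameterVector(vals, provenance = sprintf("optimum:%d", sampleSeed))
}

# Sample-level material shared by every vector on the same sample: a
# fixed priority order over reference transcripts, fixed true-positive
# coverages, and a fixed pool of perturbed false positives with fixed
# coverages. Holding these fixed makes the mock AUC a monotone function
# of quality alone. Memoized per (landscape, sample): the material is a
# pure function of the landscape content and the sample seed.
.materialCache <- new.env(parent = emptyenv())

landscapeFingerprint <- function(landscape) {
    u <- unlist(landscape@reference@exons, use.names = FALSE)
    deriveSeed(landscape@seed, length(landscape@reference),
               landscape@fpMax,
               sum(as.numeric(start(u))) %% 2^30,
               sum(as.numeric(end(u))) %% 2^30)
}

mockSampleMaterial <- function(landscape, sampleSeed) {
    cacheKey <- paste0(landscapeFingerprint(landscape), ":", sampleSeed)
    hit <- .materialCache[[cacheKey]]
    if (!is.null(hit))
        return(hit)
    ref <- landscape@reference
    nref <- length(ref)
    withLocalSeed(deriveSeed(landscape@seed, sampleSeed, "material"), {
        priority <- sample(nref)
        tpCov <- rlnorm(nref, meanlog = log(10), sdlog = 0.5)
        fpPool <- perturbTranscripts(ref, n = landscape@fpMax,
                                     idPrefix = "fp")
        fpCov <- rlnorm(landscape@fpMax, meanlog = log(2), sdlog = 0.5)
    })
    out <- list(priority = priority, tpCov = tpCov, fpPool = fpPool,
                fpCov = fpCov)
    if (length(ls(.materialCache)) > 256L)
        rm(list = ls(.materialCache), envir = .materialCache)
    .materialCache[[cacheKey]] <- out
    out
}

#' Run the mock assembler
#'
#' Deterministically produces an assembly whose agreement with the
#' landscape's reference is governed by the vector's quality `q`:
#' `round(q * maxSensitivity * |reference|)` reference transcripts are
#' copied verbatim as true positives (highest priority first, under a
#' seed-derived fixed priority) with coverages drawn from a high-mean
#' log-normal, and `round(fpMax * (1 - q))` intron-perturbed false
#' positives are added with low-mean coverages. The same (landscape,
#' vector, sample seed) always yields an identical Transcriptome.
#'
#' @inheritParams landscapeQuality
#' @return a [Transcriptome-class].
#' @examples
#' sp <- parameterSpace(parameterDef("k", "integer", 5, 0, 10, 1))
#' l <- mockLandscape(sp, seed = 7)
#' asm <- mockAssemble(l, defaultVector(sp), sampleSeed = 1)
#' assemblyAUC(asm, l@reference)
#' @export
mockAssemble <- function(landscape, v, sampleSeed = 0L) {
    viol <- validateVector(landscape@space, v)
    if (length(viol))
        stop("invalid vector: ", paste(viol, collapse = "; "))
    q <- landscapeQuality(landscape, v, sampleSeed)
    ref <- landscape@reference
    nref <- length(ref)
    mat <- mockSampleMaterial(landscape, sampleSeed)
    nTP <- round(q * landscape@maxSensitivity * nref)
    nFP <- round(landscape@fpMax * (1 - q))
    tpIdx <- mat$priority[seq_len(nTP)]
    pieces <- list()
    if (nTP > 0L) {
        tp <- ref[tpIdx]
        grl <- tp@exons
        names(grl) <- sprintf("asm.tp.%s", names(grl))
        pieces$tp <- Transcriptome(grl, geneId = geneIds(tp),
                                   coverage = mat$tpCov[tpIdx])
    }
    if (nFP > 0L) {
        fp <- mat$fpPool[seq_len(nFP)]
        txCoverage(fp) <- mat$fpCov[seq_len(nFP)]
        pieces$fp <- fp
    }
    if (!length(pieces))
        return(Transcriptome(GRangesList()))
    combineTranscriptomes(pieces)
}

# Concatenate Transcriptomes (ids must stay unique).
combineTranscriptomes <- function(xs) {
    grl <- do.call(c, unname(lapply(xs, function(x) x@exons)))
    gene <- unlist(lapply(xs, function(x) unname(geneIds(x))))
    cov <- unlist(lapply(xs, function(x) unname(txCoverage(x))))
    Transcriptome(grl, geneId = gene, coverage = cov)
}

#' Mock assembler adapter
#'
#' Wraps a [MockLandscape-class] behind the [runAssembler()] contract.
#' The `sample` argument is a token file whose first line is an integer
#' sample seed (see [writeSampleToken()]).
#'
#' @param landscape a [MockLandscape-class].
#' @param name adapter label.
#' @return a [MockAssemblerAdapter-class].
#' @export
mockAssemblerAdapter <- function(landscape, name = "mock") {
    new("MockAssemblerAdapter", name = name, timeout = Inf,
        landscape = landscape,
        cache = new.env(parent = emptyenv()))
}

#' Write a mock sample token file
#'
#' @param sampleSeed integer seed identifying the sample.
#' @param path output path; default a file in `tempdir()`.
#' @return the token path.
#' @export
writeSampleToken <- function(sampleSeed, path = tempfile(
        pattern = sprintf("sample-%d-", sampleSeed), fileext = ".txt")) {
    writeLines(as.character(as.integer(sampleSeed)), path)
    path
}

readSampleToken <- function(path) {
    s <- suppressWarnings(as.integer(readLines(path, n = 1L)))
    if (is.na(s))
        stop("mock sample token file must contain an integer seed: ", path)
    s
}

#' @rdname runAssembler
#' @export
setMethod("runAssembler", "MockAssemblerAdapter",
          function(adapter, sample, vector, outDir, ...) {
    if (!file.exists(sample))
        stop("sample file not found: ", sample)
    seed <- readSampleToken(sample)
    key <- vectorKey(vector)
    out <- file.path(outDir,
                     sprintf("mock-s%d-%s.gtf", seed, shortHash(key)))
    if (!file.exists(out)) {
        asm <- mockAssemble(adapter@landscape, vector, sampleSeed = seed)
        writeGtf(asm, out, source = adapter@name)
    }
    out
})

#' Scallop / StringTie adapters
#'
#' Invoke the external assembler as a subprocess, rendering the parameter
#' vector through the space's flags. Scallop uses
#' `scallop -i sample.bam -o out.gtf flags...` with value-style boolean
#' flags; StringTie uses `stringtie sample.bam -o out.gtf flags...` with
#' presence-style boolean flags. These adapters are exercised only in
#' optional integration runs — the default test suite and all experiments
#' use the mock adapter.
#'
#' @param space the assembler's [ParameterSpace-class] (see
#'   [readParameterSpace()] and the shipped space files).
#' @param executable program name or path.
#' @param timeout seconds allowed per invocation.
#' @return a [CommandLineAdapter-class].
#' @export
scallopAdapter <- function(space, executable = "scallop", timeout = 3600) {
    new("CommandLineAdapter", name = "scallop", timeout = timeout,
        executable = executable, space = space, argOrder = "scallop",
        booleanStyle = "value")
}

#' @rdname scallopAdapter
#' @export
stringtieAdapter <- function(space, executable = "stringtie",
                             timeout = 3600) {
    new("CommandLineAdapter", name = "stringtie", timeout = timeout,
        executable = executable, space = space, argOrder = "stringtie",
        booleanStyle = "presence")
}

#' Render a parameter vector as command-line arguments
#'
#' Each declared parameter's flag is used exactly once. Boolean
#' parameters render as `flag true|false` (value style, Scallop) or as
#' the bare flag emitted only when TRUE (presence style, StringTie).
#' Rendering is injective over valid vectors (distinct vectors yield
#' distinct argument lists) for value-style booleans.
#'
#' @param space a [ParameterSpace-class].
#' @param v a valid [ParameterVector-class].
#' @param booleanStyle `"value"` or `"presence"`.
#' @return character vector of arguments.
#' @export
renderArgs <- function(space, v, booleanStyle = c("value", "presence")) {
    booleanStyle <- match.arg(booleanStyle)
    viol <- validateVector(space, v)
    if (length(viol))
        stop("invalid vector: ", paste(viol, collapse = "; "))
    args <- character(0)
    for (p in space@params) {
        val <- v@values[[p$name]]
        if (p$kind == "boolean") {
            if (booleanStyle == "value")
                args <- c(args, p$flag, tolower(as.character(val)))
            else if (isTRUE(val))
                args <- c(args, p$flag)
        } else {
            args <- c(args, p$flag, formatParamValue(val))
        }
    }
    args
}

#' @rdname runAssembler
#' @export
setMethod("runAssembler", "CommandLineAdapter",
          function(adapter, sample, vector, outDir, ...) {
    if (!file.exists(sample))
        stop("sample file not found: ", sample)
    out <- file.path(outDir, sprintf("%s-%s.gtf", adapter@name,
                                     shortHash(vectorKey(vector))))
    flagArgs <- renderArgs(adapter@space, vector,
                           booleanStyle = adapter@booleanStyle)
    args <- switch(adapter@argOrder,
                   scallop = c("-i", sample, "-o", out, flagArgs),
                   stringtie = c(sample, "-o", out, flagArgs),
                   stop("unknown argOrder: ", adapter@argOrder))
    t0 <- Sys.time()
    res <- suppressWarnings(system2(adapter@executable, args,
                                    stdout = TRUE, stderr = TRUE,
                                    timeout = adapter@timeout))
    status <- attr(res, "status") %||% 0L
    message(sprintf("[%s] %s %s -> exit %d (%.1fs)", adapter@name,
                    adapter@executable, paste(args, collapse = " "),
                    status,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    if (status != 0L || !file.exists(out) || file.size(out) == 0L)
        stop(sprintf("assembler '%s' failed (exit %d): %s", adapter@name,
                     status, paste(tail(res, 20L), collapse = "\n")))
    out
})

# Perturb n transcripts drawn from ref: one intron boundary moved by
# >= 2 bases (multi-exon sources), so a perturbed transcript can never
# match its source chain; perturbed chains are also checked against the
# whole reference chain set and redrawn on collision. Single-exon
# sources are shifted far enough to break any reciprocal-overlap match.
# Works on plain coordinate vectors; the GRangesList is built once.
perturbTranscripts <- function(ref, n, idPrefix = "fp",
                               singleExonOverlap = 0.8) {
    if (n == 0L)
        return(Transcriptome(GRangesList()))
    grl <- ref@exons
    nEx <- elementNROWS(grl)
    u <- unlist(grl, use.names = FALSE)
    grp <- rep.int(seq_along(grl), nEx)
    sList <- unname(split(start(u), grp))
    eList <- unname(split(end(u), grp))
    meta <- txMeta(ref)
    multi <- which(nEx > 1L)
    refKeySet <- paste0(meta$chrom[multi], "|", meta$strand[multi], "|",
                        meta$chain[multi])
    srcPool <- if (length(multi)) multi else seq_along(nEx)
    src <- sample(srcPool, n, replace = TRUE)
    outS <- vector("list", n); outE <- vector("list", n)
    for (i in seq_len(n)) {
        j <- src[i]
        s0 <- sList[[j]]; e0 <- eList[[j]]
        nx <- length(s0)
        for (attempt in 1:25) {
            s <- s0; e <- e0
            if (nx == 1L) {
                delta <- sample(c(-1L, 1L), 1L) *
                    ((e - s + 1L) + sample(2:10, 1L))
                s <- max(1L, s0 + delta); e <- s + (e0 - s0)
                ov <- max(0L, min(e, e0) - max(s, s0) + 1L)
                if (ov / (e0 - s0 + 1L) < singleExonOverlap) break
            } else {
                k <- sample(nx - 1L, 1L)   # boundary of intron k
                delta <- sample(c(-1L, 1L), 1L) * sample(2:10, 1L)
                newEnd <- max(s[k], min(e[k] + delta, s[k + 1L] - 2L))
                if (newEnd == e[k])        # clamped back onto the original
                    newEnd <- max(s[k], e[k] - 2L)
                e[k] <- newEnd
                key <- paste0(meta$chrom[j], "|", meta$strand[j], "|",
                              paste(paste0(e[-nx] + 1L, "-", s[-1L] - 1L),
                                    collapse = ","))
                if (!key %in% refKeySet) break
            }
        }
        outS[[i]] <- s; outE[[i]] <- e
    }
    lens <- lengths(outS)
    gr <- GRanges(rep(meta$chrom[src], lens),
                  IRanges(unlist(outS), unlist(outE)),
                  strand = rep(meta$strand[src], lens))
    out <- relist(gr, PartitioningByEnd(cumsum(lens),
                                        names = sprintf("%s.%d", idPrefix,
                                                        seq_len(n))))
    Transcriptome(out, geneId = mcols(grl)$gene_id[src],
                  coverage = rep(NA_real_, n))
}
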