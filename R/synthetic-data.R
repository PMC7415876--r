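# Synthetic data: reference transcriptomes, assemblies with planted
# true/false positives, and random advisor sets. Everything is a pure
# function of its seed.

#' Generate a synthetic reference transcriptome
#'
#' Genes are placed without overlap along `chromCount` chromosomes;
#' transcripts within a gene share the gene's locus but have pairwise
#' distinct intron chains. Exon and intron lengths are uniform over the
#' given ranges. Multi-transcript genes are all multi-exon (so chains can
#' differ); single-transcript genes are single-exon with probability
#' `singleExonProb`, giving the reference a mix of multi- and single-exon
#' transcripts.
#'
#' @param nGenes number of genes (0 gives an empty transcriptome).
#' @param transcriptsPerGene integer vector sampled uniformly per gene.
#' @param exonsPerTranscript integer vector (values >= 1) sampled
#'   uniformly per transcript; forced to >= 2 in multi-transcript genes.
#' @param exonLengthRange,intronLengthRange inclusive positive-integer
#'   ranges.
#' @param chromCount number of chromosomes genes are spread over.
#' @param singleExonProb probability a single-transcript gene is
#'   single-exon.
#' @param seed generator seed; identical seeds give identical outputs.
#' @return a [Transcriptome-class] with coverage absent (`NA`), as is
#'   usual for references.
#' @examples
#' ref <- generateReference(nGenes = 50, seed = 1)
#' ref
#' @export
generateReference <- function(nGenes = 100, transcriptsPerGene = 1:3,
                              exonsPerTranscript = 1:8,
                              exonLengthRange = c(100L, 300L),
                              intronLengthRange = c(60L, 500L),
                              chromCount = 3L, singleExonProb = 0.25,
                              seed = 1L) {
    stopifnot(all(exonsPerTranscript >= 1L),
              exonLengthRange[1] >= 1L, exonLengthRange[2] >= exonLengthRange[1],
              intronLengthRange[1] >= 1L,
              intronLengthRange[2] >= intronLengthRange[1])
    if (nGenes == 0L)
        return(Transcriptome(GRangesList()))
    withLocalSeed(seed, {
        chromOf <- rep_len(paste0("chr", seq_len(chromCount)), nGenes)
        cursor <- setNames(rep(1L, chromCount),
                           paste0("chr", seq_len(chromCount)))
        grl <- list(); genes <- character(0)
        for (g in seq_len(nGenes)) {
            gid <- sprintf("g%04d", g)
            chrom <- chromOf[g]
            strand <- sample(c("+", "-"), 1L)
            ntx <- sample(transcriptsPerGene, 1L)
            geneStart <- cursor[[chrom]]
            geneEnd <- geneStart
            chains <- character(0)
            for (t in seq_len(ntx)) {
                nex <- sample(exonsPerTranscript, 1L)
                if (ntx > 1L)
                    nex <- max(nex, 2L)
                else if (t == 1L && runif(1) < singleExonProb)
                    nex <- 1L
                for (attempt in 1:50) {
                    exLen <- sample(exonLengthRange[1]:exonLengthRange[2],
                                    nex, replace = TRUE)
                    inLen <- if (nex > 1L)
                        sample(intronLengthRange[1]:intronLengthRange[2],
                               nex - 1L, replace = TRUE) else integer(0)
                    starts <- geneStart +
                        cumsum(c(0L, exLen[-nex] + inLen))
                    ends <- starts + exLen - 1L
                    key <- paste(starts[-1], ends[-nex], sep = "-",
                                 collapse = ",")
                    if (nex == 1L || !key %in% chains) break
                }
                chains <- c(chains, key)
                grl[[sprintf("%s.t%d", gid, t)]] <-
                    GRanges(chrom, IRanges(starts, ends), strand = strand)
                genes <- c(genes, gid)
                geneEnd <- max(geneEnd, ends[nex])
            }
            cursor[[chrom]] <- geneEnd +
                sample(intronLengthRange[1]:intronLengthRange[2], 1L) + 1000L
        }
        out <- Transcriptome(GRangesList(grl), geneId = genes)
    })
    out
}

#' Generate a synthetic assembly with planted truth
#'
#' Selects `round(tpFraction * |ref|)` reference transcripts verbatim as
#' true positives, with coverages from a high-mean log-normal, and adds
#' `fpCount` intron-perturbed false positives (perturbed by at least two
#' bases, so they can never accidentally match; they keep their source
#' gene's locus, mimicking plausible mis-assemblies) with low-mean
#' log-normal coverages. True positives skew to higher coverage, so
#' threshold sweeps produce non-trivial curves.
#'
#' @param ref reference [Transcriptome-class].
#' @param tpFraction fraction of the reference recovered, in `[0, 1]`.
#' @param fpCount number of false-positive transcripts.
#' @param tpMeanlog,tpSdlog,fpMeanlog,fpSdlog log-normal coverage
#'   parameters for true and false positives.
#' @param seed generator seed.
#' @return a [Transcriptome-class]; true positives are named
#'   `asm.tp.<refid>`, false positives `asm.fp.<i>`.
#' @examples
#' ref <- generateReference(nGenes = 40, seed = 1)
#' asm <- generateAssembly(ref, tpFraction = 0.5, fpCount = 10, seed = 2)
#' mean(matchTranscripts(asm, ref)$matched)
#' @export
generateAssembly <- function(ref, tpFraction, fpCount,
                             tpMeanlog = log(10), tpSdlog = 0.5,
                             fpMeanlog = log(2), fpSdlog = 0.5,
                             seed = 1L) {
    stopifnot(is(ref, "Transcriptome"), tpFraction >= 0, tpFraction <= 1,
              fpCount >= 0)
    nref <- length(ref)
    nTP <- round(tpFraction * nref)
    withLocalSeed(seed, {
        pieces <- list()
        if (nTP > 0L) {
            idx <- sample(nref, nTP)
            tp <- ref[idx]
            grl <- tp@exons
            names(grl) <- sprintf("asm.tp.%s", names(grl))
            pieces$tp <- Transcriptome(
                grl, geneId = geneIds(tp),
                coverage = rlnorm(nTP, tpMeanlog, tpSdlog))
        }
        if (fpCount > 0L) {
            fp <- perturbTranscripts(ref, n = fpCount, idPrefix = "asm.fp")
            txCoverage(fp) <- rlnorm(fpCount, fpMeanlog, fpSdlog)
            pieces$fp <- fp
        }
        out <- if (length(pieces)) combineTranscriptomes(pieces)
               else Transcriptome(GRangesList())
    })
    out
}

#' Sample a random advisor set
#'
#' Draws `n` pairwise-distinct parameter vectors uniformly: numeric
#' parameters uniform on the step grid within bounds, boolean and
#' categorical uniform over their values. The random-set baseline the
#' learned advisor sets are compared against.
#'
#' @param space a [ParameterSpace-class].
#' @param n number of vectors (must not exceed the number of distinct
#'   grid points).
#' @param seed generator seed.
#' @return an [AdvisorSet-class] with provenance labels `random:<i>`.
#' @export
randomAdvisorSet <- function(space, n, seed = 1L) {
    stopifnot(is(space, "ParameterSpace"), n >= 1L)
    gridPoints <- function(p)
        floor((p$upper - p$lower) / p$step + 1e-9) + 1
    gridSize <- prod(vapply(space@params, function(p) {
        switch(p$kind,
               integer = ,
               real = gridPoints(p),
               boolean = 2,
               categorical = length(p$choices))
    }, numeric(1)))
    if (n > gridSize)
        stop(sprintf("requested %d vectors but the grid has only %g distinct points",
                     n, gridSize))
    withLocalSeed(seed, {
        seen <- character(0)
        vectors <- list()
        tries <- 0L
        while (length(vectors) < n && tries < 1000L * n) {
            tries <- tries + 1L
            vals <- lapply(space@params, function(p) {
                switch(p$kind,
                       integer = ,
                       real = {
                           val <- p$lower +
                               (sample.int(gridPoints(p), 1L) - 1L) * p$step
                           val <- min(val, p$upper)
                           if (p$kind == "integer") as.integer(val) else val
                       },
                       boolean = sample(c(TRUE, FALSE), 1L),
                       categorical = sample(p$choices, 1L))
            })
            v <- parameterVector(vals,
                                 provenance = sprintf("random:%d",
                                                      length(vectors) + 1L))
            key <- vectorKey(v)
            if (!key %in% seen) {
                seen <- c(seen, key)
                vectors[[length(vectors) + 1L]] <- v
            }
        }
        if (length(vectors) < n)
            stop("could not sample enough distinct vectors")
        out <- advisorSet(vectors, includesDefault = FALSE)
    })
    out
}
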