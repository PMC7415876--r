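# Independent oracles the implementation is checked against. These are
# deliberately naive (all-pairs loops, exhaustive enumeration) and share
# no code with the package internals beyond plain accessors.

# All-pairs matcher: applies the matching rules transcript by transcript.
# Plain coordinate lists are extracted up front; the pairwise logic below
# is a direct transcription of the rules.
oracleFlatten <- function(x) {
    grl <- exonRanges(x)
    df <- as.data.frame(grl)
    byTx <- split(df[order(df$group, df$start), ],
                  factor(df$group, levels = seq_along(grl)))
    list(ids = names(grl),
         starts = lapply(byTx, `[[`, "start"),
         ends = lapply(byTx, `[[`, "end"),
         chrom = vapply(byTx, function(d) as.character(d$seqnames[1]),
                        character(1)),
         strand = vapply(byTx, function(d) as.character(d$strand[1]),
                         character(1)))
}

oracleMatch <- function(pred, ref, singleExonOverlap = 0.8) {
    P <- oracleFlatten(pred)
    R <- oracleFlatten(ref)
    strandCompat <- function(a, b) a == b || a == "*" || b == "*"
    labelOne <- function(i) {
        ps <- P$starts[[i]]; pe <- P$ends[[i]]
        hits <- character(0)
        for (j in seq_along(R$ids)) {
            if (R$chrom[j] != P$chrom[i]) next
            if (!strandCompat(P$strand[i], R$strand[j])) next
            rs <- R$starts[[j]]; re <- R$ends[[j]]
            if (length(ps) > 1 && length(rs) > 1) {
                if (length(ps) == length(rs) &&
                    all(pe[-length(pe)] + 1 == re[-length(re)] + 1) &&
                    all(ps[-1] - 1 == rs[-1] - 1))
                    hits <- c(hits, R$ids[j])
            } else if (length(ps) == 1 && length(rs) == 1) {
                ov <- min(pe, re) - max(ps, rs) + 1
                longer <- max(pe - ps + 1, re - rs + 1)
                if (ov >= 1 && ov / longer >= singleExonOverlap)
                    hits <- c(hits, R$ids[j])
            }
        }
        if (length(hits)) sort(hits)[1] else NA_character_
    }
    refHit <- vapply(seq_along(P$ids), labelOne, character(1))
    data.frame(transcript_id = P$ids,
               coverage = unname(txCoverage(pred)),
               matched = !is.na(refHit),
               matched_ref_id = refHit,
               stringsAsFactors = FALSE)
}

# Exhaustive threshold sweep + trapezoid, written as plain loops.
oracleAucFromLabels <- function(labels, referenceSize) {
    if (nrow(labels) == 0) return(0)
    cov <- labels$coverage
    cov[is.na(cov)] <- 0
    thresholds <- sort(unique(cov), decreasing = TRUE)
    sens <- numeric(0); prec <- numeric(0)
    for (t in thresholds) {
        keep <- cov >= t
        kept <- sum(keep)
        matchedKept <- sum(labels$matched & keep)
        distinctRef <- length(unique(
            labels$matched_ref_id[labels$matched & keep]))
        sens <- c(sens, distinctRef / referenceSize)
        prec <- c(prec, matchedKept / kept)
    }
    s <- c(0, sens)
    p <- c(prec[1], prec)
    area <- 0
    for (k in seq_len(length(s) - 1))
        area <- area + (s[k + 1] - s[k]) * (p[k] + p[k + 1]) / 2
    1e4 * area
}

oracleAuc <- function(pred, ref, singleExonOverlap = 0.8) {
    oracleAucFromLabels(oracleMatch(pred, ref, singleExonOverlap),
                        length(ref))
}

# Exhaustive optimum of an objective over the full integer/choice grid of
# a small parameter space.
oracleGridOptimum <- function(space, objective) {
    defs <- parameterDefs(space)
    grids <- lapply(defs, function(p) {
        switch(p$kind,
               integer = seq(p$lower, p$upper, by = p$step),
               real = seq(p$lower, p$upper, by = p$step),
               boolean = c(TRUE, FALSE),
               categorical = p$choices)
    })
    combos <- expand.grid(grids, stringsAsFactors = FALSE)
    best <- -Inf; bestRow <- NULL
    for (r in seq_len(nrow(combos))) {
        vals <- as.list(combos[r, , drop = FALSE])
        names(vals) <- names(defs)
        if (defs[[1]]$kind == "integer")
            vals <- lapply(seq_along(vals), function(k)
                if (defs[[k]]$kind == "integer") as.integer(vals[[k]])
                else vals[[k]])
        names(vals) <- names(defs)
        v <- parameterVector(vals)
        val <- objective(v)
        if (val > best) { best <- val; bestRow <- vals }
    }
    list(value = best, values = bestRow)
}

# Exhaustive best size-k subset of an AUC matrix by direct enumeration.
oracleBestSubset <- function(m, k) {
    combos <- utils::combn(ncol(m), k)
    best <- -Inf; bestSet <- NULL
    for (cidx in seq_len(ncol(combos))) {
        s <- combos[, cidx]
        rowBest <- apply(as.matrix(m)[, s, drop = FALSE], 1, max)
        sc <- sum(rowBest) / nrow(m)
        if (sc > best + 1e-12) { best <- sc; bestSet <- s }
    }
    list(score = best, subset = sort(bestSet))
}

# Random (assembly, reference) instance for matcher / AUC comparisons.
randomInstance <- function(seed, nGenes = 20, maxPred = 100) {
    ref <- generateReference(nGenes = nGenes, transcriptsPerGene = 1:2,
                             singleExonProb = 0.4, chromCount = 2,
                             seed = seed)
    set.seed(seed + 1)
    tpf <- runif(1, 0, 1)
    fpc <- sample(0:25, 1)
    asm <- generateAssembly(ref, tpFraction = min(tpf, maxPred / length(ref)),
                            fpCount = fpc, seed = seed + 3)
    list(ref = ref, asm = asm)
}
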