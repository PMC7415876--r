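# Compact advisor subsets: maximize the mean-over-examples of the best
# AUC achievable within the subset (the advising AUC on training data).

#' Advising score of a subset of advisor-set columns
#'
#' Given a training AUC matrix (examples in rows, parameter vectors in
#' columns, scaled AUC entries), the advising score of a subset of
#' columns is the mean over examples of the best entry among those
#' columns — the average advising AUC a subset would achieve on the
#' training examples.
#'
#' @param m numeric matrix, examples x vectors, entries in `[0, 1e4]`.
#' @param subset non-empty vector of column indices.
#' @return the advising score (numeric scalar).
#' @examples
#' m <- rbind(e1 = c(10, 0, 6), e2 = c(0, 10, 6), e3 = c(0, 0, 6))
#' advisingScore(m, 3)        # 6
#' advisingScore(m, c(1, 3))  # 7.33
#' @export
advisingScore <- function(m, subset) {
    m <- as.matrix(m)
    if (length(subset) == 0L)
        stop("subset must be non-empty")
    subset <- as.integer(subset)
    if (any(is.na(subset)) || any(subset < 1L) || any(subset > ncol(m)))
        stop("subset contains invalid column indices")
    mean(apply(m[, subset, drop = FALSE], 1L, max))
}

#' Greedy nested advisor subsets
#'
#' Forward selection on the training AUC matrix: the size-1 subset is the
#' argmax singleton of [advisingScore()]; each larger subset adds the
#' column with maximal marginal gain, ties broken by lowest column index.
#' Subsets are nested by construction, so scores are non-decreasing in
#' `k`. Rows that are all zero never influence selection and are flagged
#' with a message.
#'
#' @param m numeric matrix, examples x vectors.
#' @param kMax largest subset size (at most `ncol(m)`).
#' @return list of integer vectors, element `k` being the size-`k`
#'   subset.
#' @examples
#' m <- rbind(c(10, 0, 6), c(0, 10, 6), c(0, 0, 6))
#' greedySubsets(m, 2)   # list(3, c(3, 1))
#' @export
greedySubsets <- function(m, kMax) {
    m <- as.matrix(m)
    kMax <- as.integer(kMax)
    stopifnot(kMax >= 1L, kMax <= ncol(m))
    zero <- rowSums(m != 0) == 0L
    if (any(zero))
        message(sprintf("%d all-zero row(s) in the AUC matrix (never influence selection)",
                        sum(zero)))
    chosen <- integer(0)
    best <- rep(-Inf, nrow(m))
    out <- vector("list", kMax)
    for (k in seq_len(kMax)) {
        remaining <- setdiff(seq_len(ncol(m)), chosen)
        gains <- vapply(remaining, function(j)
            mean(pmax(best, m[, j])), numeric(1))
        pick <- remaining[which.max(gains)]   # which.max: lowest index wins
        chosen <- c(chosen, pick)
        best <- pmax(best, m[, pick])
        out[[k]] <- chosen
    }
    out
}

#' Exact best advisor subset by exhaustive enumeration
#'
#' Enumerates all size-`k` column subsets and returns the argmax of
#' [advisingScore()]; ties resolve to the lexicographically smallest
#' index list. Intended as the exact mode for small instances and as the
#' oracle greedy selection is checked against.
#'
#' @param m numeric matrix, examples x vectors.
#' @param k subset size.
#' @param budget maximum number of subsets to enumerate; when
#'   `choose(ncol(m), k)` exceeds it, an error directs the caller to
#'   [greedySubsets()].
#' @return integer vector of length `k` (sorted).
#' @export
exhaustiveSubset <- function(m, k, budget = 2e5) {
    m <- as.matrix(m)
    k <- as.integer(k)
    stopifnot(k >= 1L, k <= ncol(m))
    if (choose(ncol(m), k) > budget)
        stop(sprintf("C(%d, %d) exceeds the enumeration budget (%g); use greedySubsets()",
                     ncol(m), k, budget))
    combos <- combn(ncol(m), k)
    scores <- apply(combos, 2L, function(s) advisingScore(m, s))
    best <- max(scores)
    cand <- which(scores == best)
    # lexicographically smallest index list among the ties; combn emits
    # subsets in lexicographic order already, so the first tie wins
    sort(combos[, cand[1L]])
}
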