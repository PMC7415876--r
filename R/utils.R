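# Internal helpers: deterministic seeding, stable string keys, tiny hash.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators in the package route their randomness through
# this, so outputs are pure functions of their declared seeds.
withLocalSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Fold an arbitrary collection of integers / strings into one
# non-negative integer < 2^31 - 1 (polynomial rolling hash on doubles;
# exact because intermediate values stay < 2^53).
deriveSeed <- function(...) {
    parts <- list(...)
    h <- 17
    for (p in parts) {
        codes <- if (is.character(p))
            utf8ToInt(paste(p, collapse = "\x1f"))
        else as.integer(p)
        for (cc in codes)
            h <- (h * 31 + (cc %% 65521) + 1) %% 2147483629
    }
    as.integer(h)
}

# Short filename-safe hash of a string (hex, 8 chars).
shortHash <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    codes <- utf8ToInt(x)
    h1 <- 2166136261 %% 2147483629
    h2 <- 5381
    for (cc in codes) {
        h1 <- (h1 * 16777619 + cc) %% 2147483629
        h2 <- (h2 * 33 + cc) %% 2147483629
    }
    sprintf("%08x%08x", as.integer(h1 %% 4294967296 %% 2^31),
            as.integer(h2 %% 2^31))
}

# Canonical rendering of a scalar parameter value (used for keys, TSV,
# command lines). Numerics use up to 15 significant digits so that
# write/read round-trips are lossless.
formatParamValue <- function(x) {
    if (is.logical(x))
        return(ifelse(x, "TRUE", "FALSE"))
    if (is.numeric(x))
        return(format(x, digits = 15, scientific = FALSE, trim = TRUE))
    as.character(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
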