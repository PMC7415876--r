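# Parameter spaces, vectors, advisor sets, file formats, advising.

test_that("validateVector reports each violation by name", {
    sp <- makeSpace()
    expect_length(validateVector(sp, defaultVector(sp)), 0L)
    v <- parameterVector(list(p1 = -1L, p2 = 4L, p3 = 2, p4 = FALSE))
    expect_match(validateVector(sp, v), "p1.*outside")
    v2 <- parameterVector(list(p1 = 4L, p2 = 4L, p3 = 2, p4 = FALSE,
                               zzz = 1))
    expect_match(validateVector(sp, v2), "extra parameter 'zzz'")
    v3 <- parameterVector(list(p1 = 4L, p2 = 4L, p3 = 2))
    expect_match(validateVector(sp, v3), "missing parameter 'p4'")
    v4 <- parameterVector(list(p1 = 4L, p2 = 4L, p3 = 2, p4 = "yes"))
    expect_match(validateVector(sp, v4), "p4.*boolean")
    spc <- parameterSpace(parameterDef("mode", "categorical", "fast",
                                       choices = c("fast", "full")))
    expect_match(validateVector(spc, parameterVector(list(mode = "turbo"))),
                 "not among choices")
})

test_that("advisor sets reject duplicates and report distinctness", {
    sp <- makeSpace()
    d <- defaultVector(sp)
    expect_error(advisorSet(list(d, d)), "distinct")
    expect_error(advisorSet(list()), "at least one")
})

test_that("advisor-set TSV round-trips and validates", {
    sp <- makeSpace()
    set <- randomAdvisorSet(sp, 5, seed = 42)
    f <- tempfile(fileext = ".tsv")
    writeAdvisorSet(set, f, sp)
    back <- readAdvisorSet(f, sp)
    expect_equal(length(back), 5L)
    expect_identical(vapply(advisorVectors(back), TranscriptAdvisor:::vectorKey,
                            character(1)),
                     vapply(advisorVectors(set), TranscriptAdvisor:::vectorKey,
                            character(1)))
    expect_identical(vapply(advisorVectors(back), provenance, character(1)),
                     vapply(advisorVectors(set), provenance, character(1)))
    # header mismatch: missing and unexpected names are both listed
    tab <- read.delim(f, check.names = FALSE)
    tab$p4 <- NULL
    tab$bogus <- 1
    f2 <- tempfile(fileext = ".tsv")
    write.table(tab, f2, sep = "\t", row.names = FALSE, quote = FALSE)
    expect_error(readAdvisorSet(f2, sp), "missing: p4.*unexpected: bogus")
    # out-of-bounds row
    tab2 <- read.delim(f, check.names = FALSE)
    tab2$p1[2] <- 99
    f3 <- tempfile(fileext = ".tsv")
    write.table(tab2, f3, sep = "\t", row.names = FALSE, quote = FALSE)
    expect_error(readAdvisorSet(f3, sp), "row 2.*p1")
    # duplicate rows
    tab3 <- read.delim(f, check.names = FALSE)
    tab3[2, ] <- tab3[1, ]
    f4 <- tempfile(fileext = ".tsv")
    write.table(tab3, f4, sep = "\t", row.names = FALSE, quote = FALSE)
    expect_error(readAdvisorSet(f4, sp), "duplicate")
    # default in row 1 is recognized
    set2 <- advisorSet(c(list(defaultVector(sp)),
                         advisorVectors(set)[1:2]), includesDefault = TRUE)
    f5 <- tempfile(fileext = ".tsv")
    writeAdvisorSet(set2, f5, sp)
    expect_true(includesDefault(readAdvisorSet(f5, sp)))
})

test_that("parameter-space YAML round-trips and shipped spaces load", {
    sp <- makeSpace()
    f <- tempfile(fileext = ".yaml")
    writeParameterSpace(sp, f)
    back <- readParameterSpace(f)
    expect_identical(names(back), names(sp))
    expect_identical(TranscriptAdvisor:::vectorKey(defaultVector(back)),
                     TranscriptAdvisor:::vectorKey(defaultVector(sp)))
    scallop <- readParameterSpace(system.file("extdata",
        "scallop_parameters.yaml", package = "TranscriptAdvisor"))
    expect_equal(length(scallop), 18L)
    expect_length(validateVector(scallop, defaultVector(scallop)), 0L)
    stringtie <- readParameterSpace(system.file("extdata",
        "stringtie_parameters.yaml", package = "TranscriptAdvisor"))
    expect_equal(length(stringtie), 9L)
    expect_length(validateVector(stringtie, defaultVector(stringtie)), 0L)
})

test_that("flag rendering is injective and respects boolean styles", {
    sp <- makeSpace()
    set <- randomAdvisorSet(sp, 12, seed = 9)
    rendered <- vapply(advisorVectors(set), function(v)
        paste(renderArgs(sp, v), collapse = " "), character(1))
    expect_equal(anyDuplicated(rendered), 0L)
    v <- parameterVector(list(p1 = 1L, p2 = 2L, p3 = 0.5, p4 = TRUE))
    expect_true("true" %in% renderArgs(sp, v, booleanStyle = "value"))
    pres <- renderArgs(sp, v, booleanStyle = "presence")
    expect_true("--p4" %in% pres && !"true" %in% pres)
    vF <- parameterVector(list(p1 = 1L, p2 = 2L, p3 = 0.5, p4 = FALSE))
    expect_false("--p4" %in% renderArgs(sp, vF, booleanStyle = "presence"))
    expect_error(renderArgs(sp, parameterVector(list(p1 = 99L))), "invalid")
})

test_that("advise is an argmax with position-based tie-breaking", {
    l <- makeLandscape(seed = 21, sampleShift = TRUE)
    sp <- l@space
    ad <- mockAssemblerAdapter(l)
    s <- writeSampleToken(5)
    # singleton set: that vector is chosen regardless of score
    single <- advisorSet(list(randomAdvisorSet(sp, 1, seed = 1)@vectors[[1]]))
    res1 <- advise(s, single, ad, l@reference)
    expect_equal(res1@chosenIndex, 1L)
    # default first: never worse than the default assembly
    set <- advisorSet(c(list(defaultVector(sp)),
                        advisorVectors(randomAdvisorSet(sp, 4, seed = 2))),
                      includesDefault = TRUE)
    res <- advise(s, set, ad, l@reference)
    expect_equal(chosenAuc(res), max(perVectorAuc(res)))
    expect_gte(chosenAuc(res), perVectorAuc(res)[1])
    # re-scoring the winning assembly reproduces chosenAuc
    expect_equal(assemblyAUC(readGtf(assemblyPath(res)), l@reference),
                 chosenAuc(res))
    # monotone under set growth
    small <- advisorSet(advisorVectors(set)[1:2], includesDefault = TRUE)
    expect_lte(chosenAuc(advise(s, small, ad, l@reference)),
               chosenAuc(res) + 1e-9)
    # permutation invariance when scores are distinct
    auc <- perVectorAuc(res)
    if (!anyDuplicated(auc)) {
        perm <- rev(seq_along(auc))
        resP <- advise(s, advisorSet(advisorVectors(set)[perm]),
                       ad, l@reference)
        expect_identical(TranscriptAdvisor:::vectorKey(chosenVector(resP)),
                         TranscriptAdvisor:::vectorKey(chosenVector(res)))
    }
})

test_that("failed assembler invocations are excluded with a warning", {
    sp <- parameterSpace(parameterDef("k", "integer", 5L, 0L, 10L, 1L))
    failing <- scallopAdapter(sp, executable = "definitely-not-a-binary")
    s <- tempfile(); writeLines("x", s)
    set <- advisorSet(list(defaultVector(sp)))
    ref <- generateReference(nGenes = 5, seed = 1)
    expect_error(suppressWarnings(advise(s, set, failing, ref)),
                 "all assembler invocations failed")
})
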