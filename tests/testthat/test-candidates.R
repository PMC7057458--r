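test_that("VCF ingestion converts coordinates, filters types and falls back to SVLEN", {
    vcf <- writeTestVcf(c(
        "11\t1001\tinv1\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=3000",
        "11\t5001\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=6000",
        "11\t7001\tinv2\tN\t<INV>\t.\tPASS\tSVTYPE=INV;SVLEN=1500",
        "11\t9001\tinv3\tN\t<INV>\t.\tPASS\tSVTYPE=INV"))
    expect_warning(calls <- readCallerCalls(vcf, "delly"), "skipped")
    expect_equal(length(calls), 2L)               # DEL and END-less dropped
    expect_equal(BiocGenerics::start(calls), c(1001L, 7001L))
    expect_equal(BiocGenerics::end(calls), c(3000L, 8501L))
    expect_equal(unlist(calls$sources), c("delly", "delly"))
})

test_that("BED ingestion converts 0-based half-open intervals", {
    bed <- tempfile(fileext = ".bed")
    writeLines("11\t1000\t3000", bed)
    calls <- readCallerCalls(bed, "pindel")
    expect_equal(BiocGenerics::start(calls), 1001L)
    expect_equal(BiocGenerics::end(calls), 3000L)
    expect_equal(BiocGenerics::width(calls), 2000L)
})

test_that("merging collapses near-duplicates and is idempotent", {
    a <- grFixture("11", 1001L, 3000L)
    a$sources <- IRanges::CharacterList("delly")
    a$ids <- IRanges::CharacterList("d1")
    b <- grFixture("11", 1006L, 3005L)        # within eps = 10 at both ends
    b$sources <- IRanges::CharacterList("lumpy")
    b$ids <- IRanges::CharacterList("l1")
    c_ <- grFixture("11", 1051L, 3050L)       # 50 bp off: kept separate
    c_$sources <- IRanges::CharacterList("pindel")
    c_$ids <- IRanges::CharacterList("p1")
    merged <- mergeCandidates(c(a, b, c_), eps = 10L)
    expect_equal(length(merged), 2L)
    # first-seen breakpoints kept, sources unioned
    expect_equal(BiocGenerics::start(merged)[1], 1001L)
    expect_equal(sort(unlist(merged$sources[1])), c("delly", "lumpy"))
    # idempotent
    again <- mergeCandidates(merged, eps = 10L)
    expect_equal(BiocGenerics::start(again), BiocGenerics::start(merged))
    expect_equal(as.list(again$sources), as.list(merged$sources))
    # eps = 0 collapses exact duplicates only
    expect_equal(length(mergeCandidates(c(a, b, c_), eps = 0L)), 3L)
    expect_equal(length(mergeCandidates(c(a, a), eps = 0L)), 1L)
    # single-caller input: identity up to sorting
    solo <- mergeCandidates(c_, eps = 10L)
    expect_equal(BiocGenerics::start(solo), 1051L)
    # never grows
    expect_lte(length(merged), 3L)
})

test_that("the length filter keeps candidates at least one mean ISPE long", {
    st <- statsFixture(mean = 400)
    calls <- grFixture("11", c(1001L, 5001L, 9001L),
                       c(1399L, 5400L, 10000L))   # widths 399, 400, 1000
    kept <- filterByLength(calls, st)
    expect_equal(BiocGenerics::width(kept), c(400L, 1000L))
    expect_equal(length(filterByLength(calls[0], st)), 0L)
    # brute-force count over a random fixture
    set.seed(3)
    st2 <- statsFixture(mean = 350)
    w <- sample(200:800, 50, replace = TRUE)
    gr <- grFixture("11", seq(1L, by = 2000L, length.out = 50),
                    seq(1L, by = 2000L, length.out = 50) + w - 1L)
    expect_equal(length(filterByLength(gr, st2)), sum(w >= 350))
})

test_that("inversion calls round-trip through the VCF writer", {
    calls <- grFixture("11", c(1001L, 7001L), c(3000L, 9000L))
    calls$sources <- IRanges::CharacterList(list("delly",
                                                 c("delly", "lumpy")))
    path <- tempfile(fileext = ".vcf")
    writeCallsVcf(calls, path)
    back <- readCallerCalls(path, "self")
    expect_equal(BiocGenerics::start(back), BiocGenerics::start(calls))
    expect_equal(BiocGenerics::end(back), BiocGenerics::end(calls))
    # empty call set: valid header-only file
    writeCallsVcf(calls[0], path)
    empty <- readCallerCalls(path, "self")
    expect_equal(length(empty), 0L)
})

test_that("pseudo-caller candidates jitter the truth and include decoys", {
    sim <- smallSim()
    cand <- pseudoCallerCalls(sim$truth, maxJitter = 100L, seed = 8L)
    nInv <- length(sim$truth@inversions)
    expect_equal(length(cand),
                 nInv + length(sim$truth@wildTypeWindows))
    d <- abs(BiocGenerics::start(cand)[seq_len(nInv)] -
             BiocGenerics::start(sim$truth@inversions))
    expect_true(all(d <= 100L))
    noDecoy <- pseudoCallerCalls(sim$truth, includeDecoys = FALSE,
                                 seed = 8L)
    expect_equal(length(noDecoy), nInv)
})
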