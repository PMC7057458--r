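test_that("padded windows enlarge regions by the mean ISPE and clamp at the origin", {
    st <- statsFixture(mean = 400)
    w <- paddedWindow(grFixture("11", 1001L, 3000L), st)
    expect_equal(BiocGenerics::start(w), 601L)
    expect_equal(BiocGenerics::end(w), 3400L)
    # clamp at the first base
    w2 <- paddedWindow(grFixture("11", 101L, 500L), st)
    expect_equal(BiocGenerics::start(w2), 1L)
    expect_equal(BiocGenerics::end(w2), 900L)
    # length identity away from the boundary
    r <- grFixture("11", 5001L, 6234L)
    expect_equal(BiocGenerics::width(paddedWindow(r, st)),
                 BiocGenerics::width(r) + 2L * 400L)
})

test_that("an empty window yields the all-zero feature vector", {
    aset <- fixtureSet(mkRec("far", pos = 100000L, mpos = 100330L,
                             tlen = 400L))
    st <- statsFixture()
    f <- extractFeatures(aset, grFixture("11", 1001L, 3000L), st)
    expect_equal(unname(f), rep(0, 15))
})

test_that("hand-built fixture counts match exact enumeration", {
    # pair A: both mates on the forward strand, TLEN in the normal range
    # read B: 30S40M with an unmapped mate, MAPQ 30
    # read C: unpaired, unique, error-free, MAPQ 60
    aset <- fixtureSet(
        mkRec("A", pos = 1000L, mpos = 1330L, tlen = 400L,
              mateReverse = FALSE),
        mkRec("A", pos = 1330L, first = FALSE, reverse = FALSE,
              mateReverse = FALSE, mpos = 1000L, tlen = -400L),
        mkRec("B", pos = 1100L, cigar = "30S40M", mapq = 30L,
              mateUnmapped = TRUE, mpos = 1100L, nm = 1L),
        mkRec("C", pos = 1200L, paired = FALSE, mateReverse = FALSE))
    st <- statsFixture()
    f <- extractFeatures(aset, grFixture("11", 1001L, 2000L), st,
                         featureConfig(minClip = 5L))
    expect_equal(unname(f[c("f13", "f14", "f15")]), c(0, 1, 1))
    expect_equal(unname(f["f3"]), 1)          # one-end-unmapped
    expect_equal(unname(f["f4"]), 1)          # clipped (30 >= minClip)
    expect_equal(unname(f["f9"]), 60 + 60 + 30 + 60)
    expect_equal(unname(f[c("f10", "f11", "f12")]), c(0, 1, 3))
    expect_equal(unname(f[c("f5", "f6")]), c(3, 1))
    expect_equal(unname(f[c("f1", "f2")]), c(4, 0))
    # the both-forward pair is orientation-discordant, not ISPE-concordant
    expect_equal(unname(f[c("f7", "f8")]), c(0, 1))
    # a larger minClip drops the clipped-read count
    f2 <- extractFeatures(aset, grFixture("11", 1001L, 2000L), st,
                          featureConfig(minClip = 31L))
    expect_equal(unname(f2["f4"]), 0)
})

test_that("partition identities and permutation invariance hold on simulated windows", {
    sim <- smallSim()
    st <- estimateLibraryStats(sim$alignments)
    tw <- buildTrainingWindows(sim$truth, st)
    regions <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(tw),
        IRanges::IRanges(tw$regionStart, tw$regionEnd))
    fs <- extractFeatureMatrix(sim$alignments, regions,
                               label = tw$label, stats = st)
    X <- featureMatrix(fs)
    expect_true(all(X[, "f15"] == X[, "f13"] + X[, "f14"]))
    # every scored read is exactly one of unique/multiple and lands in
    # exactly one MAPQ bin
    expect_true(all(X[, "f10"] + X[, "f11"] + X[, "f12"] ==
                    X[, "f1"] + X[, "f2"]))
    # NM present on all simulated mapped reads
    expect_true(all(X[, "f5"] + X[, "f6"] == X[, "f1"] + X[, "f2"]))
    # pairs counted once never exceed the per-read totals
    expect_true(all(X[, "f7"] + X[, "f8"] <= X[, "f1"] + X[, "f2"]))
    expect_true(all(X >= 0))

    # permutation invariance of the record stream
    rec <- alignmentRecords(sim$alignments)
    set.seed(7)
    shuf <- alignmentSet(rec[sample.int(nrow(rec)), ],
                         sim$alignments@seqlengths)
    f1 <- extractFeatures(sim$alignments, regions[1], st)
    f2 <- extractFeatures(shuf, regions[1], st)
    expect_identical(f1, f2)
})

test_that("adding a record to the window never decreases any count", {
    st <- statsFixture()
    base <- fixtureSet(
        mkRec("A", pos = 1000L, mpos = 1330L, tlen = 400L))
    extra <- rbind(alignmentRecords(base),
                   mkRec("D", pos = 1500L, cigar = "20S50M", mapq = 10L,
                         mpos = 1100L, tlen = -450L, nm = 3L,
                         reverse = TRUE, mateReverse = TRUE))
    grown <- alignmentSet(extra, base@seqlengths)
    r <- grFixture("11", 1001L, 2000L)
    f0 <- extractFeatures(base, r, st)
    f1 <- extractFeatures(grown, r, st)
    expect_true(all(f1 >= f0))
})

test_that("inversion windows dominate wild-type windows in same-strand and discordant pairs", {
    sim <- smallSim()
    st <- estimateLibraryStats(sim$alignments)
    tw <- buildTrainingWindows(sim$truth, st)
    regions <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(tw),
        IRanges::IRanges(tw$regionStart, tw$regionEnd))
    fs <- extractFeatureMatrix(sim$alignments, regions,
                               label = tw$label, stats = st)
    X <- featureMatrix(fs)
    lab <- featureLabels(fs)
    expect_gt(min(X[lab == 1L, "f15"]), max(X[lab == 0L, "f15"]))
    expect_gt(min(X[lab == 1L, "f8"]), max(X[lab == 0L, "f8"]))
})

test_that("feature TSV persists regions, labels and counts losslessly", {
    sim <- smallSim()
    st <- estimateLibraryStats(sim$alignments)
    fs <- extractFeatureMatrix(
        sim$alignments, GenomicRanges::granges(sim$truth@inversions),
        label = 1L, stats = st)
    path <- tempfile(fileext = ".tsv")
    writeFeatureTsv(fs, path)
    back <- readFeatureTsv(path, st)
    expect_equal(featureMatrix(back), featureMatrix(fs))
    expect_equal(featureLabels(back), featureLabels(fs))
    expect_equal(BiocGenerics::start(featureRegions(back)),
                 BiocGenerics::start(featureRegions(fs)))
    expect_equal(BiocGenerics::end(featureRegions(back)),
                 BiocGenerics::end(featureRegions(fs)))
})
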