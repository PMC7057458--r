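test_that("configuration invariants are enforced before any simulation", {
    inv <- grFixture("sim", 5001L, 5400L, zygosity = "hom")
    # shorter than the mean ISPE
    expect_error(simulationConfig(20000L, inv, ispeMean = 450),
                 "ispeMean")
    # extending past the reference
    inv2 <- grFixture("sim", 19000L, 21000L, zygosity = "hom")
    expect_error(simulationConfig(20000L, inv2), "past refLength")
    # overlapping inversions
    inv3 <- grFixture("sim", c(5001L, 5500L), c(8000L, 9000L),
                      zygosity = c("hom", "hom"))
    expect_error(simulationConfig(20000L, inv3), "non-overlapping")
})

test_that("a wild-type sample contains only opposite-strand pairs within the insert-size support", {
    cfg <- simulationConfig(25000L, inversions = NULL, errorRate = 0,
                            ispeMean = 400, ispeSd = 30, depth = 8,
                            seed = 31L)
    sim <- simulateSample(cfg)
    rec <- alignmentRecords(sim$alignments)
    expect_true(all(bitwAnd(rec$flag, 4L) == 0L))        # all mapped
    rev <- InversionMiner:::.flagReverse(rec$flag)
    mrev <- InversionMiner:::.flagMateReverse(rec$flag)
    expect_equal(sum(rev == mrev), 0L)                   # no same-strand
    tl <- abs(rec$tlen)
    expect_true(all(tl >= 2L * cfg@readLength))          # truncation
    expect_true(all(tl <= 400 + 6 * 30))                 # Normal support
    expect_true(all(rec$nm == 0L))                       # error-free
})

test_that("a homozygous inversion yields breakpoint signatures at the expected depth", {
    inv <- grFixture("sim", 10001L, 12000L, zygosity = "hom")
    cfg <- simulationConfig(30000L, inv, ispeMean = 400, depth = 20,
                            seed = 41L)
    sim <- simulateSample(cfg)
    rec <- alignmentRecords(sim$alignments)
    rev <- InversionMiner:::.flagReverse(rec$flag)
    mrev <- InversionMiner:::.flagMateReverse(rec$flag)
    mapped <- bitwAnd(rec$flag, 4L) == 0L
    ends <- InversionMiner:::.recordEnd(rec)
    # same-strand pairs overlap both breakpoints
    for (bp in c(10001L, 12000L)) {
        near <- mapped & rec$pos <= bp + 400L & ends >= bp - 400L
        expect_gte(sum(near & rev == mrev &
                       !InversionMiner:::.flagMateUnmapped(rec$flag)), 1L)
    }
    # emitted bases conserve depth: expected 2 * depth/ (2rl) * L reads;
    # Poisson bound on the fragment count, 5 standard deviations
    lambda <- cfg@depth * cfg@refLength / (2 * cfg@readLength)
    nFrag <- length(unique(rec$qname))
    expect_lt(abs(nFrag - lambda), 5 * sqrt(lambda))
    # no pair has both mates unmapped
    unm <- tapply(bitwAnd(rec$flag, 4L) != 0L, rec$qname, sum)
    expect_true(all(unm <= 1L))
})

test_that("the same-strand fraction at an inversion exceeds every wild-type window", {
    sim <- smallSim()
    rec <- alignmentRecords(sim$alignments)
    mapped <- bitwAnd(rec$flag, 4L) == 0L &
        !InversionMiner:::.flagMateUnmapped(rec$flag)
    rev <- InversionMiner:::.flagReverse(rec$flag)
    mrev <- InversionMiner:::.flagMateReverse(rec$flag)
    ends <- InversionMiner:::.recordEnd(rec)
    ssFrac <- function(gr) {
        w <- mapped & rec$chrom ==
            as.character(GenomicRanges::seqnames(gr)) &
            rec$pos <= BiocGenerics::end(gr) &
            ends >= BiocGenerics::start(gr)
        sum(w & rev == mrev) / max(sum(w), 1L)
    }
    invFrac <- vapply(seq_along(sim$truth@inversions), function(i)
        ssFrac(sim$truth@inversions[i]), numeric(1))
    wtFrac <- vapply(seq_along(sim$truth@wildTypeWindows), function(i)
        ssFrac(sim$truth@wildTypeWindows[i]), numeric(1))
    expect_true(all(outer(invFrac, wtFrac, ">")))
})

test_that("identical configuration and seed give a byte-identical record stream", {
    inv <- grFixture("sim", 5001L, 8000L, zygosity = "het")
    mk <- function() {
        sim <- simulateSample(simulationConfig(20000L, inv, depth = 6,
                                               seed = 9L))
        f <- tempfile(fileext = ".sam")
        writeSam(sim$alignments, f)
        f
    }
    expect_equal(unname(tools::md5sum(mk())), unname(tools::md5sum(mk())))
})

test_that("training windows are labeled, padded and never overlap across labels", {
    st <- statsFixture()
    sim <- smallSim()
    tw <- buildTrainingWindows(sim$truth, st)
    expect_equal(sum(tw$label == 1L), length(sim$truth@inversions))
    expect_equal(sum(tw$label == 0L), length(sim$truth@wildTypeWindows))
    # padding arithmetic: window = region +/- round(ispeMean)
    expect_equal(BiocGenerics::start(tw),
                 pmax(1L, tw$regionStart - 400L))
    expect_equal(BiocGenerics::end(tw), tw$regionEnd + 400L)
    # label-1 and label-0 windows are disjoint (interval sweep)
    ov <- GenomicRanges::findOverlaps(tw[tw$label == 1L],
                                      tw[tw$label == 0L])
    expect_equal(length(ov), 0L)

    # N_s samples x M_s1 inversions give N_s * M_s1 label-1 windows
    ts <- trainingDraw()
    expect_equal(sum(featureLabels(ts$features) == 1L), 13L * 5L)
})

test_that("truth BED and config sidecar are written deterministically", {
    inv <- grFixture("sim", 5001L, 8000L, zygosity = "hom")
    cfg <- simulationConfig(20000L, inv, depth = 5, seed = 3L)
    d1 <- tempfile(); d2 <- tempfile()
    p1 <- runSimulate(cfg, d1)
    p2 <- runSimulate(cfg, d2)
    for (k in names(p1))
        expect_equal(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])))
    bed <- read.table(p1[["truth"]], sep = "\t")
    expect_equal(nrow(bed), 2L)          # inversion + wild-type window
    expect_true(all(bed$V3 > bed$V2))
})
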