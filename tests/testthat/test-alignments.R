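test_that("SAM writing and reading round-trips records field for field", {
    # empty file with a valid header
    empty <- alignmentSet(
        data.frame(qname = character(0), flag = integer(0),
                   chrom = character(0), pos = integer(0),
                   mapq = integer(0), cigar = character(0),
                   mchrom = character(0), mpos = integer(0),
                   tlen = integer(0), readLength = integer(0),
                   xt = character(0), nm = integer(0),
                   xa = character(0)),
        seqlengths = c("11" = 200000L))
    sam <- tempfile(fileext = ".sam")
    writeSam(empty, sam)
    expect_equal(length(readAlignments(sam)), 0L)

    # three records, written then read back
    aset <- fixtureSet(
        mkRec("a", pos = 1000L, mpos = 1330L, tlen = 400L,
              mateReverse = TRUE),
        mkRec("a", pos = 1330L, first = FALSE, reverse = TRUE,
              mateReverse = FALSE, mpos = 1000L, tlen = -400L, nm = 2L),
        mkRec("b", pos = 2000L, cigar = "30S40M", mapq = 30L,
              mateUnmapped = TRUE, mpos = 2000L, xt = NA_character_,
              xa = "11,+5000,70M,2;"))
    writeSam(aset, sam)
    back <- readAlignments(sam)
    a <- alignmentRecords(aset)
    b <- alignmentRecords(back)
    b <- b[order(match(paste(b$qname, b$flag), paste(a$qname, a$flag))), ]
    rownames(b) <- NULL
    expect_equal(b, a)
})

test_that("read length equals the CIGAR query width", {
    rec <- mkRec("c", cigar = "50M20S")
    expect_equal(rec$readLength, 70L)
    # inconsistent readLength is rejected by the container
    bad <- mkRec("c", cigar = "50M20S", readLength = 69L)
    expect_error(fixtureSet(bad), "query width")
})

test_that("regional queries return exactly the overlapping records", {
    sim <- smallSim()
    sam <- tempfile(fileext = ".sam")
    writeSam(sim$alignments, sam)
    reg <- grFixture("sim", 5001L, 6000L)
    sub <- readAlignments(sam, region = reg)
    rec <- alignmentRecords(sub)
    ends <- InversionMiner:::.recordEnd(rec)
    expect_true(all(rec$pos <= 6000L & ends >= 5001L))
    # consistency with an in-memory overlap scan of the full file
    full <- alignmentRecords(readAlignments(sam))
    fends <- InversionMiner:::.recordEnd(full)
    mapped <- bitwAnd(full$flag, 4L) == 0L
    expected <- sum(mapped & full$pos <= 6000L & fends >= 5001L)
    expect_equal(sum(bitwAnd(rec$flag, 4L) == 0L), expected)
})

test_that("library ISPE statistics match direct formulas and are permutation-invariant", {
    pair <- function(qn, tlen, pos = 1000L)
        rbind(mkRec(qn, pos = pos, mpos = pos + tlen - 70L, tlen = tlen),
              mkRec(qn, pos = pos + tlen - 70L, first = FALSE,
                    reverse = TRUE, mateReverse = FALSE, mpos = pos,
                    tlen = -tlen))
    # constant insert size
    rows <- do.call(rbind, lapply(1:60, function(i)
        pair(paste0("p", i), 400L)))
    aset <- alignmentSet(rows, c("11" = 200000L))
    st <- estimateLibraryStats(aset)
    expect_equal(ispeMean(st), 400)
    expect_equal(ispeSd(st), 0)

    # {300, 400, 500} multiset: mean/sd from the direct formula
    tlens <- rep(c(300L, 400L, 500L), each = 20L)
    rows <- do.call(rbind, Map(function(i, t) pair(paste0("q", i), t),
                               seq_along(tlens), tlens))
    aset <- alignmentSet(rows, c("11" = 200000L))
    st <- estimateLibraryStats(aset)
    expect_equal(ispeMean(st), mean(tlens))
    expect_equal(ispeSd(st), sd(tlens))
    # permutation invariance over the sampled set
    shuf <- alignmentSet(rows[sample.int(nrow(rows)), ],
                         c("11" = 200000L))
    st2 <- estimateLibraryStats(shuf)
    expect_equal(ispeMean(st2), ispeMean(st))
    expect_equal(ispeSd(st2), ispeSd(st))

    # too few usable pairs
    few <- alignmentSet(do.call(rbind, lapply(1:10, function(i)
        pair(paste0("f", i), 400L))), c("11" = 200000L))
    expect_error(estimateLibraryStats(few), "insufficient")
})

test_that("simulated libraries recover the configured ISPE within sampling error", {
    cfg <- simulationConfig(30000L, ispeMean = 400, ispeSd = 30,
                            depth = 10, seed = 21L)
    sim <- simulateSample(cfg)
    st <- estimateLibraryStats(sim$alignments)
    rec <- alignmentRecords(sim$alignments)
    n <- sum(rec$tlen > 0L)
    expect_lt(abs(ispeMean(st) - 400), 3 * 30 / sqrt(n) + 1)
})
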