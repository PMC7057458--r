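# Fixtures are built in code: hand-assembled alignment records for exact
# counting oracles, plus memoized simulator outputs shared across files.

statsFixture <- function(mean = 400, sd = 30, rl = 100L)
    LibraryStats(ispeMean = mean, ispeSd = sd, readLengthMode = rl)

# One SAM record with sensible defaults; readLength derived from the CIGAR.
mkRec <- function(qname = "r1", chrom = "11", pos = 1000L, mapq = 60L,
                  cigar = "70M", paired = TRUE, unmapped = FALSE,
                  mateUnmapped = FALSE, reverse = FALSE,
                  mateReverse = TRUE, first = TRUE, mpos = NA_integer_,
                  tlen = 0L, xt = "U", nm = 0L, xa = NA_character_,
                  readLength = NULL) {
    if (is.null(readLength))
        readLength <- if (cigar == "*") 70L else
            GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
    data.frame(
        qname = qname,
        flag = InversionMiner:::samFlag(paired = paired,
                                        unmapped = unmapped,
                                        mateUnmapped = mateUnmapped,
                                        reverse = reverse,
                                        mateReverse = mateReverse,
                                        first = first, second = !first),
        chrom = chrom, pos = as.integer(pos), mapq = as.integer(mapq),
        cigar = cigar,
        mchrom = if (is.na(mpos)) NA_character_ else chrom,
        mpos = as.integer(mpos), tlen = as.integer(tlen),
        readLength = as.integer(readLength), xt = xt,
        nm = as.integer(nm), xa = xa, stringsAsFactors = FALSE)
}

fixtureSet <- function(..., seqlengths = c("11" = 200000L)) {
    alignmentSet(do.call(rbind, list(...)), seqlengths = seqlengths)
}

grFixture <- function(chrom, start, end, ...)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)

# Memoized expensive objects (built once per test run)
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (is.null(.cache[[key]]))
        .cache[[key]] <- force(expr)
    .cache[[key]]
}

# A small two-inversion sample reused by feature/simulator tests
smallSim <- function() memo("smallSim", {
    inv <- grFixture("sim", c(5001L, 15001L), c(8000L, 18000L),
                     zygosity = c("hom", "het"))
    simulateSample(simulationConfig(40000L, inversions = inv, depth = 12,
                                    seed = 5L))
})

# The full training draw under the standard parameter ranges (13 samples)
trainingDraw <- function() memo("trainingDraw", {
    cfgs <- drawSimulationConfigs(n = 13L, nInversions = 5L, seed = 11L)
    simulateTrainingSet(cfgs)
})

writeTestVcf <- function(lines, path = tempfile(fileext = ".vcf")) {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"type\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"end\">",
             "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"len\">",
             "##contig=<ID=11,length=135006516>",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    writeLines(c(hdr, lines), path)
    path
}

# Independent brute-force oracle for the chi-square feature score:
# per-class observed sums vs expected sums under the class priors,
# looped explicitly (kept separate from the implementation).
bruteChi2 <- function(X, y) {
    vapply(seq_len(ncol(X)), function(j) {
        tot <- sum(X[, j])
        if (tot == 0) return(0)
        x2 <- 0
        for (cl in c(0L, 1L)) {
            O <- sum(X[y == cl, j])
            E <- mean(y == cl) * tot
            x2 <- x2 + (O - E)^2 / E
        }
        x2
    }, numeric(1))
}
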