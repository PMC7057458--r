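#' @include AllClasses.R alignments.R
#' @importFrom stats rnorm rpois rbinom runif
NULL

#' Create a simulator configuration
#'
#' Convenience constructor for [SimulationConfig-class]. Defaults sit in
#' the middle of typical short-read library ranges (ISPE 300-500 bp, read
#' length 70-150 bp, error rate 0.003-0.005, depth 4-25x).
#'
#' @param refLength reference length (bp).
#' @param inversions `GRanges` with a `zygosity` column ("het"/"hom"), or
#'   NULL for a wild-type-only sample.
#' @param ispeMean,ispeSd insert-size distribution (bp).
#' @param errorRate per-base substitution error probability.
#' @param readLength read length (bp).
#' @param depth expected per-base coverage.
#' @param minAnchor minimum mapped anchor (bp) for breakpoint-spanning
#'   reads.
#' @param breakpointJitter integer pair: range of absolute jitter applied
#'   to recorded truth breakpoints; `c(0L, 0L)` disables.
#' @param pUnmappedCross probability a breakpoint-crossing read is emitted
#'   as an unmapped mate instead of soft-clipped.
#' @param seqname reference sequence name.
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @examples
#' inv <- GenomicRanges::GRanges("sim", IRanges::IRanges(5001, 7000),
#'                               zygosity = "hom")
#' cfg <- simulationConfig(20000L, inversions = inv, depth = 15)
#' cfg
#' @export
simulationConfig <- function(refLength, inversions = NULL, ispeMean = 400,
                             ispeSd = 30, errorRate = 0.004,
                             readLength = 100L, depth = 10,
                             minAnchor = 20L,
                             breakpointJitter = c(20L, 30L),
                             pUnmappedCross = 0.35, seqname = "sim",
                             seed = 1L) {
    if (is.null(inversions))
        inversions <- GenomicRanges::GRanges(
            seqnames = character(0), ranges = IRanges::IRanges(),
            zygosity = character(0))
    new("SimulationConfig", refLength = as.integer(refLength),
        inversions = inversions, ispeMean = ispeMean, ispeSd = ispeSd,
        errorRate = errorRate, readLength = as.integer(readLength),
        depth = depth, minAnchor = as.integer(minAnchor),
        breakpointJitter = as.integer(breakpointJitter),
        pUnmappedCross = pUnmappedCross, seqname = seqname,
        seed = as.integer(seed))
}

# Map one haplotype read through at most one active inversion.
# a, b: 1-based closed donor interval; rev: donor strand; j: index of the
# active inversion overlapping the read (NA if none). Returns placement,
# CIGAR pieces and anchor bookkeeping for the crossing cases.
.mapThroughInversion <- function(a, b, rev, j, s, e) {
    n <- length(a)
    pos <- a
    outRev <- rev
    mlen <- b - a + 1L
    clip <- integer(n)
    clipLeft <- logical(n)
    crossing <- logical(n)
    hit <- !is.na(j)
    if (any(hit)) {
        js <- s[j[hit]]; je <- e[j[hit]]
        ah <- a[hit]; bh <- b[hit]
        inside <- ah >= js & bh <= je
        crossL <- ah < js & bh >= js
        crossR <- ah <= je & bh > je
        idx <- which(hit)
        # fully inside: mirrored placement on the opposite strand
        ii <- idx[inside]
        pos[ii] <- js[inside] + je[inside] - b[ii]
        outRev[ii] <- !rev[ii]
        # crossing a breakpoint: keep the larger piece as the mapped anchor
        o <- integer(sum(hit)); i <- integer(sum(hit))
        o[crossL] <- js[crossL] - ah[crossL]
        i[crossL] <- bh[crossL] - js[crossL] + 1L
        o[crossR] <- bh[crossR] - je[crossR]
        i[crossR] <- je[crossR] - ah[crossR] + 1L
        useIn <- i > o
        cl <- idx[crossL & !useIn]          # left bp, outside piece mapped
        pos[cl] <- a[cl]
        mlen[cl] <- o[crossL & !useIn]
        clip[cl] <- i[crossL & !useIn]
        clipLeft[cl] <- FALSE
        cl <- idx[crossL & useIn]           # left bp, inside piece mapped
        pos[cl] <- js[crossL & useIn] + je[crossL & useIn] - b[cl]
        outRev[cl] <- !rev[cl]
        mlen[cl] <- i[crossL & useIn]
        clip[cl] <- o[crossL & useIn]
        clipLeft[cl] <- FALSE
        cl <- idx[crossR & !useIn]          # right bp, outside piece mapped
        pos[cl] <- je[crossR & !useIn] + 1L
        mlen[cl] <- o[crossR & !useIn]
        clip[cl] <- i[crossR & !useIn]
        clipLeft[cl] <- TRUE
        cl <- idx[crossR & useIn]           # right bp, inside piece mapped
        pos[cl] <- js[crossR & useIn]
        outRev[cl] <- !rev[cl]
        mlen[cl] <- i[crossR & useIn]
        clip[cl] <- o[crossR & useIn]
        clipLeft[cl] <- TRUE
        crossing[idx] <- crossL | crossR
    }
    list(pos = pos, rev = outRev, mlen = mlen, clip = clip,
         clipLeft = clipLeft, crossing = crossing,
         anchor = ifelse(crossing, mlen, b - a + 1L))
}

.cigarFor <- function(mlen, clip, clipLeft) {
    ifelse(clip == 0L, paste0(mlen, "M"),
           ifelse(clipLeft, paste0(clip, "S", mlen, "M"),
                  paste0(mlen, "M", clip, "S")))
}

#' Simulate a paired-end sample with implanted inversions
#'
#' Samples fragments uniformly along a diploid genome (expected per-base
#' depth `depth`, fragment length Normal(ispeMean, ispeSd) truncated at
#' 2 x readLength), emits one forward and one reverse read per fragment,
#' and maps donor coordinates back through the implanted inversions the
#' way a mapper would see them:
#' \itemize{
#'   \item a read wholly inside an inverted segment is placed at the
#'     mirrored reference position on the opposite strand (producing
#'     same-strand pairs when exactly one mate is inside);
#'   \item a read crossing a breakpoint is soft-clipped at the breakpoint
#'     when its larger mapped anchor reaches `minAnchor`, and with
#'     probability `pUnmappedCross` is reported as an unmapped mate
#'     instead (never both mates of a pair);
#'   \item heterozygous inversions affect each fragment with probability
#'     1/2 (random haplotype assignment); homozygous ones affect all.
#' }
#' Substitution errors are injected at `errorRate` per aligned base and
#' recorded in the `NM` tag; MAPQ is 60 for placed reads and `XT:A:U` is
#' written; TLEN is recomputed from the final mapped positions. Records
#' are returned coordinate-sorted. Identical config and seed give an
#' identical record stream.
#'
#' Recorded truth breakpoints are jittered by a uniform offset in the
#' `breakpointJitter` range (emulating the imprecision of a truth call
#' set); the exact implanted coordinates stay available as metadata.
#' Wild-type windows (one per inversion, matched widths) are placed at
#' least 2 x ispeMean away from every inversion.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements `alignments` ([AlignmentSet-class]) and
#'   `truth` ([TruthSet-class]).
#' @examples
#' inv <- GenomicRanges::GRanges("sim", IRanges::IRanges(8001, 10000),
#'                               zygosity = "hom")
#' sim <- simulateSample(simulationConfig(30000L, inv, depth = 8, seed = 2L))
#' sim$alignments
#' sim$truth
#' @export
simulateSample <- function(config) {
    validObject(config)
    set.seed(config@seed)
    L <- config@refLength
    rl <- config@readLength
    inv <- config@inversions
    s <- BiocGenerics::start(inv)
    e <- BiocGenerics::end(inv)
    zyg <- if (length(inv)) inv$zygosity else character(0)
    nFrag <- rpois(1L, config@depth * L / (2 * rl))
    fragLen <- pmin(pmax(round(rnorm(nFrag, config@ispeMean,
                                     config@ispeSd)), 2L * rl), L)
    fragStart <- 1L + as.integer(floor(runif(nFrag) *
                                       (L - fragLen + 1)))
    hap <- sample(1:2, nFrag, replace = TRUE)
    u1 <- runif(nFrag)
    u2 <- runif(nFrag)

    a1 <- fragStart;               b1 <- fragStart + rl - 1L
    b2 <- fragStart + as.integer(fragLen) - 1L; a2 <- b2 - rl + 1L

    # which inversion (if any) is active for each read
    findInv <- function(a, b) {
        j <- rep(NA_integer_, length(a))
        if (length(inv) == 0L) return(j)
        hits <- GenomicRanges::findOverlaps(
            IRanges::IRanges(a, b), IRanges::IRanges(s, e))
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        active <- zyg[sh] == "hom" | hap[qh] == 1L
        j[qh[active]] <- sh[active]
        j
    }
    m1 <- .mapThroughInversion(a1, b1, rep(FALSE, nFrag), findInv(a1, b1),
                               s, e)
    m2 <- .mapThroughInversion(a2, b2, rep(TRUE, nFrag), findInv(a2, b2),
                               s, e)

    af1 <- m1$crossing & m1$anchor < config@minAnchor
    af2 <- m2$crossing & m2$anchor < config@minAnchor
    drop <- af1 & af2
    pf1 <- m1$crossing & !af1 & u1 < config@pUnmappedCross & !af2
    pf2 <- m2$crossing & !af2 & u2 < config@pUnmappedCross &
        !(af1 | pf1)
    unm1 <- af1 | pf1
    unm2 <- af2 | pf2

    keep <- !drop
    n <- sum(keep)
    if (n == 0L)
        stop("no fragments survived; increase depth or refLength")
    pick <- function(v) v[keep]
    m1 <- lapply(m1, pick); m2 <- lapply(m2, pick)
    unm1 <- unm1[keep]; unm2 <- unm2[keep]

    # unmapped reads are placed at their mate's coordinate
    pos1 <- ifelse(unm1, m2$pos, m1$pos)
    pos2 <- ifelse(unm2, m1$pos, m2$pos)
    end1 <- pos1 + ifelse(unm1, 0L, m1$mlen) - 1L
    end2 <- pos2 + ifelse(unm2, 0L, m2$mlen) - 1L
    bothMapped <- !unm1 & !unm2
    lo <- pmin(pos1, pos2)
    hi <- pmax(end1, end2)
    span <- hi - lo + 1L
    t1 <- ifelse(bothMapped, ifelse(pos1 <= pos2, span, -span), 0L)
    t2 <- ifelse(bothMapped, -t1, 0L)

    rev1 <- m1$rev & !unm1
    rev2 <- m2$rev & !unm2
    mlen1 <- ifelse(unm1, 0L, m1$mlen)
    mlen2 <- ifelse(unm2, 0L, m2$mlen)
    nm1 <- ifelse(unm1, NA_integer_, rbinom(n, mlen1, config@errorRate))
    nm2 <- ifelse(unm2, NA_integer_, rbinom(n, mlen2, config@errorRate))

    qname <- sprintf("frag%07d", seq_len(n))
    mk <- function(first, pos, unm, rev, mrev, munm, mpos, tlen, mlen,
                   clip, clipLeft, nm) {
        data.frame(
            qname = qname,
            flag = samFlag(paired = TRUE, unmapped = unm,
                           mateUnmapped = munm, reverse = rev,
                           mateReverse = mrev, first = first,
                           second = !first),
            chrom = config@seqname, pos = as.integer(pos),
            mapq = ifelse(unm, 0L, 60L),
            cigar = ifelse(unm, "*", .cigarFor(mlen, clip, clipLeft)),
            mchrom = config@seqname, mpos = as.integer(mpos),
            tlen = as.integer(tlen), readLength = rl,
            xt = ifelse(unm, NA_character_, "U"),
            nm = nm, xa = NA_character_, stringsAsFactors = FALSE)
    }
    r1 <- mk(TRUE, pos1, unm1, rev1, rev2, unm2, pos2, t1, m1$mlen,
             ifelse(unm1, 0L, rl - mlen1), m1$clipLeft, nm1)
    r2 <- mk(FALSE, pos2, unm2, rev2, rev1, unm1, pos1, t2, m2$mlen,
             ifelse(unm2, 0L, rl - mlen2), m2$clipLeft, nm2)
    # clipped length recomputation: for unmapped reads CIGAR is "*"
    rec <- rbind(r1, r2)
    rec <- rec[order(rec$pos, rec$qname, rec$flag), , drop = FALSE]
    sl <- structure(L, names = config@seqname)
    aln <- alignmentSet(rec, sl)

    truth <- .buildTruth(config)
    list(alignments = aln, truth = truth)
}

# Jitter recorded truth breakpoints and place wild-type windows.
# Called inside simulateSample after the read draws (fixed RNG order).
.buildTruth <- function(config) {
    inv <- config@inversions
    L <- config@refLength
    nInv <- length(inv)
    jit <- config@breakpointJitter
    s <- BiocGenerics::start(inv)
    e <- BiocGenerics::end(inv)
    if (nInv > 0L && jit[2L] > 0L) {
        mag <- matrix(sample(seq(jit[1L], jit[2L]), 2L * nInv,
                             replace = TRUE), ncol = 2L)
        sgn <- matrix(sample(c(-1L, 1L), 2L * nInv, replace = TRUE),
                      ncol = 2L)
        rs <- pmax(1L, pmin(L, s + mag[, 1L] * sgn[, 1L]))
        re <- pmax(1L, pmin(L, e + mag[, 2L] * sgn[, 2L]))
        bad <- rs >= re
        rs[bad] <- s[bad]; re[bad] <- e[bad]
    } else {
        rs <- s; re <- e
    }
    recorded <- GenomicRanges::GRanges(
        rep(config@seqname, nInv), IRanges::IRanges(rs, re),
        zygosity = if (nInv) inv$zygosity else character(0),
        actualStart = s, actualEnd = e)
    pad2 <- as.integer(round(2 * config@ispeMean))
    widths <- if (nInv) BiocGenerics::width(inv) else
        as.integer(round(3 * config@ispeMean))
    nWT <- max(nInv, 1L)
    forbidden <- IRanges::IRanges(pmax(1L, s - pad2),
                                  pmin(L, e + pad2))
    wt <- .placeWindows(L, forbidden, rep_len(widths, nWT), pad2,
                        minWidth = as.integer(round(config@ispeMean)))
    wtg <- GenomicRanges::GRanges(rep(config@seqname, length(wt)), wt)
    new("TruthSet", inversions = recorded, wildTypeWindows = wtg,
        refLength = L)
}

# Sample non-overlapping windows of the requested widths in the free space
# left by `forbidden`, keeping `pad` bp of clearance around each placement.
.placeWindows <- function(L, forbidden, widths, pad, minWidth) {
    free <- BiocGenerics::setdiff(IRanges::IRanges(1L, L), forbidden)
    out <- IRanges::IRanges()
    for (w in widths) {
        gw <- BiocGenerics::width(free)
        fit <- which(gw >= w)
        if (length(fit) == 0L) {
            w <- min(max(gw, 0L), w)
            if (w < minWidth)
                stop("refLength too small to place wild-type windows")
            fit <- which(gw >= w)
        }
        slots <- gw[fit] - w + 1L
        g <- fit[sample.int(length(fit), 1L, prob = slots)]
        off <- sample.int(BiocGenerics::width(free)[g] - w + 1L, 1L) - 1L
        st <- BiocGenerics::start(free)[g] + off
        win <- IRanges::IRanges(st, st + w - 1L)
        out <- c(out, win)
        blocked <- IRanges::IRanges(max(1L, st - pad),
                                    min(L, st + w - 1L + pad))
        free <- BiocGenerics::setdiff(free, blocked)
    }
    out
}

#' Labeled training windows from a truth set
#'
#' One labeled window per inversion (label 1) and per wild-type window
#' (label 0); each window is the truth interval padded by the mean ISPE on
#' both sides, the range in which breakpoint signatures concentrate. The
#' unpadded interval is carried in `regionStart`/`regionEnd` metadata
#' columns.
#'
#' @param truth a [TruthSet-class].
#' @param stats a [LibraryStats-class].
#' @return a `GRanges` of padded windows with metadata columns `label`,
#'   `regionStart`, `regionEnd`.
#' @export
buildTrainingWindows <- function(truth, stats) {
    regions <- c(GenomicRanges::granges(truth@inversions),
                 GenomicRanges::granges(truth@wildTypeWindows))
    if (length(regions) == 0L)
        stop("truth set is empty")
    label <- c(rep(1L, length(truth@inversions)),
               rep(0L, length(truth@wildTypeWindows)))
    win <- paddedWindow(regions, stats)
    win$label <- label
    win$regionStart <- BiocGenerics::start(regions)
    win$regionEnd <- BiocGenerics::end(regions)
    win
}

#' Write a truth set as a BED file
#'
#' Four columns: chrom, 0-based start, end, zygosity (wild-type windows
#' are written with name `WT`).
#'
#' @param truth a [TruthSet-class].
#' @param path output path.
#' @param includeWildType also write the wild-type windows (default TRUE).
#' @return `path`, invisibly.
#' @export
writeTruthBed <- function(truth, path, includeWildType = TRUE) {
    inv <- truth@inversions
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(inv)),
        start = BiocGenerics::start(inv) - 1L,
        end = BiocGenerics::end(inv),
        name = if (length(inv)) inv$zygosity else character(0))
    if (includeWildType && length(truth@wildTypeWindows)) {
        wt <- truth@wildTypeWindows
        df <- rbind(df, data.frame(
            chrom = as.character(GenomicRanges::seqnames(wt)),
            start = BiocGenerics::start(wt) - 1L,
            end = BiocGenerics::end(wt), name = "WT"))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
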