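#' @include AllClasses.R alignments.R utils.R
NULL

#' Construct a feature-counting configuration
#'
#' @param mqLowMax MAPQ strictly below this counts as low (default 20).
#' @param mqHighMin MAPQ at or above this counts as high (default 40).
#' @param concordantK half-width of the concordant insert-size band in
#'   standard deviations (default 3).
#' @param minClip minimum total soft-clipped bases for the clipped-read
#'   count (default 5).
#' @param countDuplicates count duplicate-flagged records (default FALSE).
#' @return a [FeatureConfig-class].
#' @export
featureConfig <- function(mqLowMax = 20L, mqHighMin = 40L, concordantK = 3,
                          minClip = 5L, countDuplicates = FALSE) {
    new("FeatureConfig", mqLowMax = as.integer(mqLowMax),
        mqHighMin = as.integer(mqHighMin), concordantK = concordantK,
        minClip = as.integer(minClip), countDuplicates = countDuplicates)
}

#' ISPE-padded breakpoint window
#'
#' Enlarges an interval by the mean ISPE on both sides (clamped at the
#' first base), the window from which breakpoint-signature features are
#' counted: read pairs informative about a breakpoint start up to one
#' insert size away from it.
#'
#' @param region a `GRanges`.
#' @param stats a [LibraryStats-class].
#' @return a `GRanges` of padded windows, parallel to `region`.
#' @examples
#' st <- LibraryStats(ispeMean = 400, ispeSd = 30, readLengthMode = 100L)
#' r <- GenomicRanges::GRanges("11", IRanges::IRanges(1001, 3000))
#' paddedWindow(r, st)  # 601-3400
#' @export
paddedWindow <- function(region, stats) {
    pad <- as.integer(round(ispeMean(stats)))
    GenomicRanges::GRanges(
        GenomicRanges::seqnames(region),
        IRanges::IRanges(pmax(1L, BiocGenerics::start(region) - pad),
                         BiocGenerics::end(region) + pad),
        strand = GenomicRanges::strand(region))
}

# Count the fifteen features over the mapped primary records of `rec`
# that overlap [wstart, wend] on `chrom`. `recEnd` is the precomputed
# reference end of each record.
.countFeatures <- function(rec, recEnd, chrom, wstart, wend, stats, fcfg) {
    f <- stats::setNames(numeric(15L), paste0("f", 1:15))
    if (nrow(rec) == 0L)
        return(f)
    keep <- rec$chrom == chrom & !.flagUnmapped(rec$flag) &
        !.flagSecondary(rec$flag) & !.flagSupplementary(rec$flag) &
        rec$pos <= wend & recEnd >= wstart
    if (!fcfg@countDuplicates)
        keep <- keep & !.flagDuplicate(rec$flag)
    r <- rec[keep, , drop = FALSE]
    if (nrow(r) == 0L)
        return(f)
    # per-read features -------------------------------------------------
    hasXT <- !is.na(r$xt)
    multiple <- (hasXT & r$xt == "R") |
        (!hasXT & (!is.na(r$xa) | r$mapq == 0L))
    unique_ <- (hasXT & r$xt == "U") |
        (!hasXT & is.na(r$xa) & r$mapq > 0L)
    f["f1"] <- sum(unique_)
    f["f2"] <- sum(multiple)
    f["f3"] <- sum(.flagMateUnmapped(r$flag))
    clipped <- GenomicAlignments::cigarOpTable(r$cigar)[, "S"]
    f["f4"] <- sum(clipped >= fcfg@minClip)
    hasNM <- !is.na(r$nm)
    f["f5"] <- sum(hasNM & r$nm == 0L)
    f["f6"] <- sum(hasNM & r$nm > 0L)
    f["f9"] <- sum(r$mapq)
    f["f10"] <- sum(r$mapq < fcfg@mqLowMax)
    f["f12"] <- sum(r$mapq >= fcfg@mqHighMin)
    f["f11"] <- nrow(r) - f["f10"] - f["f12"]
    # per-pair features, counted once at the leftmost mate in the window --
    paired <- .flagPaired(r$flag) & !.flagMateUnmapped(r$flag) &
        !is.na(r$mpos) & (is.na(r$mchrom) | r$mchrom == r$chrom)
    mateEnd <- r$mpos + ifelse(is.na(r$readLength), 1L, r$readLength) - 1L
    mateOutside <- mateEnd < wstart | r$mpos > wend
    rep_ <- paired & ((r$pos < r$mpos) |
                      (r$pos == r$mpos & .flagFirstInPair(r$flag)) |
                      (r$pos > r$mpos & mateOutside))
    p <- r[rep_, , drop = FALSE]
    if (nrow(p)) {
        opp <- .flagReverse(p$flag) != .flagMateReverse(p$flag)
        band <- fcfg@concordantK * ispeSd(stats)
        normal <- abs(p$tlen) >= ispeMean(stats) - band &
            abs(p$tlen) <= ispeMean(stats) + band
        f["f7"] <- sum(opp & normal)
        f["f8"] <- nrow(p) - f["f7"]
        f["f13"] <- sum(.flagReverse(p$flag) & .flagMateReverse(p$flag))
        f["f14"] <- sum(!.flagReverse(p$flag) & !.flagMateReverse(p$flag))
        f["f15"] <- f["f13"] + f["f14"]
    }
    f
}

#' Extract the fifteen features for one region
#'
#' Counts the fifteen alignment-signature features (see
#' [FeatureSet-class]) over the mapped primary records overlapping the
#' ISPE-padded window of `region`. Per-read channels (unique/multiple
#' placement, one-end-unmapped, clipping, edit-distance class, MAPQ sum
#' and bins) count each record once; per-pair channels (ISPE concordance,
#' strand orientation) count each fully mapped pair once, at its leftmost
#' mate inside the window, or at the in-window mate when the other falls
#' outside. The extraction is invariant under permutation of the record
#' stream.
#'
#' @param x an [AlignmentSet-class].
#' @param region a `GRanges` of length 1 (unpadded interval).
#' @param stats a [LibraryStats-class].
#' @param fcfg a [FeatureConfig-class].
#' @return a named numeric vector `f1..f15`.
#' @export
extractFeatures <- function(x, region, stats, fcfg = featureConfig()) {
    stopifnot(length(region) == 1L)
    fs <- extractFeatureMatrix(x, region, stats = stats, fcfg = fcfg)
    stats::setNames(as.numeric(fs@X[1L, ]), colnames(fs@X))
}

#' Extract a feature matrix over many regions
#'
#' Vectorized form of [extractFeatures()]: one row per region, with the
#' optional 0/1 labels attached.
#'
#' @param x an [AlignmentSet-class].
#' @param regions `GRanges` of unpadded intervals; a numeric `label`
#'   metadata column is used when `label` is NULL.
#' @param label optional integer vector of 0/1 labels.
#' @param stats a [LibraryStats-class].
#' @param fcfg a [FeatureConfig-class].
#' @return a [FeatureSet-class].
#' @examples
#' inv <- GenomicRanges::GRanges("sim", IRanges::IRanges(8001, 10000),
#'                               zygosity = "hom")
#' sim <- simulateSample(simulationConfig(30000L, inv, depth = 10, seed = 3L))
#' st <- estimateLibraryStats(sim$alignments)
#' fs <- extractFeatureMatrix(sim$alignments,
#'                            GenomicRanges::granges(sim$truth@inversions),
#'                            label = 1L, stats = st)
#' featureMatrix(fs)
#' @export
extractFeatureMatrix <- function(x, regions, label = NULL, stats,
                                 fcfg = featureConfig()) {
    if (is.null(label))
        label <- if (!is.null(regions$label))
            as.integer(regions$label) else rep(NA_integer_,
                                               length(regions))
    label <- rep_len(as.integer(label), length(regions))
    win <- paddedWindow(regions, stats)
    rec <- x@records
    recEnd <- .recordEnd(rec)
    X <- matrix(0, nrow = length(regions), ncol = 15L,
                dimnames = list(NULL, paste0("f", 1:15)))
    ws <- BiocGenerics::start(win)
    we <- BiocGenerics::end(win)
    chr <- as.character(GenomicRanges::seqnames(win))
    for (i in seq_along(regions))
        X[i, ] <- .countFeatures(rec, recEnd, chr[i], ws[i], we[i],
                                 stats, fcfg)
    new("FeatureSet", regions = GenomicRanges::granges(regions),
        windows = win, X = X, label = label)
}

#' Write / read a feature matrix as TSV
#'
#' Persists a [FeatureSet-class] with header
#' `region_chrom region_start region_end label f1..f15`; coordinates are
#' written 0-based half-open (BED convention) and converted back on read.
#' Unknown labels are written as `NA`.
#'
#' @param fs a [FeatureSet-class].
#' @param path file path.
#' @return `path` invisibly (write) or a [FeatureSet-class] (read).
#' @export
writeFeatureTsv <- function(fs, path) {
    df <- data.frame(
        region_chrom = as.character(GenomicRanges::seqnames(fs@regions)),
        region_start = BiocGenerics::start(fs@regions) - 1L,
        region_end = BiocGenerics::end(fs@regions),
        label = fs@label)
    df <- cbind(df, as.data.frame(fs@X))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTsv
#' @param stats a [LibraryStats-class] used to reconstruct the padded
#'   windows.
#' @export
readFeatureTsv <- function(path, stats) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    regions <- GenomicRanges::GRanges(
        df$region_chrom,
        IRanges::IRanges(df$region_start + 1L, df$region_end))
    X <- as.matrix(df[, paste0("f", 1:15), drop = FALSE])
    dimnames(X) <- list(NULL, paste0("f", 1:15))
    new("FeatureSet", regions = regions,
        windows = paddedWindow(regions, stats), X = X,
        label = as.integer(df$label))
}
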