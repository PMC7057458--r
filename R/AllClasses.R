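#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

# Column layout shared by every AlignmentSet; kept minimal but sufficient for
# the breakpoint-signature features (flags, CIGAR, MAPQ, mate info, XT/NM/XA).
.RECORD_COLS <- c("qname", "flag", "chrom", "pos", "mapq", "cigar",
                  "mchrom", "mpos", "tlen", "readLength", "xt", "nm", "xa")

#' Library insert-size statistics
#'
#' Summary of a sequencing library estimated from concordantly oriented
#' proper pairs: the mean and standard deviation of the insert size of
#' paired-end reads (ISPE) and the modal read length. The ISPE mean drives
#' window padding around breakpoints, the candidate length filter, and the
#' breakpoint-matching thresholds (multiples of the mean ISPE).
#'
#' @slot ispeMean mean observed insert size (bp), > 0.
#' @slot ispeSd standard deviation of the insert size (bp), >= 0.
#' @slot readLengthMode modal read length (bp).
#' @aliases LibraryStats
#' @export LibraryStats
#' @exportClass LibraryStats
LibraryStats <- setClass("LibraryStats",
    representation(ispeMean = "numeric", ispeSd = "numeric",
                   readLengthMode = "integer"))

setValidity("LibraryStats", function(object) {
    if (length(object@ispeMean) != 1L || !is.finite(object@ispeMean) ||
        object@ispeMean <= 0)
        return("ispeMean must be a single positive number")
    if (length(object@ispeSd) != 1L || !is.finite(object@ispeSd) ||
        object@ispeSd < 0)
        return("ispeSd must be a single non-negative number")
    TRUE
})

#' A set of paired-end alignment records
#'
#' In-memory representation of SAM/BAM records: one row per record with SAM
#' flag, 1-based leftmost position, CIGAR, MAPQ, mate coordinates, observed
#' template length, and the optional tags used by the feature extractor
#' (`XT` unique/repeat placement, `NM` edit distance, `XA` alternative hits).
#' Unmapped records carry CIGAR `"*"`; placed-unmapped mates sit at the
#' mate's coordinate, as written by mainstream aligners.
#'
#' @slot records a `data.frame` with the columns listed under
#'   [alignmentRecords()].
#' @slot seqlengths named integer vector of reference sequence lengths
#'   (used for the SAM header).
#' @aliases AlignmentSet
#' @export AlignmentSet
#' @exportClass AlignmentSet
AlignmentSet <- setClass("AlignmentSet",
    representation(records = "data.frame", seqlengths = "integer"))

setValidity("AlignmentSet", function(object) {
    rec <- object@records
    if (!all(.RECORD_COLS %in% names(rec)))
        return(paste0("records must contain columns: ",
                      paste(.RECORD_COLS, collapse = ", ")))
    if (nrow(rec) == 0L)
        return(TRUE)
    if (any(rec$pos < 1L, na.rm = TRUE))
        return("pos must be >= 1 (1-based SAM coordinate)")
    if (any(rec$mapq < 0L | rec$mapq > 255L, na.rm = TRUE))
        return("mapq must lie in [0, 255]")
    mapped <- bitwAnd(rec$flag, 4L) == 0L
    if (any(mapped & rec$cigar == "*"))
        return("mapped records must have a CIGAR string")
    qw <- rep(NA_integer_, nrow(rec))
    if (any(mapped))
        qw[mapped] <- GenomicAlignments::cigarWidthAlongQuerySpace(
            rec$cigar[mapped])
    bad <- mapped & !is.na(rec$readLength) & qw != rec$readLength
    if (any(bad))
        return("readLength must equal the CIGAR query width (M,I,S,=,X)")
    TRUE
})

#' Configuration of the inversion read-pair simulator
#'
#' Describes a synthetic diploid sample: a single reference sequence of
#' `refLength` bp carrying non-overlapping inversions, sequenced as
#' paired-end fragments with Normal(ispeMean, ispeSd) insert sizes.
#' Defaults reflect typical short-read libraries: ISPE 300-500 bp,
#' read length 70-150 bp, per-base error rate 0.003-0.005, depth 4-25x.
#' Every inversion must be at least `ispeMean` long, the regime in which
#' read-pair signatures are informative.
#'
#' @slot refLength reference length in bp.
#' @slot inversions `GRanges` of implanted inversions with a metadata column
#'   `zygosity` in `{"het","hom"}`.
#' @slot ispeMean,ispeSd insert-size distribution (bp).
#' @slot errorRate per-base substitution error probability.
#' @slot readLength read length (bp).
#' @slot depth expected per-base coverage.
#' @slot minAnchor minimum mapped bases for a breakpoint-spanning read to be
#'   placed at all (soft-clipped); shorter anchors leave the read unmapped.
#' @slot breakpointJitter two integers: range of the absolute offset applied
#'   to the recorded truth breakpoints (emulating imprecise truth
#'   coordinates); `c(0, 0)` disables jitter.
#' @slot pUnmappedCross probability that a breakpoint-crossing read is
#'   reported unmapped instead of soft-clipped, modelling end-to-end
#'   aligners that fail on split reads (never applied to both mates).
#' @slot seqname reference sequence name.
#' @slot seed RNG seed; identical config + seed gives an identical record
#'   stream.
#' @aliases SimulationConfig
#' @export SimulationConfig
#' @exportClass SimulationConfig
SimulationConfig <- setClass("SimulationConfig",
    representation(refLength = "integer", inversions = "GRanges",
                   ispeMean = "numeric", ispeSd = "numeric",
                   errorRate = "numeric", readLength = "integer",
                   depth = "numeric", minAnchor = "integer",
                   breakpointJitter = "integer", pUnmappedCross = "numeric",
                   seqname = "character", seed = "integer"),
    prototype(ispeMean = 400, ispeSd = 30, errorRate = 0.004,
              readLength = 100L, depth = 10, minAnchor = 20L,
              breakpointJitter = c(20L, 30L), pUnmappedCross = 0.35,
              seqname = "sim", seed = 1L))

setValidity("SimulationConfig", function(object) {
    inv <- object@inversions
    if (object@refLength < 1L)
        return("refLength must be positive")
    if (object@errorRate < 0 || object@errorRate >= 1)
        return("errorRate must lie in [0, 1)")
    if (object@minAnchor >= object@readLength)
        return("minAnchor must be smaller than readLength")
    if (length(object@breakpointJitter) != 2L ||
        any(object@breakpointJitter < 0L) ||
        object@breakpointJitter[1L] > object@breakpointJitter[2L])
        return("breakpointJitter must be a non-decreasing pair of non-negative integers")
    if (object@pUnmappedCross < 0 || object@pUnmappedCross > 1)
        return("pUnmappedCross must lie in [0, 1]")
    if (length(inv) > 0L) {
        if (is.null(inv$zygosity) ||
            !all(inv$zygosity %in% c("het", "hom")))
            return("inversions need a zygosity column with values 'het'/'hom'")
        if (any(BiocGenerics::end(inv) > object@refLength))
            return("inversion extends past refLength")
        if (any(BiocGenerics::start(inv) < 1L))
            return("inversion start must be >= 1")
        if (any(BiocGenerics::width(inv) < object@ispeMean))
            return("every inversion must be at least ispeMean long")
        red <- GenomicRanges::reduce(inv, ignore.strand = TRUE)
        if (length(red) != length(inv))
            return("inversions must be non-overlapping")
    }
    TRUE
})

#' Truth set of a simulated sample
#'
#' Recorded inversion coordinates (after optional breakpoint jitter) with
#' zygosity, plus wild-type windows guaranteed to lie at least
#' 2 x ispeMean away from any implanted inversion. Inversions carry the
#' actual implanted coordinates in metadata columns `actualStart` and
#' `actualEnd`.
#'
#' @slot inversions `GRanges` with `zygosity`, `actualStart`, `actualEnd`.
#' @slot wildTypeWindows `GRanges` of negative-class windows.
#' @slot refLength reference length in bp.
#' @aliases TruthSet
#' @export TruthSet
#' @exportClass TruthSet
TruthSet <- setClass("TruthSet",
    representation(inversions = "GRanges", wildTypeWindows = "GRanges",
                   refLength = "integer"))

#' Feature-counting configuration
#'
#' Thresholds used when mapping alignment records to the fifteen numeric
#' features: MAPQ bin edges, the concordant insert-size band (mean +/-
#' `concordantK` standard deviations, opposite-strand orientation), and the
#' minimum number of soft-clipped bases for a read to count as clipped.
#'
#' @slot mqLowMax MAPQ strictly below this is "low" (default 20).
#' @slot mqHighMin MAPQ at or above this is "high" (default 40).
#' @slot concordantK width of the concordant ISPE band in standard
#'   deviations (default 3).
#' @slot minClip minimum total soft-clipped bases for the clipped-read
#'   feature (default 5).
#' @slot countDuplicates whether to count records flagged as PCR/optical
#'   duplicates (default FALSE).
#' @aliases FeatureConfig
#' @export FeatureConfig
#' @exportClass FeatureConfig
FeatureConfig <- setClass("FeatureConfig",
    representation(mqLowMax = "integer", mqHighMin = "integer",
                   concordantK = "numeric", minClip = "integer",
                   countDuplicates = "logical"),
    prototype(mqLowMax = 20L, mqHighMin = 40L, concordantK = 3,
              minClip = 5L, countDuplicates = FALSE))

setValidity("FeatureConfig", function(object) {
    if (object@mqLowMax <= 0L || object@mqLowMax > object@mqHighMin ||
        object@mqHighMin > 255L)
        return("need 0 < mqLowMax <= mqHighMin <= 255")
    if (object@concordantK <= 0)
        return("concordantK must be positive")
    if (object@minClip < 1L)
        return("minClip must be >= 1")
    TRUE
})

#' Per-window alignment-signature features
#'
#' One row per breakpoint window: the unpadded region, the ISPE-padded
#' window actually scanned, the fifteen counts `f1..f15`, and an optional
#' 0/1 label (1 = inversion, 0 = wild-type, NA = unknown/candidate).
#'
#' Feature IDs: 1 uniquely mapped reads; 2 multiply mapped reads; 3 pairs
#' with one end unmapped; 4 clipped reads; 5 mapped error-free; 6 mapped
#' with error; 7 concordant pairs; 8 discordant pairs; 9 sum of mapping
#' quality; 10/11/12 low/middle/high mapping-quality reads; 13 pairs both
#' on the reverse strand; 14 pairs both on the forward strand; 15 pairs on
#' the same strand (13 + 14).
#'
#' @slot regions `GRanges` of unpadded intervals.
#' @slot windows `GRanges` of padded windows.
#' @slot X numeric matrix, one row per region, columns `f1..f15`.
#' @slot label integer vector of 0/1/NA labels.
#' @aliases FeatureSet
#' @export FeatureSet
#' @exportClass FeatureSet
FeatureSet <- setClass("FeatureSet",
    representation(regions = "GRanges", windows = "GRanges", X = "matrix",
                   label = "integer"))

setValidity("FeatureSet", function(object) {
    n <- length(object@regions)
    if (nrow(object@X) != n || length(object@windows) != n ||
        length(object@label) != n)
        return("regions, windows, X rows and label must have equal length")
    if (ncol(object@X) != 15L ||
        !identical(colnames(object@X), paste0("f", 1:15)))
        return("X must have 15 columns named f1..f15")
    if (any(object@X < 0))
        return("features must be non-negative")
    if (n > 0L && any(abs(object@X[, "f15"] -
                          (object@X[, "f13"] + object@X[, "f14"])) > 1e-9))
        return("f15 must equal f13 + f14")
    if (!all(object@label %in% c(0L, 1L, NA_integer_)))
        return("label must be 0, 1 or NA")
    TRUE
})

#' Result of chi-square feature mining
#'
#' Chi-square score of each feature against the inversion/wild-type label,
#' the descending ranking, and the final selected ID set: the top `k`
#' scorers unioned with the curated IDs that domain experience adds back
#' (by default 3, one-end-unmapped pairs, and 9, summed mapping quality).
#'
#' @slot chi2 named numeric vector of chi-square values (names "1".."15").
#' @slot rankedIds feature IDs by descending chi-square (ties by ascending
#'   ID).
#' @slot selectedIds final selected IDs, ascending.
#' @slot curatedIds force-included IDs.
#' @slot k number of top-ranked IDs kept.
#' @aliases SelectionResult
#' @export SelectionResult
#' @exportClass SelectionResult
SelectionResult <- setClass("SelectionResult",
    representation(chi2 = "numeric", rankedIds = "integer",
                   selectedIds = "integer", curatedIds = "integer",
                   k = "integer"))

#' A trained inversion classifier
#'
#' Support vector machine over standardized breakpoint-window features,
#' together with everything needed to score new windows: the selected
#' feature IDs, the scaling parameters, the kernel and its parameters, and
#' the raw training matrix (kept so that the transductive "joint" scaling
#' mode can re-standardize training and candidate features together, the
#' procedure used when a model trained on simulation scores real
#' candidates).
#'
#' @slot selectedIds ordered feature IDs used by the model.
#' @slot kernel `"linear"` or `"radial"`.
#' @slot cost penalty factor (the C of the margin objective).
#' @slot gamma kernel coefficient (inert for the linear kernel; stored
#'   because it is part of the model specification).
#' @slot scalingMode `"joint"` (standardize train and test stacked
#'   together; transductive) or `"train_only"`.
#' @slot trainX raw (unscaled) training matrix restricted to
#'   `selectedIds`.
#' @slot y training labels (0/1).
#' @slot center,spread per-feature standardization parameters fitted on
#'   the training matrix (spread 1 for zero-variance columns).
#' @slot fit the underlying `e1071::svm` fit on the train-only scaled
#'   matrix.
#' @slot seed RNG seed recorded for reproducibility.
#' @aliases InversionClassifier
#' @export InversionClassifier
#' @exportClass InversionClassifier
InversionClassifier <- setClass("InversionClassifier",
    representation(selectedIds = "integer", kernel = "character",
                   cost = "numeric", gamma = "numeric",
                   scalingMode = "character", trainX = "matrix",
                   y = "integer", center = "numeric", spread = "numeric",
                   fit = "ANY", seed = "integer"))

setValidity("InversionClassifier", function(object) {
    if (!all(object@selectedIds %in% 1:15))
        return("selectedIds must be a subset of 1..15")
    if (any(object@spread <= 0))
        return("scaler spread entries must be positive")
    if (!object@scalingMode %in% c("joint", "train_only"))
        return("scalingMode must be 'joint' or 'train_only'")
    TRUE
})

#' Benchmark-matching evaluation result
#'
#' Confusion counts and metrics from matching predicted inversions to a
#' benchmark with breakpoint thresholds of `k` times the mean ISPE:
#' `tp` is the number of calls matching a benchmark entry, `tp0` the number
#' of distinct benchmark entries matched (TP after removing repeats),
#' `fp = noCalls - tp`, `fn = benchmarkN - tp0`,
#' precision = tp / noCalls, recall = tp0 / benchmarkN,
#' F1 = 2PR / (P + R).
#'
#' @slot noCalls,tp,tp0,fp,fn,benchmarkN integer confusion counts.
#' @slot precision,recall,f1 proportions in [0, 1].
#' @slot k threshold multiplier.
#' @slot threshold the absolute breakpoint distance threshold in bp.
#' @aliases EvaluationResult
#' @export EvaluationResult
#' @exportClass EvaluationResult
EvaluationResult <- setClass("EvaluationResult",
    representation(noCalls = "integer", tp = "integer", tp0 = "integer",
                   fp = "integer", fn = "integer", benchmarkN = "integer",
                   precision = "numeric", recall = "numeric",
                   f1 = "numeric", k = "numeric", threshold = "numeric"))

setValidity("EvaluationResult", function(object) {
    if (object@fp != object@noCalls - object@tp)
        return("fp must equal noCalls - tp")
    if (object@fn != object@benchmarkN - object@tp0)
        return("fn must equal benchmarkN - tp0")
    if (object@tp0 > min(object@tp, object@benchmarkN))
        return("tp0 cannot exceed min(tp, benchmarkN)")
    prf <- c(object@precision, object@recall, object@f1)
    if (any(prf < 0 | prf > 1))
        return("precision, recall and f1 must lie in [0, 1]")
    TRUE
})

#' Repeated k-fold cross-validation report
#'
#' Mean confusion counts over all repeats (each repeat: a seeded shuffle,
#' a partition into `nFolds` near-equal folds, training on k-1 folds and
#' scoring the held-out fold so the validation folds tile the data set),
#' plus precision/recall/F1 computed from the mean counts.
#'
#' @slot nRepeats,nFolds integers.
#' @slot tp,tn,fp,fn mean counts per repeat (totals over validation folds).
#' @slot precision,recall,f1 proportions in [0, 1].
#' @slot perRepeat `data.frame` of per-repeat counts.
#' @slot seed RNG seed.
#' @aliases CVReport
#' @export CVReport
#' @exportClass CVReport
CVReport <- setClass("CVReport",
    representation(nRepeats = "integer", nFolds = "integer",
                   tp = "numeric", tn = "numeric", fp = "numeric",
                   fn = "numeric", precision = "numeric",
                   recall = "numeric", f1 = "numeric",
                   perRepeat = "data.frame", seed = "integer"))
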