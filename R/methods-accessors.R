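#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname ispeMean
#' @export
setMethod("ispeMean", "LibraryStats", function(x) x@ispeMean)

#' @rdname ispeMean
#' @export
setMethod("ispeSd", "LibraryStats", function(x) x@ispeSd)

#' @rdname ispeMean
#' @export
setMethod("readLengthMode", "LibraryStats", function(x) x@readLengthMode)

#' @rdname alignmentRecords
#' @export
setMethod("alignmentRecords", "AlignmentSet", function(x) x@records)

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "FeatureSet", function(x) x@X)

#' @rdname featureMatrix
#' @export
setMethod("featureLabels", "FeatureSet", function(x) x@label)

#' @rdname featureMatrix
#' @export
setMethod("featureRegions", "FeatureSet", function(x) x@regions)

#' @rdname featureMatrix
#' @export
setMethod("featureWindows", "FeatureSet", function(x) x@windows)

#' @rdname selectedIds
#' @export
setMethod("selectedIds", "SelectionResult", function(x) x@selectedIds)

#' @rdname selectedIds
#' @export
setMethod("selectedIds", "InversionClassifier", function(x) x@selectedIds)

#' @rdname chiSquareValues
#' @export
setMethod("chiSquareValues", "SelectionResult", function(x) x@chi2)

#' @describeIn AlignmentSet number of records.
#' @param x an `AlignmentSet`.
#' @export
setMethod("length", "AlignmentSet", function(x) nrow(x@records))

#' @describeIn FeatureSet number of feature rows.
#' @param x a `FeatureSet`.
#' @export
setMethod("length", "FeatureSet", function(x) length(x@regions))

setMethod("show", "LibraryStats", function(object) {
    cat(sprintf("LibraryStats: ISPE %.1f +/- %.1f bp, read length %d bp\n",
                object@ispeMean, object@ispeSd, object@readLengthMode))
})

setMethod("show", "AlignmentSet", function(object) {
    rec <- object@records
    mapped <- sum(bitwAnd(rec$flag, 4L) == 0L)
    cat(sprintf("AlignmentSet: %d records (%d mapped) on %d sequence(s)\n",
                nrow(rec), mapped, length(object@seqlengths)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %s (%d bp), %d inversion(s), ",
                       "ISPE %.0f +/- %.0f, read %d bp, depth %.1fx, ",
                       "error %.4f, seed %d\n"),
                object@seqname, object@refLength, length(object@inversions),
                object@ispeMean, object@ispeSd, object@readLength,
                object@depth, object@errorRate, object@seed))
})

setMethod("show", "TruthSet", function(object) {
    cat(sprintf("TruthSet: %d inversion(s), %d wild-type window(s), %d bp reference\n",
                length(object@inversions), length(object@wildTypeWindows),
                object@refLength))
})

setMethod("show", "FeatureSet", function(object) {
    lab <- object@label
    cat(sprintf("FeatureSet: %d windows x 15 features (%d inversion, %d wild-type, %d unlabeled)\n",
                length(object), sum(lab == 1L, na.rm = TRUE),
                sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
})

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: top %d by chi-square = {%s}; curated {%s}; selected {%s}\n",
                object@k,
                paste(utils::head(object@rankedIds, object@k), collapse = ","),
                paste(object@curatedIds, collapse = ","),
                paste(object@selectedIds, collapse = ",")))
})

setMethod("show", "InversionClassifier", function(object) {
    cat(sprintf("InversionClassifier: %s kernel (C=%g, gamma=%g), %d features {%s}, %d training rows, scaling '%s'\n",
                object@kernel, object@cost, object@gamma,
                length(object@selectedIds),
                paste(object@selectedIds, collapse = ","),
                nrow(object@trainX), object@scalingMode))
})

setMethod("show", "EvaluationResult", function(object) {
    cat(sprintf("EvaluationResult (k=%g, threshold %.0f bp):\n", object@k,
                object@threshold))
    cat(sprintf("  No.Calls %d, TP %d, TP0 %d, FP %d, FN %d (benchmark %d)\n",
                object@noCalls, object@tp, object@tp0, object@fp,
                object@fn, object@benchmarkN))
    cat(sprintf("  precision %.2f%%, recall %.2f%%, F1 %.2f%%\n",
                percentValue(object@precision), percentValue(object@recall),
                percentValue(object@f1)))
})

setMethod("show", "CVReport", function(object) {
    cat(sprintf("CVReport: %d x %d-fold CV (seed %d)\n", object@nRepeats,
                object@nFolds, object@seed))
    cat(sprintf("  mean TP %.2f, TN %.2f, FP %.2f, FN %.2f\n",
                object@tp, object@tn, object@fp, object@fn))
    cat(sprintf("  precision %.2f%%, recall %.2f%%, F1 %.2f%%\n",
                percentValue(object@precision), percentValue(object@recall),
                percentValue(object@f1)))
})
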