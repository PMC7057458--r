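#' @include AllClasses.R
NULL

#' Accessors for library insert-size statistics
#'
#' `ispeMean()`, `ispeSd()` and `readLengthMode()` extract the mean and
#' standard deviation of the insert size of paired-end reads (ISPE) and the
#' modal read length from a [LibraryStats-class] object.
#'
#' @param x a `LibraryStats` object.
#' @return a single numeric (or integer for `readLengthMode`).
#' @examples
#' st <- LibraryStats(ispeMean = 400, ispeSd = 30, readLengthMode = 100L)
#' ispeMean(st)
#' @export
setGeneric("ispeMean", function(x) standardGeneric("ispeMean"))

#' @rdname ispeMean
#' @export
setGeneric("ispeSd", function(x) standardGeneric("ispeSd"))

#' @rdname ispeMean
#' @export
setGeneric("readLengthMode", function(x) standardGeneric("readLengthMode"))

#' Access the per-record table of an AlignmentSet
#'
#' Returns the underlying `data.frame` of alignment records (one row per
#' SAM record; columns `qname`, `flag`, `chrom`, `pos`, `mapq`, `cigar`,
#' `mchrom`, `mpos`, `tlen`, `readLength`, `xt`, `nm`, `xa`).
#'
#' @param x an [AlignmentSet-class].
#' @return a `data.frame`.
#' @export
setGeneric("alignmentRecords", function(x) standardGeneric("alignmentRecords"))

#' Accessors for FeatureSet objects
#'
#' `featureMatrix()` returns the n-by-15 numeric feature matrix,
#' `featureLabels()` the 0/1/NA label vector, `featureRegions()` the
#' unpadded candidate/truth intervals and `featureWindows()` the
#' ISPE-padded windows the features were counted in.
#'
#' @param x a [FeatureSet-class].
#' @return a matrix, an integer vector, or a `GRanges`.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' @rdname featureMatrix
#' @export
setGeneric("featureRegions", function(x) standardGeneric("featureRegions"))

#' @rdname featureMatrix
#' @export
setGeneric("featureWindows", function(x) standardGeneric("featureWindows"))

#' Selected feature IDs of a selection result or classifier
#'
#' @param x a [SelectionResult-class] or [InversionClassifier-class].
#' @return an integer vector of feature IDs (subset of 1..15).
#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))

#' Chi-square scores of a selection result
#'
#' @param x a [SelectionResult-class].
#' @return a named numeric vector of chi-square values, one per feature ID.
#' @export
setGeneric("chiSquareValues", function(x) standardGeneric("chiSquareValues"))
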