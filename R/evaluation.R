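#' @include AllClasses.R utils.R
NULL

#' Precision, recall and F1 from confusion counts
#'
#' Exact metric arithmetic: precision = TP / No.Calls (equivalently
#' TP / (TP + FP)), recall = TP0 / benchmark size when the distinct-
#' benchmark-entry count is available (whole-set evaluation), otherwise
#' TP / (TP + FN) (cross-validation mode, where FN is counted per fold
#' rather than against a benchmark denominator), and
#' F1 = 2PR / (P + R). All-zero denominators yield 0 with a warning.
#' Values are exact proportions; rounding (half-up, 2 decimals on the
#' percent scale) is applied only at report time via [percentValue()].
#'
#' @param tp true positives.
#' @param fp false positives (used when `noCalls` is NULL).
#' @param fn false negatives (used when `tp0`/`benchmarkN` are NULL).
#' @param tp0 distinct benchmark entries matched.
#' @param noCalls total calls made.
#' @param benchmarkN benchmark size.
#' @return named numeric vector `c(precision, recall, f1)` (proportions).
#' @examples
#' # printed two-decimal percentages follow via percentValue():
#' m <- metricsFromCounts(tp = 478, tp0 = 168, noCalls = 1468,
#'                        benchmarkN = 238)
#' percentValue(m[["precision"]])  # 32.56
#' percentValue(m[["recall"]])     # 70.59
#' @export
metricsFromCounts <- function(tp, fp = NULL, fn = NULL, tp0 = NULL,
                              noCalls = NULL, benchmarkN = NULL) {
    stopifnot(tp >= 0)
    if (is.null(noCalls)) {
        if (is.null(fp))
            stop("need either noCalls or fp")
        noCalls <- tp + fp
    }
    precision <- if (noCalls > 0) tp / noCalls else {
        warning("no calls: precision defined as 0")
        0
    }
    recall <- if (!is.null(tp0) && !is.null(benchmarkN)) {
        if (benchmarkN > 0) tp0 / benchmarkN else {
            warning("empty benchmark: recall defined as 0")
            0
        }
    } else {
        if (is.null(fn))
            stop("need either tp0+benchmarkN or fn")
        if (tp + fn > 0) tp / (tp + fn) else {
            warning("no positives: recall defined as 0")
            0
        }
    }
    f1 <- if (precision + recall > 0)
        2 * precision * recall / (precision + recall) else 0
    c(precision = precision, recall = recall, f1 = f1)
}

#' Match predicted inversions against a benchmark
#'
#' A call matches a benchmark entry iff both lie on the same chromosome
#' and each breakpoint of the call is within `k` times the mean ISPE of
#' the corresponding benchmark breakpoint. Each call is assigned to at
#' most one benchmark entry — the nearest by summed breakpoint distance,
#' ties to the earlier entry. `tp` counts matching calls; `tp0` counts
#' distinct benchmark entries matched (TP with repeats removed); then
#' `fp = noCalls - tp`, `fn = benchmarkN - tp0`, and precision/recall/F1
#' follow [metricsFromCounts()]. The result is invariant under
#' permutation of calls and benchmark.
#'
#' @param calls `GRanges` of predicted inversions.
#' @param benchmark `GRanges` of benchmark inversions.
#' @param stats a [LibraryStats-class].
#' @param k threshold multiplier, conventionally 1, 2 or 3 (other values
#'   are allowed with a warning).
#' @return an [EvaluationResult-class].
#' @export
matchCalls <- function(calls, benchmark, stats, k = 3) {
    if (!k %in% c(1, 2, 3))
        warning("k = ", k, " is outside the conventional {1,2,3}")
    thr <- k * ispeMean(stats)
    cChr <- as.character(GenomicRanges::seqnames(calls))
    bChr <- as.character(GenomicRanges::seqnames(benchmark))
    cs <- BiocGenerics::start(calls); ce <- BiocGenerics::end(calls)
    bs <- BiocGenerics::start(benchmark)
    be <- BiocGenerics::end(benchmark)
    matched <- rep(NA_integer_, length(calls))
    for (i in seq_along(calls)) {
        ds <- abs(cs[i] - bs)
        de <- abs(ce[i] - be)
        ok <- bChr == cChr[i] & ds <= thr & de <= thr
        if (any(ok)) {
            tot <- ds + de
            tot[!ok] <- Inf
            matched[i] <- which.min(tot)
        }
    }
    tp <- sum(!is.na(matched))
    tp0 <- length(unique(matched[!is.na(matched)]))
    noCalls <- length(calls)
    benchmarkN <- length(benchmark)
    m <- suppressWarnings(
        metricsFromCounts(tp = tp, tp0 = tp0, noCalls = noCalls,
                          benchmarkN = benchmarkN))
    new("EvaluationResult", noCalls = as.integer(noCalls),
        tp = as.integer(tp), tp0 = as.integer(tp0),
        fp = as.integer(noCalls - tp),
        fn = as.integer(benchmarkN - tp0),
        benchmarkN = as.integer(benchmarkN),
        precision = m[["precision"]], recall = m[["recall"]],
        f1 = m[["f1"]], k = k, threshold = thr)
}

#' Repeated k-fold cross-validation of the inversion classifier
#'
#' For each repeat the rows are shuffled with a seeded RNG and split into
#' `nFolds` near-equal folds; the SVM is trained on k-1 folds and scored
#' on the held-out fold, rotating so the validation folds tile the data
#' set; confusion counts are accumulated over validation folds only. The
#' report averages the per-repeat totals over all repeats and derives
#' precision (TP/(TP+FP)), recall (TP/(TP+FN)) and F1 from the mean
#' counts. An optional `scoreMask` restricts which validation rows are
#' counted (e.g. scoring only real-data rows while simulated rows still
#' participate in training). A training fold with a single class triggers
#' a reshuffle with the next seed (logged via `message()`).
#'
#' @param X raw feature matrix (15 columns or exactly the selected
#'   columns); standardized internally once, over all rows.
#' @param y 0/1 labels.
#' @param selectedIds feature IDs to use (default [defaultFeatureIds()]).
#' @param nFolds folds per repeat (default 10).
#' @param nRepeats repeats (default 100).
#' @param kernel,C,gamma SVM specification (default linear, C = 0.1,
#'   gamma = 20).
#' @param seed base RNG seed; repeat r uses `seed + r - 1`.
#' @param scoreMask optional logical vector: rows counted when held out.
#' @return a [CVReport-class].
#' @export
crossValidate <- function(X, y, selectedIds = defaultFeatureIds(),
                          nFolds = 10L, nRepeats = 100L,
                          kernel = c("linear", "radial"), C = 0.1,
                          gamma = 20, seed = 1L, scoreMask = NULL) {
    kernel <- match.arg(kernel)
    X <- .selectColumns(as.matrix(X), selectedIds)
    y <- as.integer(y)
    n <- nrow(X)
    if (n < nFolds)
        stop("need at least nFolds rows")
    if (length(unique(y)) < 2L)
        stop("degenerate labels: both classes must be present")
    if (is.null(scoreMask))
        scoreMask <- rep(TRUE, n)
    Xs <- scaleFeatures(X, mode = "train_only")$train
    per <- matrix(0, nrow = nRepeats, ncol = 4L,
                  dimnames = list(NULL, c("tp", "tn", "fp", "fn")))
    for (r in seq_len(nRepeats)) {
        counts <- NULL
        attempt <- 0L
        while (is.null(counts)) {
            set.seed(seed + r - 1L + attempt * 10000L)
            perm <- sample.int(n)
            fold <- rep_len(seq_len(nFolds), n)[order(perm)]
            counts <- tryCatch(
                .cvOneRepeat(Xs, y, fold, nFolds, kernel, C, gamma,
                             scoreMask),
                singleClassFold = function(e) NULL)
            if (is.null(counts)) {
                attempt <- attempt + 1L
                message("repeat ", r,
                        ": single-class training fold, reshuffling")
                if (attempt > 25L)
                    stop("could not form folds with both classes")
            }
        }
        per[r, ] <- counts
    }
    means <- colMeans(per)
    m <- suppressWarnings(
        metricsFromCounts(tp = means[["tp"]], fp = means[["fp"]],
                          fn = means[["fn"]]))
    new("CVReport", nRepeats = as.integer(nRepeats),
        nFolds = as.integer(nFolds), tp = means[["tp"]],
        tn = means[["tn"]], fp = means[["fp"]], fn = means[["fn"]],
        precision = m[["precision"]], recall = m[["recall"]],
        f1 = m[["f1"]], perRepeat = as.data.frame(per),
        seed = as.integer(seed))
}

.cvOneRepeat <- function(Xs, y, fold, nFolds, kernel, C, gamma,
                         scoreMask) {
    counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (f in seq_len(nFolds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L)
            stop(structure(class = c("singleClassFold", "error",
                                     "condition"),
                           list(message = "single-class fold",
                                call = NULL)))
        fit <- e1071::svm(x = Xs[tr, , drop = FALSE],
                          y = factor(y[tr], levels = c(0L, 1L)),
                          kernel = kernel, cost = C, gamma = gamma,
                          scale = FALSE)
        te <- which(!tr & scoreMask)
        if (length(te) == 0L)
            next
        pred <- as.integer(as.character(
            stats::predict(fit, Xs[te, , drop = FALSE])))
        truth <- y[te]
        counts["tp"] <- counts["tp"] + sum(pred == 1L & truth == 1L)
        counts["tn"] <- counts["tn"] + sum(pred == 0L & truth == 0L)
        counts["fp"] <- counts["fp"] + sum(pred == 1L & truth == 0L)
        counts["fn"] <- counts["fn"] + sum(pred == 0L & truth == 1L)
    }
    counts
}

#' Read a benchmark inversion set
#'
#' Accepts VCF (`SVTYPE=INV`) or BED, returning plain intervals.
#'
#' @param path file path.
#' @return a `GRanges`.
#' @export
readBenchmark <- function(path) {
    GenomicRanges::granges(readCallerCalls(path, "benchmark"))
}
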