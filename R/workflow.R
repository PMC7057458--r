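#' @include AllClasses.R simulator.R features.R selection.R classifier.R
#' @include candidates.R evaluation.R
NULL

#' Draw simulator parameter sets within the standard ranges
#'
#' Samples `n` parameter sets uniformly within the ranges a short-read
#' inversion study spans: inversion length 500-6000 bp (never below the
#' drawn ISPE mean), ISPE mean 300-500 bp, per-base error rate
#' 0.003-0.005, read length 70-150 bp, depth 4-25x, truth-breakpoint
#' offset 20-30 bp. Each set becomes a [SimulationConfig-class] with
#' `nInversions` inversions (zygosity alternating het/hom) spaced so that
#' padded training windows never collide, on a reference sized to fit.
#'
#' @param n number of parameter sets (default 13).
#' @param nInversions inversions per sample (default 5).
#' @param seed RNG seed.
#' @return a list of [SimulationConfig-class] objects.
#' @export
drawSimulationConfigs <- function(n = 13L, nInversions = 5L, seed = 1L) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
        ispe <- runif(1, 300, 500)
        sd <- runif(1, 20, 40)
        widths <- as.integer(round(runif(nInversions,
                                         max(500, ceiling(ispe)), 6000)))
        gap <- as.integer(ceiling(2 * ispe)) + 200L
        starts <- integer(nInversions)
        pos <- gap
        for (j in seq_len(nInversions)) {
            starts[j] <- pos + as.integer(sample.int(200L, 1L))
            pos <- starts[j] + widths[j] + gap
        }
        # room for one wild-type window per inversion, plus clearance
        refLength <- pos + sum(widths) + (nInversions + 2L) * gap
        inv <- GenomicRanges::GRanges(
            sprintf("sim%02d", i),
            IRanges::IRanges(starts, width = widths),
            zygosity = rep_len(c("hom", "het"), nInversions))
        simulationConfig(
            refLength = refLength, inversions = inv, ispeMean = ispe,
            ispeSd = sd, errorRate = runif(1, 0.003, 0.005),
            readLength = as.integer(round(runif(1, 70, 150))),
            depth = runif(1, 4, 25),
            breakpointJitter = c(20L, 30L),
            seqname = sprintf("sim%02d", i),
            seed = as.integer(seed + 1000L * i))
    })
}

#' Simulate samples and extract labeled training features
#'
#' Runs the simulator for each configuration, estimates per-sample
#' library statistics, builds the labeled windows (inversions = 1,
#' wild-type = 0) and extracts the fifteen features, concatenating
#' everything into one [FeatureSet-class]. With `nSamples` samples of
#' `nInversions` each, the result contains `nSamples * nInversions`
#' label-1 rows.
#'
#' @param configs list of [SimulationConfig-class] (e.g. from
#'   [drawSimulationConfigs()]).
#' @param fcfg a [FeatureConfig-class].
#' @return a list with `features` ([FeatureSet-class]), `stats` (list of
#'   per-sample [LibraryStats-class]), `truths` (list of
#'   [TruthSet-class]).
#' @export
simulateTrainingSet <- function(configs, fcfg = featureConfig()) {
    fsets <- vector("list", length(configs))
    stats <- vector("list", length(configs))
    truths <- vector("list", length(configs))
    for (i in seq_along(configs)) {
        sim <- simulateSample(configs[[i]])
        st <- estimateLibraryStats(sim$alignments)
        tw <- buildTrainingWindows(sim$truth, st)
        regions <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(tw),
            IRanges::IRanges(tw$regionStart, tw$regionEnd))
        fsets[[i]] <- extractFeatureMatrix(sim$alignments, regions,
                                           label = tw$label, stats = st,
                                           fcfg = fcfg)
        stats[[i]] <- st
        truths[[i]] <- sim$truth
    }
    list(features = .rbindFeatureSets(fsets), stats = stats,
         truths = truths)
}

.rbindFeatureSets <- function(fsets) {
    lv <- unique(unlist(lapply(fsets, function(f)
        GenomeInfoDb::seqlevels(f@regions))))
    cat_ <- function(grs) {
        grs <- lapply(grs, function(g) {
            GenomeInfoDb::seqlevels(g) <- lv
            g
        })
        do.call(c, grs)
    }
    new("FeatureSet",
        regions = cat_(lapply(fsets, slot, "regions")),
        windows = cat_(lapply(fsets, slot, "windows")),
        X = do.call(rbind, lapply(fsets, slot, "X")),
        label = do.call(c, lapply(fsets, slot, "label")))
}

#' Simulate a sample and write its artifact files
#'
#' Writes the SAM file, the truth BED (inversions with zygosity plus
#' wild-type windows) and a JSON sidecar echoing the resolved
#' configuration and seed.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory (created if missing).
#' @param prefix file name prefix (default `"sim"`).
#' @return named character vector of the written paths, invisibly.
#' @export
runSimulate <- function(config, outDir, prefix = "sim") {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateSample(config)
    samPath <- file.path(outDir, paste0(prefix, ".sam"))
    bedPath <- file.path(outDir, paste0(prefix, ".truth.bed"))
    cfgPath <- file.path(outDir, paste0(prefix, ".config.json"))
    writeSam(sim$alignments, samPath)
    writeTruthBed(sim$truth, bedPath)
    inv <- config@inversions
    jsonlite::write_json(list(
        refLength = config@refLength,
        seqname = config@seqname,
        inversions = data.frame(
            start = BiocGenerics::start(inv),
            end = BiocGenerics::end(inv),
            zygosity = if (length(inv)) inv$zygosity else character(0)),
        ispeMean = config@ispeMean, ispeSd = config@ispeSd,
        errorRate = config@errorRate, readLength = config@readLength,
        depth = config@depth, minAnchor = config@minAnchor,
        breakpointJitter = config@breakpointJitter,
        pUnmappedCross = config@pUnmappedCross, seed = config@seed),
        cfgPath, auto_unbox = TRUE, digits = NA)
    invisible(c(sam = samPath, truth = bedPath, config = cfgPath))
}

#' Train a model from simulated samples and write it with a report
#'
#' Simulates the configured samples, extracts labeled features, performs
#' chi-square feature mining (or uses a fixed ID set), standardizes,
#' trains the SVM and serializes the model, alongside a JSON training
#' report (chi-square table, ranking, selected IDs, cross-validation
#' metrics).
#'
#' @param configs list of [SimulationConfig-class].
#' @param outDir output directory.
#' @param features `"chi2"` (default: top-8 by chi-square plus curated
#'   {3, 9}), `"reference"` (the fixed reference ten-feature set,
#'   [defaultFeatureIds()]) or `"all"` (all fifteen).
#' @param kernel,C,gamma,scalingMode SVM specification.
#' @param cvRepeats cross-validation repeats for the report (default
#'   10; 0 skips CV).
#' @param seed RNG seed.
#' @param fcfg a [FeatureConfig-class].
#' @return a list with `model`, `selection`, `cv`, `features` and the
#'   written `paths`.
#' @export
runTrain <- function(configs, outDir, features = c("chi2", "reference",
                                                   "all"),
                     kernel = "linear", C = 0.1, gamma = 20,
                     scalingMode = "joint", cvRepeats = 10L, seed = 1L,
                     fcfg = featureConfig()) {
    features <- match.arg(features)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ts <- simulateTrainingSet(configs, fcfg = fcfg)
    fs <- ts$features
    X <- featureMatrix(fs)
    y <- featureLabels(fs)
    sel <- selectFeatures(chiSquareScores(X, y))
    ids <- switch(features,
                  chi2 = selectedIds(sel),
                  reference = defaultFeatureIds(),
                  all = 1:15)
    model <- trainInversionClassifier(X, y, selectedIds = ids,
                                      kernel = kernel, C = C,
                                      gamma = gamma,
                                      scalingMode = scalingMode,
                                      seed = seed)
    cv <- if (cvRepeats > 0L)
        crossValidate(X, y, selectedIds = ids, nRepeats = cvRepeats,
                      kernel = kernel, C = C, gamma = gamma,
                      seed = seed) else NULL
    modelPath <- file.path(outDir, "model.rds")
    reportPath <- file.path(outDir, "training_report.json")
    tsvPath <- file.path(outDir, "training_features.tsv")
    writeInversionModel(model, modelPath)
    writeFeatureTsv(fs, tsvPath)
    report <- list(
        chi2_by_feature = as.list(chiSquareValues(sel)),
        ranked_ids = sel@rankedIds,
        selected_ids = ids,
        n_windows = length(fs),
        n_label1 = sum(y == 1L),
        kernel = kernel, C = C, gamma = gamma,
        scaling_mode = scalingMode, seed = seed)
    if (!is.null(cv))
        report$cv <- list(
            n_repeats = cv@nRepeats, n_folds = cv@nFolds,
            tp = cv@tp, tn = cv@tn, fp = cv@fp, fn = cv@fn,
            precision_pct = percentValue(cv@precision),
            recall_pct = percentValue(cv@recall),
            f1_pct = percentValue(cv@f1))
    jsonlite::write_json(report, reportPath, auto_unbox = TRUE,
                         digits = NA)
    list(model = model, selection = sel, cv = cv, features = fs,
         paths = c(model = modelPath, report = reportPath,
                   features = tsvPath))
}

#' Classify candidate inversions with a trained model
#'
#' Reads candidate calls from one or more caller files, merges them into
#' the union candidate set, drops candidates shorter than the mean ISPE,
#' extracts per-candidate window features, scores them with the model and
#' writes the label-1 candidates as a VCF (plus a per-candidate
#' feature/score TSV). Zero surviving candidates yield a valid
#' header-only VCF with a warning.
#'
#' @param model an [InversionClassifier-class] or a path to one.
#' @param alignments an [AlignmentSet-class] or a SAM/BAM path.
#' @param callerFiles named character vector of VCF/BED paths (names =
#'   caller names), or a ready `GRanges` of candidates.
#' @param outDir output directory.
#' @param stats optional [LibraryStats-class]; estimated from the
#'   alignments when NULL.
#' @param eps breakpoint tolerance for merging (default 10 bp).
#' @param fcfg a [FeatureConfig-class].
#' @return a list with `calls` (`GRanges` of label-1 candidates),
#'   `candidates`, `predictions`, `features` and written `paths`.
#' @export
runCall <- function(model, alignments, callerFiles, outDir,
                    stats = NULL, eps = 10L, fcfg = featureConfig()) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (is.character(model))
        model <- readInversionModel(model)
    if (is.character(alignments))
        alignments <- readAlignments(alignments)
    if (is.null(stats))
        stats <- estimateLibraryStats(alignments)
    cand <- if (is(callerFiles, "GRanges")) callerFiles else {
        nm <- names(callerFiles)
        if (is.null(nm))
            nm <- paste0("caller", seq_along(callerFiles))
        do.call(c, unname(Map(readCallerCalls, callerFiles, nm)))
    }
    cand <- mergeCandidates(cand, eps = eps)
    cand <- filterByLength(cand, stats)
    vcfPath <- file.path(outDir, "calls.vcf")
    tsvPath <- file.path(outDir, "candidate_features.tsv")
    if (length(cand) == 0L) {
        warning("no candidates survive the length filter")
        writeCallsVcf(GenomicRanges::GRanges(), vcfPath)
        return(list(calls = GenomicRanges::GRanges(), candidates = cand,
                    predictions = integer(0), features = NULL,
                    paths = c(vcf = vcfPath)))
    }
    fs <- extractFeatureMatrix(alignments, cand, stats = stats,
                               fcfg = fcfg)
    pred <- predictInversions(model, featureMatrix(fs))
    calls <- cand[pred == 1L]
    writeCallsVcf(calls, vcfPath)
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(cand)),
        start = BiocGenerics::start(cand) - 1L,
        end = BiocGenerics::end(cand), predicted = pred)
    utils::write.table(cbind(df, as.data.frame(featureMatrix(fs))),
                       tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(calls = calls, candidates = cand, predictions = pred,
         features = fs, paths = c(vcf = vcfPath, features = tsvPath))
}

#' Evaluate calls against a benchmark at several thresholds
#'
#' Runs [matchCalls()] at each requested multiple of the mean ISPE and
#' writes a JSON report; chromosome namespaces must overlap.
#'
#' @param calls `GRanges` or a VCF/BED path.
#' @param benchmark `GRanges` or a VCF/BED path.
#' @param stats a [LibraryStats-class].
#' @param k vector of threshold multipliers (default `1:3`).
#' @param outPath optional JSON report path.
#' @return a named list of [EvaluationResult-class], one per `k`.
#' @export
runEvaluate <- function(calls, benchmark, stats, k = 1:3,
                        outPath = NULL) {
    if (is.character(calls))
        calls <- GenomicRanges::granges(readCallerCalls(calls, "calls"))
    if (is.character(benchmark))
        benchmark <- readBenchmark(benchmark)
    if (length(calls) && length(benchmark)) {
        cn <- unique(as.character(GenomicRanges::seqnames(calls)))
        bn <- unique(as.character(GenomicRanges::seqnames(benchmark)))
        if (!any(cn %in% bn))
            stop("chromosome namespaces do not overlap; calls use {",
                 paste(cn, collapse = ","), "}, benchmark uses {",
                 paste(bn, collapse = ","), "}")
    }
    res <- lapply(k, function(kk)
        matchCalls(calls, benchmark, stats, k = kk))
    names(res) <- paste0("k", k)
    if (!is.null(outPath)) {
        rep <- lapply(res, function(r) list(
            no_calls = r@noCalls, tp = r@tp, tp0 = r@tp0, fp = r@fp,
            fn = r@fn, benchmark_n = r@benchmarkN,
            precision_pct = percentValue(r@precision),
            recall_pct = percentValue(r@recall),
            f1_pct = percentValue(r@f1)))
        jsonlite::write_json(rep, outPath, auto_unbox = TRUE,
                             digits = NA)
    }
    res
}
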