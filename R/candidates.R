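#' @include AllClasses.R
NULL

#' Read inversion calls from an upstream caller
#'
#' Ingests a caller's output as candidate inversions. VCF input keeps
#' records with `SVTYPE=INV` and an interval end derived from the INFO
#' `END` key (or `POS + |SVLEN|` when only `SVLEN` is present); records
#' with neither are skipped with a warning giving the skip count. BED
#' input is taken as-is. Intervals are returned 1-based closed (`GRanges`
#' convention; BED's 0-based half-open coordinates are converted on
#' read).
#'
#' @param path a `.vcf`, `.vcf.gz` or `.bed` file.
#' @param callerName name recorded in the `sources` column.
#' @return a `GRanges` with metadata columns `sources` and `ids`
#'   (`CharacterList`).
#' @export
readCallerCalls <- function(path, callerName) {
    if (!file.exists(path))
        stop("call file not found: ", path)
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    gr <- if (ext == "vcf") {
        .readVcfInversions(path)
    } else if (ext == "bed") {
        bed <- rtracklayer::import(path, format = "BED")
        GenomicRanges::granges(bed)
    } else {
        stop("unsupported call format: ", path)
    }
    ids <- names(gr)
    if (is.null(ids))
        ids <- paste0(callerName, "_", seq_along(gr))
    names(gr) <- NULL
    gr$sources <- IRanges::CharacterList(as.list(rep(callerName,
                                                     length(gr))))
    gr$ids <- IRanges::CharacterList(as.list(ids))
    gr
}

.readVcfInversions <- function(path) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    info <- VariantAnnotation::info(vcf)
    svtype <- if ("SVTYPE" %in% colnames(info))
        as.character(info$SVTYPE) else rep(NA_character_, nrow(info))
    inv <- !is.na(svtype) & svtype == "INV"
    vcf <- vcf[inv, ]
    info <- VariantAnnotation::info(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    st <- BiocGenerics::start(rr)
    en <- rep(NA_integer_, length(rr))
    if ("END" %in% colnames(info)) {
        v <- info$END
        if (is(v, "List")) v <- as.integer(vapply(v, function(z)
            if (length(z)) z[[1L]] else NA_integer_, integer(1L)))
        en <- as.integer(v)
    }
    if ("SVLEN" %in% colnames(info)) {
        v <- info$SVLEN
        if (is(v, "List")) v <- vapply(v, function(z)
            if (length(z)) as.integer(z[[1L]]) else NA_integer_,
            integer(1L))
        miss <- is.na(en) & !is.na(v)
        en[miss] <- st[miss] + abs(as.integer(v[miss]))
    }
    keep <- !is.na(en) & en > st
    if (any(!keep))
        warning(sum(!keep),
                " INV record(s) without usable END/SVLEN skipped")
    gr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(rr)[keep],
        IRanges::IRanges(st[keep], en[keep]))
    names(gr) <- names(rr)[keep]
    gr
}

#' Merge candidate inversions from multiple callers
#'
#' Forms the union of calls across callers; two calls whose left
#' breakpoints differ by at most `eps` bp AND whose right breakpoints
#' differ by at most `eps` bp are collapsed into one candidate (the
#' breakpoints of the first-seen call are kept, sources and IDs are
#' unioned). `eps = 0` collapses exact duplicates only. The operation is
#' idempotent and the output is sorted by (chrom, start).
#'
#' @param calls a `GRanges` with `sources`/`ids` columns (e.g.
#'   concatenated [readCallerCalls()] output).
#' @param eps breakpoint tolerance in bp (default 10).
#' @return a merged, sorted `GRanges`.
#' @export
mergeCandidates <- function(calls, eps = 10L) {
    n <- length(calls)
    if (n == 0L)
        return(calls)
    if (is.null(calls$sources))
        calls$sources <- IRanges::CharacterList(
            as.list(rep("unknown", n)))
    if (is.null(calls$ids))
        calls$ids <- IRanges::CharacterList(
            as.list(paste0("call_", seq_len(n))))
    chr <- as.character(GenomicRanges::seqnames(calls))
    st <- BiocGenerics::start(calls)
    en <- BiocGenerics::end(calls)
    src <- as.list(calls$sources)
    ids <- as.list(calls$ids)
    keepIdx <- integer(0)
    assign <- integer(n)
    for (i in seq_len(n)) {
        hit <- 0L
        for (j in keepIdx) {
            if (chr[j] == chr[i] && abs(st[j] - st[i]) <= eps &&
                abs(en[j] - en[i]) <= eps) {
                hit <- j
                break
            }
        }
        if (hit == 0L) {
            keepIdx <- c(keepIdx, i)
            assign[i] <- i
        } else {
            assign[i] <- hit
        }
    }
    out <- calls[keepIdx]
    out$sources <- IRanges::CharacterList(lapply(keepIdx, function(j)
        sort(unique(unlist(src[assign == j])))))
    out$ids <- IRanges::CharacterList(lapply(keepIdx, function(j)
        unique(unlist(ids[assign == j]))))
    GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Drop candidates shorter than the mean ISPE
#'
#' Read-pair signatures are only informative for inversions at least one
#' insert size long, so candidates shorter than the library's mean ISPE
#' are removed; a candidate exactly as long as the mean survives.
#'
#' @param calls a `GRanges`.
#' @param stats a [LibraryStats-class].
#' @return the filtered `GRanges`.
#' @export
filterByLength <- function(calls, stats) {
    calls[BiocGenerics::width(calls) >= ispeMean(stats)]
}

#' Write candidates as BED (with a sources column)
#'
#' @param calls a `GRanges` with an optional `sources` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCandidatesBed <- function(calls, path) {
    src <- if (is.null(calls$sources)) rep(".", length(calls)) else
        vapply(as.list(calls$sources), paste, character(1L),
               collapse = ",")
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(calls)),
        start = BiocGenerics::start(calls) - 1L,
        end = BiocGenerics::end(calls), name = src)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write inversion calls as a minimal VCF
#'
#' Emits VCF v4.2 with symbolic `<INV>` alleles and INFO keys `SVTYPE`,
#' `END` and `SOURCES`. An empty call set yields a valid header-only
#' file.
#'
#' @param calls a `GRanges` (metadata column `sources` optional).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCallsVcf <- function(calls, path) {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
             "##INFO=<ID=SOURCES,Number=.,Type=String,Description=\"Supporting callers\">",
             "##ALT=<ID=INV,Description=\"Inversion\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    if (length(calls) == 0L) {
        writeLines(hdr, path)
        return(invisible(path))
    }
    src <- if (is.null(calls$sources)) rep(".", length(calls)) else
        vapply(as.list(calls$sources), paste, character(1L),
               collapse = ",")
    lines <- sprintf("%s\t%d\tinv%d\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=%d;SOURCES=%s",
                     as.character(GenomicRanges::seqnames(calls)),
                     BiocGenerics::start(calls), seq_along(calls),
                     BiocGenerics::end(calls), src)
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Derive jittered pseudo-candidates from a truth set
#'
#' Stands in for upstream callers when exercising the pipeline offline:
#' each truth inversion yields a candidate with both breakpoints offset
#' by a uniform amount up to `maxJitter` bp, and (optionally) each
#' wild-type window yields a decoy candidate, so downstream
#' classification has true and false candidates to separate.
#'
#' @param truth a [TruthSet-class].
#' @param maxJitter maximum absolute breakpoint offset (default 100 bp).
#' @param includeDecoys add wild-type windows as decoy candidates
#'   (default TRUE).
#' @param seed RNG seed.
#' @return a `GRanges` with `sources`/`ids` columns.
#' @export
pseudoCallerCalls <- function(truth, maxJitter = 100L,
                              includeDecoys = TRUE, seed = 1L) {
    set.seed(seed)
    inv <- truth@inversions
    L <- truth@refLength
    jit <- function(x) as.integer(x + round(runif(length(x), -maxJitter,
                                                  maxJitter)))
    st <- pmax(1L, jit(BiocGenerics::start(inv)))
    en <- pmin(L, jit(BiocGenerics::end(inv)))
    bad <- st >= en
    st[bad] <- BiocGenerics::start(inv)[bad]
    en[bad] <- BiocGenerics::end(inv)[bad]
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(inv),
                                 IRanges::IRanges(st, en))
    if (includeDecoys && length(truth@wildTypeWindows))
        gr <- c(gr, GenomicRanges::granges(truth@wildTypeWindows))
    gr$sources <- IRanges::CharacterList(
        as.list(rep("pseudo", length(gr))))
    gr$ids <- IRanges::CharacterList(
        as.list(paste0("pseudo_", seq_along(gr))))
    gr
}
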