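#' @include AllClasses.R utils.R
NULL

#' Construct an AlignmentSet from a record table
#'
#' @param records a `data.frame` with the columns listed under
#'   [alignmentRecords()]; missing optional columns (`xt`, `nm`, `xa`)
#'   are filled with NA.
#' @param seqlengths named integer vector of reference lengths.
#' @return an [AlignmentSet-class].
#' @export
alignmentSet <- function(records, seqlengths) {
    for (col in c("xt", "nm", "xa"))
        if (is.null(records[[col]]))
            records[[col]] <- if (col == "nm") NA_integer_ else NA_character_
    records <- records[, .RECORD_COLS, drop = FALSE]
    rownames(records) <- NULL
    new("AlignmentSet", records = records,
        seqlengths = structure(as.integer(seqlengths),
                               names = names(seqlengths)))
}

#' Reference ending coordinate of each record
#'
#' 1-based inclusive rightmost mapped base (`pos` for unmapped records, so
#' placed-unmapped mates behave as 1 bp points for overlap queries).
#'
#' @param x an [AlignmentSet-class].
#' @return integer vector.
#' @keywords internal
.recordEnd <- function(rec) {
    end <- rec$pos
    mapped <- bitwAnd(rec$flag, 4L) == 0L & rec$cigar != "*"
    if (any(mapped)) {
        rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(
            rec$cigar[mapped])
        end[mapped] <- rec$pos[mapped] + pmax(rw, 1L) - 1L
    }
    end
}

#' Write an AlignmentSet as a SAM file
#'
#' Emits a SAM v1 text file with `@HD`/`@SQ` header lines, `*` qualities,
#' and an N-run sequence of the recorded read length (so read length
#' round-trips for unmapped records too). Optional tags `XT:A`, `NM:i`,
#' `XA:Z` are written when present.
#'
#' @param x an [AlignmentSet-class].
#' @param path output file path (`.sam`).
#' @return `path`, invisibly.
#' @seealso [readAlignments()]
#' @export
writeSam <- function(x, path) {
    rec <- x@records
    so <- if (.isCoordSorted(rec)) "coordinate" else "unsorted"
    hdr <- c(sprintf("@HD\tVN:1.6\tSO:%s", so),
             sprintf("@SQ\tSN:%s\tLN:%d", names(x@seqlengths),
                     x@seqlengths))
    if (nrow(rec) == 0L) {
        writeLines(hdr, path)
        return(invisible(path))
    }
    rnext <- ifelse(is.na(rec$mchrom), "*",
                    ifelse(rec$mchrom == rec$chrom, "=", rec$mchrom))
    pnext <- ifelse(is.na(rec$mpos), 0L, rec$mpos)
    seqs <- strrep("N", ifelse(is.na(rec$readLength), 1L, rec$readLength))
    tags <- character(nrow(rec))
    hasXT <- !is.na(rec$xt)
    tags[hasXT] <- paste0("\tXT:A:", rec$xt[hasXT])
    hasNM <- !is.na(rec$nm)
    tags[hasNM] <- paste0(tags[hasNM], "\tNM:i:", rec$nm[hasNM])
    hasXA <- !is.na(rec$xa)
    tags[hasXA] <- paste0(tags[hasXA], "\tXA:Z:", rec$xa[hasXA])
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*%s",
                     rec$qname, rec$flag, rec$chrom, rec$pos, rec$mapq,
                     rec$cigar, rnext, pnext, rec$tlen, seqs, tags)
    writeLines(c(hdr, lines), path)
    invisible(path)
}

.isCoordSorted <- function(rec) {
    if (nrow(rec) < 2L) return(TRUE)
    o <- order(rec$chrom, rec$pos)
    identical(o, seq_len(nrow(rec)))
}

#' Read paired-end alignments from SAM or BAM
#'
#' Reads records (optionally restricted to those overlapping a region)
#' into an [AlignmentSet-class]. SAM input is converted to sorted,
#' indexed BAM on the fly via [Rsamtools::asBam()]; regional queries use
#' the BAI index and return every record with a mapped base in the region,
#' including placed-unmapped mates sitting at an overlapping coordinate.
#'
#' @param path a `.sam` or `.bam` file.
#' @param region optional `GRanges` of length 1 restricting the query.
#' @param includeSecondary keep secondary (0x100) and supplementary
#'   (0x800) records (default FALSE).
#' @return an [AlignmentSet-class].
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' cfg <- simulationConfig(refLength = 20000L, seed = 7L)
#' sim <- simulateSample(cfg)
#' writeSam(sim$alignments, sam)
#' aln <- readAlignments(sam)
#' length(aln)
#' @export
readAlignments <- function(path, region = NULL, includeSecondary = FALSE) {
    if (!file.exists(path))
        stop("alignment file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext == "sam") {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                                indexDestination = TRUE)
    } else {
        bam <- path
        if (!file.exists(paste0(path, ".bai")) && !is.null(region))
            Rsamtools::indexBam(path)
    }
    what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
              "mpos", "isize", "seq")
    param <- if (is.null(region)) {
        Rsamtools::ScanBamParam(what = what, tag = c("XT", "NM", "XA"))
    } else {
        Rsamtools::ScanBamParam(what = what, tag = c("XT", "NM", "XA"),
                                which = region)
    }
    res <- Rsamtools::scanBam(bam, param = param)
    recs <- lapply(res, function(r) {
        n <- length(r$qname)
        seqw <- if (n) BiocGenerics::width(r$seq) else integer(0)
        cig <- as.character(r$cigar)
        mapped <- !is.na(cig) & cig != "*"
        rl <- seqw
        rl[mapped & (is.na(rl) | rl <= 1L)] <-
            GenomicAlignments::cigarWidthAlongQuerySpace(
                cig[mapped & (is.na(rl) | rl <= 1L)])
        data.frame(
            qname = as.character(r$qname), flag = as.integer(r$flag),
            chrom = as.character(r$rname), pos = as.integer(r$pos),
            mapq = as.integer(r$mapq),
            cigar = ifelse(is.na(cig), "*", cig),
            mchrom = as.character(r$mrnm), mpos = as.integer(r$mpos),
            tlen = as.integer(r$isize), readLength = as.integer(rl),
            xt = .tagOrNA(r$tag$XT, n, "character"),
            nm = .tagOrNA(r$tag$NM, n, "integer"),
            xa = .tagOrNA(r$tag$XA, n, "character"),
            stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, recs)
    rownames(rec) <- NULL
    if (!is.null(region) && length(recs) > 1L)
        rec <- rec[!duplicated(paste(rec$qname, rec$flag, rec$pos)), ]
    if (!includeSecondary && nrow(rec) > 0L)
        rec <- rec[!(.flagSecondary(rec$flag) |
                     .flagSupplementary(rec$flag)), , drop = FALSE]
    rec$mapq[is.na(rec$mapq)] <- 0L
    rec$tlen[is.na(rec$tlen)] <- 0L
    # scanBam reports no position for placed-unmapped records; restore the
    # mate coordinate they are stored at
    unm <- .flagUnmapped(rec$flag) & is.na(rec$pos)
    rec$pos[unm] <- rec$mpos[unm]
    rec$chrom[unm & is.na(rec$chrom)] <- rec$mchrom[unm & is.na(rec$chrom)]
    # likewise a placed-unmapped mate sits at the record's own coordinate
    munm <- .flagMateUnmapped(rec$flag) & is.na(rec$mpos)
    rec$mpos[munm] <- rec$pos[munm]
    rec$mchrom[munm & is.na(rec$mchrom)] <- rec$chrom[munm & is.na(rec$mchrom)]
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    alignmentSet(rec, seqlengths = hdr)
}

.tagOrNA <- function(v, n, mode) {
    if (is.null(v))
        return(vector(mode, n)[NA][seq_len(n)])
    if (mode == "integer") as.integer(v) else as.character(v)
}

#' Estimate library insert-size statistics
#'
#' Computes the mean and standard deviation of the insert size of
#' paired-end reads (ISPE) from concordantly oriented pairs: primary
#' mapped records whose mate maps to the opposite strand, with
#' `0 < TLEN < tlenCap` (each pair counted once via the positive-TLEN
#' mate). The cap excludes chimeric/inter-chromosomal artifacts. The modal
#' read length is taken over mapped records.
#'
#' @param x an [AlignmentSet-class].
#' @param maxRecords number of leading records to sample (default 200000).
#' @param tlenCap upper bound on |TLEN| (default 10000 bp).
#' @param minPairs minimum usable pairs required (default 50).
#' @return a [LibraryStats-class].
#' @export
estimateLibraryStats <- function(x, maxRecords = 200000L, tlenCap = 10000,
                                 minPairs = 50L) {
    rec <- utils::head(x@records, maxRecords)
    ok <- !.flagUnmapped(rec$flag) & .flagPaired(rec$flag) &
        !.flagMateUnmapped(rec$flag) &
        !.flagSecondary(rec$flag) & !.flagSupplementary(rec$flag) &
        (.flagReverse(rec$flag) != .flagMateReverse(rec$flag)) &
        rec$tlen > 0L & rec$tlen < tlenCap
    tl <- rec$tlen[ok]
    if (length(tl) < minPairs)
        stop("insufficient data: only ", length(tl),
             " usable opposite-strand pairs (need >= ", minPairs, ")")
    mapped <- !.flagUnmapped(rec$flag)
    rls <- rec$readLength[mapped & !is.na(rec$readLength)]
    mode <- if (length(rls)) {
        tab <- table(rls)
        as.integer(names(tab)[which.max(tab)])
    } else NA_integer_
    new("LibraryStats", ispeMean = mean(tl),
        ispeSd = if (length(tl) > 1L) stats::sd(tl) else 0,
        readLengthMode = mode)
}
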