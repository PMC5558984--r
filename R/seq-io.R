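#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings with the validation the pipeline relies
#' on: sequences over \code{A,C,G,T,N}, non-empty, unique ids. A light
#' pre-scan reports the offending line for malformed input.
#'
#' @param path file path.
#' @param records a named \code{DNAStringSet} (or named character vector).
#' @param width line wrap for writing.
#' @return \code{readFasta}: a named \code{DNAStringSet}. \code{writeFasta}:
#'   the path, invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeFasta(c(r1 = "ACGT"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    inseq <- FALSE
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (!nzchar(ln)) next
        if (startsWith(ln, ">")) { inseq <- TRUE; next }
        if (!inseq)
            stop(sprintf("FASTA format error at line %d: sequence before header", i))
        if (grepl("[^ACGTNacgtn]", ln))
            stop(sprintf("non-IUPAC character in FASTA at line %d", i))
    }
    x <- Biostrings::readDNAStringSet(path)
    if (length(x)) {
        if (any(Biostrings::width(x) == 0L)) stop("empty sequence in ", path)
        if (anyDuplicated(names(x))) stop("duplicate sequence ids in ", path)
    }
    x
}

#' @rdname readFasta
#' @export
writeFasta <- function(records, path, width = 70L) {
    if (is.character(records))
        records <- Biostrings::DNAStringSet(records)
    if (length(records) && (is.null(names(records)) || anyDuplicated(names(records))))
        stop("records must carry unique ids")
    Biostrings::writeXStringSet(records, path, width = width)
    invisible(path)
}

#' Write paired reads as FASTQ
#'
#' @param seqs character vector of read sequences.
#' @param names read names.
#' @param path output file.
#' @param qual single quality character applied to every base (the simulator
#'   carries no quality model).
#' @return the path, invisibly.
#' @export
writeFastq <- function(seqs, names, path, qual = "I") {
    stopifnot(length(seqs) == length(names))
    quals <- vapply(nchar(seqs), function(n) strrep(qual, n), "")
    writeLines(paste0("@", names, "\n", seqs, "\n+\n", quals), path)
    invisible(path)
}

# ---- SAM -------------------------------------------------------------------

.SAM_COLS <- c("qname", "flag", "rname", "pos0", "mapq", "cigar",
               "rnext", "pnext0", "tlen", "seq", "qual", "tags")

#' Read and write plain-text SAM
#'
#' The pipeline's alignment contract is tab-separated SAM text with
#' \code{@HD}/\code{@SQ} headers. SAM's 1-based POS/PNEXT are converted to
#' the package-internal 0-based \code{pos0}/\code{pnext0} on reading and
#' back on writing; everything else round-trips verbatim. Optional tags are
#' carried as a single string and otherwise ignored.
#'
#' @param path SAM file.
#' @param reads a read data.frame as returned by \code{readSam} (columns
#'   \code{qname,flag,rname,pos0,mapq,cigar,rnext,pnext0,tlen,seq,qual,tags}
#'   plus derived \code{mapped,strand}).
#' @param header character vector of header lines; defaults to
#'   \code{attr(reads, "header")}.
#' @return \code{readSam}: data.frame of aligned reads with the header in
#'   \code{attr(,"header")}. \code{writeSam}: the path, invisibly.
#' @export
readSam <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "@")]
    if (!any(startsWith(hdr, "@SQ")))
        stop("SAM file lacks an @SQ header line: ", path)
    rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (!length(rec)) {
        out <- as.data.frame(setNames(
            c(list(character(0), integer(0), character(0), integer(0),
                   integer(0), character(0), character(0), integer(0),
                   integer(0), character(0), character(0), character(0)),
              list()), .SAM_COLS))
        attr(out, "header") <- hdr
        return(out)
    }
    fields <- strsplit(rec, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
        stop("SAM record with fewer than 11 fields at data line ",
             which(nf < 11L)[1L])
    g <- function(i) vapply(fields, `[`, "", i)
    tags <- vapply(fields, function(f)
        if (length(f) > 11L) paste(f[-(1:11)], collapse = "\t") else "", "")
    out <- data.frame(
        qname = g(1L), flag = as.integer(g(2L)), rname = g(3L),
        pos0 = as.integer(g(4L)) - 1L, mapq = as.integer(g(5L)),
        cigar = g(6L), rnext = g(7L), pnext0 = as.integer(g(8L)) - 1L,
        tlen = as.integer(g(9L)), seq = g(10L), qual = g(11L),
        tags = tags, stringsAsFactors = FALSE)
    out$pos0[out$pos0 < 0L] <- NA_integer_    # SAM POS 0 = placed nowhere
    out$pnext0[out$pnext0 < 0L] <- NA_integer_
    out$mapped <- bitwAnd(out$flag, 4L) == 0L
    out$strand <- ifelse(bitwAnd(out$flag, 16L) != 0L, "-", "+")
    # per-record validation: query-consuming CIGAR length must equal SEQ length
    chk <- out$mapped & out$cigar != "*" & out$seq != "*"
    if (any(chk)) {
        ql <- cigarQueryLength(out$cigar[chk])
        bad <- ql != nchar(out$seq[chk])
        if (any(bad))
            stop("CIGAR/sequence length mismatch for read(s): ",
                 paste(head(out$qname[chk][bad], 5L), collapse = ", "))
    }
    attr(out, "header") <- hdr
    out
}

#' @rdname readSam
#' @export
writeSam <- function(reads, path, header = attr(reads, "header")) {
    if (is.null(header))
        stop("no SAM header supplied and none attached to the reads")
    lines <- header
    if (nrow(reads)) {
        tagcol <- if (!is.null(reads$tags)) reads$tags else rep("", nrow(reads))
        pos <- ifelse(is.na(reads$pos0), 0L, reads$pos0 + 1L)
        pnext <- ifelse(is.na(reads$pnext0), 0L, reads$pnext0 + 1L)
        body <- paste(reads$qname, reads$flag, reads$rname, pos,
                      reads$mapq, reads$cigar, reads$rnext, pnext,
                      reads$tlen, reads$seq, reads$qual, sep = "\t")
        has <- nzchar(tagcol)
        body[has] <- paste(body[has], tagcol[has], sep = "\t")
        lines <- c(lines, body)
    }
    writeLines(lines, path)
    invisible(path)
}

.samHeader <- function(refName, refLen) {
    c("@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", refName, refLen))
}

.headerRefNames <- function(header) {
    sq <- header[startsWith(header, "@SQ")]
    sub(".*\tSN:([^\t]+).*", "\\1", sq)
}

# ---- pileup & coverage -----------------------------------------------------

#' Per-base read depth over an interval
#'
#' Depth at base \code{i} is the number of reads whose reference-consuming
#' CIGAR operations cover \code{i}; soft-clipped bases contribute nothing.
#'
#' @param reads aligned read data.frame (see \code{\link{readSam}}).
#' @param refName reference sequence to pile up on.
#' @param interval 0-based half-open \code{c(start, end)}.
#' @return a \code{\linkS4class{PileupTrack}}.
#' @export
pileup <- function(reads, refName, interval) {
    stopifnot(length(interval) == 2L, interval[2L] > interval[1L])
    hdr <- attr(reads, "header")
    known <- unique(c(if (!is.null(hdr)) .headerRefNames(hdr),
                      reads$rname[reads$mapped]))
    if (!refName %in% known)
        stop("unknown reference sequence: ", refName)
    sel <- reads$mapped & reads$rname == refName & !is.na(reads$pos0)
    width <- as.integer(interval[2L] - interval[1L])
    if (!any(sel)) {
        return(new("PileupTrack", refName = refName,
                   start = as.integer(interval[1L]),
                   depth = integer(width)))
    }
    rl <- .refLenFast(reads$cigar[sel])
    ir <- IRanges::IRanges(start = reads$pos0[sel] + 1L, width = rl)
    cov <- IRanges::coverage(ir, width = max(IRanges::end(ir), interval[2L]))
    v <- as.integer(as.vector(cov))
    lo <- interval[1L] + 1L
    hi <- interval[2L]
    dep <- integer(width)
    if (lo <= length(v)) {
        take <- seq.int(lo, min(hi, length(v)))
        dep[seq_along(take)] <- v[take]
    }
    new("PileupTrack", refName = refName, start = as.integer(interval[1L]),
        depth = dep)
}

#' Median depth and fraction of bases at or above a threshold
#'
#' @param track a \code{\linkS4class{PileupTrack}}.
#' @param threshold minimum depth.
#' @return list with \code{medianDepth} and \code{fractionAtOrAbove}.
#' @examples
#' tr <- new("PileupTrack", refName = "r", start = 0L,
#'           depth = c(0L, 10L, 20L))
#' coverageSummary(tr, 10)  # median 10, fraction 2/3
#' @export
coverageSummary <- function(track, threshold) {
    d <- depth(track)
    if (!length(d)) stop("empty pileup track")
    list(medianDepth = stats::median(d),
         fractionAtOrAbove = mean(d >= threshold))
}

# ---- clip extraction -------------------------------------------------------

#' Extract terminal soft-clip events from aligned reads
#'
#' One event per terminal soft clip of at least \code{minClipLen} bases.
#' The breakpoint coordinate of a right clip is the reference position one
#' past the last aligned base (i.e. where the clipped tail begins); for a
#' left clip it is the first aligned position. Hard clips never yield
#' events: their bases are absent from the record.
#'
#' @param reads aligned read data.frame.
#' @param minClipLen minimum clip length (default 5; shorter clips are
#'   alignment noise).
#' @return data.frame with columns \code{side} ("left"/"right"),
#'   \code{refCoord} (0-based), \code{clippedSeq}, \code{readName}.
#' @export
clipEvents <- function(reads, minClipLen = 5L) {
    empty <- data.frame(side = character(), refCoord = integer(),
                        clippedSeq = character(), readName = character(),
                        stringsAsFactors = FALSE)
    sel <- reads$mapped & !is.na(reads$pos0) & reads$cigar != "*"
    if (!any(sel)) return(empty)
    r <- reads[sel, , drop = FALSE]
    cl <- .terminalClips(r$cigar)
    rl <- .refLenFast(r$cigar)
    out <- list(empty)
    li <- which(cl$left >= minClipLen)
    if (length(li)) {
        out[[length(out) + 1L]] <- data.frame(
            side = "left", refCoord = r$pos0[li],
            clippedSeq = substr(r$seq[li], 1L, cl$left[li]),
            readName = r$qname[li], stringsAsFactors = FALSE)
    }
    ri <- which(cl$right >= minClipLen)
    if (length(ri)) {
        n <- nchar(r$seq[ri])
        out[[length(out) + 1L]] <- data.frame(
            side = "right", refCoord = r$pos0[ri] + rl[ri],
            clippedSeq = substr(r$seq[ri], n - cl$right[ri] + 1L, n),
            readName = r$qname[ri], stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}
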