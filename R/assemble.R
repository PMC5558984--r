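# Harvesting and greedy overlap assembly of the insertion allele. The
# assembly task mirrors a single-amplicon reconstruction: one contig,
# unidirectional growth from the 5' junction consensus, terminating in the
# element's poly-A tail.

#' Harvest the reads carrying insertion sequence at a call
#'
#' Returns the clipped tails of reads clipped at (within \code{tol} bp of)
#' either breakpoint, plus unmapped reads whose mates map within
#' \code{flank} bp of the call. Unmapped reads are included in both
#' orientations, since their strand relative to the inserted element is
#' unknown.
#'
#' @param reads aligned read data.frame of one individual.
#' @param call an \code{\linkS4class{InsertionCall}}.
#' @param minClipLen minimum harvested clip length.
#' @param flank mate-mapping window around the call.
#' @param tol breakpoint tolerance for clip harvesting.
#' @param includeUnplaced also harvest read pairs in which both mates are
#'   unmapped. With fragment sizes well below the element length, the
#'   element interior is populated almost entirely by such pairs, so this
#'   is on by default; switch it off when the alignment contains unplaced
#'   reads from elsewhere in the genome.
#' @return character vector of sequences (tails and unmapped reads).
#' @export
collectInsertReads <- function(reads, call, minClipLen = 5L, flank = 1000L,
                               tol = 5L, includeUnplaced = TRUE) {
    ev <- clipEvents(reads, minClipLen = minClipLen)
    nearR <- ev$side == "right" & abs(ev$refCoord - call@tsdEnd) <= tol
    nearL <- ev$side == "left" & abs(ev$refCoord - call@tsdStart) <= tol
    tails <- ev$clippedSeq[nearR | nearL]
    un <- reads[!reads$mapped, , drop = FALSE]
    mateNear <- !is.na(un$pnext0) &
        un$pnext0 >= call@tsdStart - flank &
        un$pnext0 <= call@tsdEnd + flank
    if (includeUnplaced) mateNear <- mateNear | is.na(un$pnext0)
    uns <- un$seq[mateNear]
    out <- c(tails, uns, if (length(uns)) .revcomp(uns))
    out[nchar(out) > 0L]
}

#' Greedy overlap consensus assembly
#'
#' Unidirectional greedy extension: starting from the 5' seed contig (the
#' right-clip cluster consensus, i.e. the start of the inserted element),
#' the read with the longest exact suffix-prefix overlap of at least
#' \code{minOverlap} bases is merged in, repeatedly. Inputs are sorted
#' lexicographically first and ties broken by sequence order, so the result
#' is a pure function of the input multiset. Extension stops when the
#' growing 3' end is an A-run of \code{polyaStop}+ bases (the element's
#' poly-A tail, whose full length is unrecoverable from short reads) or
#' when no read overlaps.
#'
#' @param reads character vector (or \code{DNAStringSet}) of harvested
#'   sequences.
#' @param minOverlap minimum exact overlap (bp).
#' @param seedContigs optional seed sequences, 5' junction consensus first;
#'   defaults to the longest read.
#' @param polyaStop terminal A-run length that terminates assembly.
#' @param maxTrim total error-backtracking budget: when no read overlaps
#'   the growing end exactly (a sequencing error in the most recently
#'   merged tail blocks every exact overlap), terminal bases are trimmed
#'   one at a time, up to this many in total, before extension is retried.
#' @return an \code{\linkS4class{AssembledContig}}.
#' @examples
#' assembleConsensus(c("ACGTACGTAA", "GTAACCCC"), minOverlap = 4)
#' @export
assembleConsensus <- function(reads, minOverlap = 31L, seedContigs = NULL,
                              polyaStop = 15L, maxTrim = 200L) {
    reads <- as.character(reads)
    reads <- reads[nzchar(reads)]
    if (!length(reads) && is.null(seedContigs)) stop("no reads to assemble")
    reads <- sort(unique(reads))
    contig <- if (!is.null(seedContigs)) seedContigs[[1]]
              else reads[which.max(nchar(reads))]
    k <- as.integer(minOverlap)
    # index reads by their k-base prefix
    idx <- new.env(parent = emptyenv(), hash = TRUE)
    alive <- rep(TRUE, length(reads))
    pre <- substr(reads, 1L, k)
    usable <- nchar(reads) >= k
    for (i in which(usable)) {
        key <- pre[i]
        assign(key, c(idx[[key]], i), envir = idx)
    }
    nUsed <- 0L
    terminated <- "read-exhaustion"
    maxRead <- if (length(reads)) max(nchar(reads)) else 0L
    longest <- contig
    repeat {
        if (nchar(contig) > nchar(longest)) longest <- contig
        if (.trailingRun(contig, "A") >= polyaStop) {
            terminated <- "polyA-run"
            break
        }
        cl <- nchar(contig)
        best <- 0L; bestRead <- NA_integer_
        pmin_ <- max(1L, cl - maxRead + 1L)
        pmax_ <- cl - k + 1L
        if (pmax_ >= pmin_) {
            for (p in pmin_:pmax_) {      # longest overlap first
                key <- substr(contig, p, p + k - 1L)
                cand <- idx[[key]]
                if (is.null(cand)) next
                o <- cl - p + 1L
                suff <- substr(contig, p, cl)
                for (i in cand) {
                    if (!alive[i]) next
                    if (nchar(reads[i]) < o) next
                    if (substr(reads[i], 1L, o) == suff) {
                        best <- o; bestRead <- i
                        break
                    }
                }
                if (best > 0L) break
            }
        }
        if (best == 0L) {
            # error backtracking: a substitution in the last merged tail
            # blocks every exact overlap; trim it away and retry
            if (maxTrim > 0L && cl > k) {
                maxTrim <- maxTrim - 1L
                contig <- substr(contig, 1L, cl - 1L)
                next
            }
            break
        }
        ext <- substr(reads[bestRead], best + 1L, nchar(reads[bestRead]))
        alive[bestRead] <- FALSE
        nUsed <- nUsed + 1L
        if (nzchar(ext)) contig <- paste0(contig, ext)
    }
    # on exhaustion, keep the longest contig held (terminal error trims
    # that never recovered are restored)
    if (terminated == "read-exhaustion" && nchar(longest) > nchar(contig))
        contig <- longest
    new("AssembledContig", sequence = contig, nReadsUsed = nUsed,
        terminatedBy = terminated)
}
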