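# Structural annotation of an assembled insertion allele: open reading
# frames, repeat-library classification by seeded ungapped alignment, and
# the LINE-1 segment decomposition (5'UTR, ORF1, spacer, ORF2, 3'UTR,
# poly-A, orientation).

#' Find open reading frames on both strands
#'
#' Scans all six frames for ATG-to-stop spans of at least \code{minLen}
#' bases. Within each (stop, frame) pair the span is trimmed to the
#' outermost (most upstream) ATG following the previous stop. A frame's
#' trailing segment with no stop yields an ORF running to the last complete
#' codon. The reported length includes the stop codon.
#'
#' @param sequence character or \code{DNAString(Set)}.
#' @param minLen minimum ORF length in bp (multiple of 3, >= 3).
#' @return data.frame with 0-based half-open \code{start, end} on the input
#'   sequence, \code{strand}, and \code{length}; sorted by start.
#' @examples
#' findOrfs("ATGAAATAA", minLen = 9)
#' @export
findOrfs <- function(sequence, minLen = 300L) {
    if (minLen < 3L || minLen %% 3L != 0L)
        stop("minLen must be a multiple of 3 and >= 3")
    s <- toupper(as.character(sequence)[[1]])
    L <- nchar(s)
    res <- list(data.frame(start = integer(), end = integer(),
                           strand = character(), length = integer(),
                           stringsAsFactors = FALSE))
    for (strand in c("+", "-")) {
        str <- if (strand == "+") s else .revcomp(s)
        for (f in 0:2) {
            if (L - 2L < f + 1L) next
            starts <- seq.int(f + 1L, L - 2L, by = 3L)
            codons <- substring(str, starts, starts + 2L)
            isStop <- codons %in% .STOP_CODONS
            isAtg <- codons == "ATG"
            bounds <- c(0L, which(isStop), length(codons) + 1L)
            for (bi in seq_len(length(bounds) - 1L)) {
                lo <- bounds[bi] + 1L          # first codon after prev stop
                hi <- bounds[bi + 1L]          # stop codon index (or past end)
                if (lo > length(codons)) next
                seg <- seq.int(lo, min(hi, length(codons)))
                atg <- seg[isAtg[seg]]
                if (!length(atg)) next
                a <- atg[1L]                   # outermost ATG
                endCodon <- min(hi, length(codons))
                b0 <- starts[a] - 1L           # 0-based start on str
                e0 <- starts[endCodon] + 2L    # 0-based end (half-open)
                if (e0 - b0 < minLen) next
                if (strand == "+") {
                    st <- b0; en <- e0
                } else {
                    st <- L - e0; en <- L - b0
                }
                res[[length(res) + 1L]] <- data.frame(
                    start = st, end = en, strand = strand,
                    length = e0 - b0, stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, res)
    out[order(out$start, out$end), , drop = FALSE]
}

#' Build a synthetic repeat consensus library
#'
#' The classification library for desk-scale runs: the generator's LINE-1
#' element plus decoy consensus sequences (a SINE-sized and an LTR-sized
#' random sequence) so that classification is a genuine choice. A real
#' repeat consensus (e.g. a curated L1 family) can be supplied instead for
#' real-data work.
#'
#' @param element the synthetic element (\code{DNAStringSet}).
#' @param seed RNG seed for the decoys.
#' @return a named \code{DNAStringSet}.
#' @export
makeRepeatLibrary <- function(element, seed) {
    set.seed(.deriveSeed(seed, 40L))
    lib <- c(as.character(element)[[1]],
             .randDna(250L), .randDna(5000L))
    names(lib) <- c("L1_synthetic", "SINE_decoy_synthetic",
                    "LTR_decoy_synthetic")
    Biostrings::DNAStringSet(lib)
}

# shared k-mer diagonal fit of query against one subject strand; returns
# NULL or list(identity, qStart, qEnd, votes)
.diagonalHit <- function(query, subject, k = 11L, maxKmerOcc = 5L,
                         minSeeds = 3L) {
    ql <- nchar(query); sl <- nchar(subject)
    if (ql < k || sl < k) return(NULL)
    sPos <- seq_len(sl - k + 1L)
    sK <- substring(subject, sPos, sPos + k - 1L)
    tab <- table(sK)
    ok <- sK %in% names(tab)[tab <= maxKmerOcc]
    dict <- split(sPos[ok], sK[ok])
    qPos <- seq_len(ql - k + 1L)
    qK <- substring(query, qPos, qPos + k - 1L)
    hit <- qK %in% names(dict)
    if (!any(hit)) return(NULL)
    diags <- unlist(lapply(which(hit), function(i)
        qPos[i] - dict[[qK[i]]]), use.names = FALSE)
    dt <- sort(table(diags), decreasing = TRUE)
    votes <- as.integer(dt[1L])
    if (votes < minSeeds) return(NULL)
    d <- as.integer(names(dt)[1L])
    qs <- max(1L, 1L + d); qe <- min(ql, sl + d)
    if (qe - qs + 1L < k) return(NULL)
    qc <- strsplit(substr(query, qs, qe), "")[[1]]
    sc <- strsplit(substr(subject, qs - d, qe - d), "")[[1]]
    list(identity = 100 * mean(qc == sc), qStart = qs - 1L, qEnd = qe,
         votes = votes)
}

#' Classify a contig against a repeat consensus library
#'
#' Seeded ungapped alignment: shared 11-mers vote for a diagonal against
#' each library entry on each strand; the best diagonal's full overlap is
#' scored base-by-base. Percent identity is computed over the aligned span
#' only. Hits are returned best-first (aligned length x identity).
#'
#' @param contig character, \code{DNAStringSet} or
#'   \code{\linkS4class{AssembledContig}}.
#' @param library a named \code{DNAStringSet} (see
#'   \code{\link{makeRepeatLibrary}}).
#' @param k seed k-mer size.
#' @param minIdentity discard hits below this percent identity (chance
#'   diagonals over long overlaps score near 25).
#' @return data.frame with \code{libraryId, identityPct, alignedStart,
#'   alignedEnd} (0-based half-open on the contig), \code{alignedLen,
#'   strand}.
#' @export
classifyRepeat <- function(contig, library, k = 11L, minIdentity = 40) {
    if (is(contig, "AssembledContig")) contig <- contig@sequence
    query <- toupper(as.character(contig)[[1]])
    if (!length(library)) stop("empty repeat library")
    res <- list()
    for (i in seq_along(library)) {
        subj <- as.character(library[[i]])
        for (strand in c("+", "-")) {
            s <- if (strand == "+") subj else .revcomp(subj)
            h <- .diagonalHit(query, s, k = k)
            if (is.null(h) || h$identity < minIdentity) next
            res[[length(res) + 1L]] <- data.frame(
                libraryId = names(library)[i], identityPct = h$identity,
                alignedStart = h$qStart, alignedEnd = h$qEnd,
                alignedLen = h$qEnd - h$qStart, strand = strand,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(res))
        return(data.frame(libraryId = character(), identityPct = numeric(),
                          alignedStart = integer(), alignedEnd = integer(),
                          alignedLen = integer(), strand = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    out[order(-(out$alignedLen * out$identityPct)), , drop = FALSE]
}

#' Annotate the LINE-1 structure of an assembled insertion allele
#'
#' Orientation comes from the best repeat hit's strand relative to the host
#' gene strand; ORF1 and ORF2 are the two longest non-overlapping ORFs on
#' the element strand, in positional order; the spacer is the gap between
#' them; the UTRs are the residual flanks, and the poly-A length is the
#' terminal A-run (a lower bound when assembly stopped inside the tail).
#' The element is called full length when both ORFs reach at least 90% of
#' the lengths expected from the classifying library entry.
#'
#' @param contig an \code{\linkS4class{AssembledContig}} (or sequence).
#' @param call the \code{\linkS4class{InsertionCall}} the contig was
#'   assembled at (provides the TSD length).
#' @param library repeat consensus library.
#' @param hostGeneStrand genome strand of the host gene.
#' @param minOrfLen minimum ORF length considered.
#' @return a \code{\linkS4class{Line1Annotation}}.
#' @export
annotateLine1 <- function(contig, call, library, hostGeneStrand = "+",
                          minOrfLen = 300L) {
    seqc <- if (is(contig, "AssembledContig")) contig@sequence
            else as.character(contig)[[1]]
    hits <- classifyRepeat(seqc, library)
    elementStrand <- if (nrow(hits)) hits$strand[1L] else "+"
    orient <- if (elementStrand == hostGeneStrand) "+" else "-"
    es <- if (elementStrand == "+") seqc else .revcomp(seqc)
    orfs <- findOrfs(es, minLen = minOrfLen)
    orfs <- orfs[orfs$strand == "+", , drop = FALSE]
    # two longest non-overlapping ORFs, greedy by length then leftmost start
    orfs <- orfs[order(-orfs$length, orfs$start), , drop = FALSE]
    pick <- list()
    for (i in seq_len(nrow(orfs))) {
        cand <- orfs[i, ]
        if (all(vapply(pick, function(p)
            cand$end <= p$start || cand$start >= p$end, logical(1)))) {
            pick[[length(pick) + 1L]] <- cand
            if (length(pick) == 2L) break
        }
    }
    na <- c(NA_integer_, NA_integer_)
    L <- nchar(es)
    polya <- .trailingRun(es, "A")
    if (length(pick) < 2L) {
        one <- if (length(pick)) c(pick[[1]]$start, pick[[1]]$end) else na
        return(new("Line1Annotation", tsdLen = call@tsdEnd - call@tsdStart,
                   utr5 = na, orf1 = as.integer(one), spacerLen = NA_integer_,
                   orf2 = na, utr3 = na, polyaLen = as.integer(polya),
                   orientation = orient, fullLength = FALSE))
    }
    pick <- pick[order(vapply(pick, function(p) p$start, numeric(1)))]
    orf1 <- c(pick[[1]]$start, pick[[1]]$end)
    orf2 <- c(pick[[2]]$start, pick[[2]]$end)
    # expected ORF lengths from the classifying library entry
    full <- FALSE
    if (nrow(hits)) {
        lib <- as.character(library[[hits$libraryId[1L]]])
        lorfs <- findOrfs(lib, minLen = minOrfLen)
        lorfs <- lorfs[lorfs$strand == "+", , drop = FALSE]
        lorfs <- lorfs[order(-lorfs$length), , drop = FALSE]
        if (nrow(lorfs) >= 2L) {
            expLens <- sort(lorfs$length[1:2])
            gotLens <- sort(c(orf1[2] - orf1[1], orf2[2] - orf2[1]))
            full <- all(gotLens >= 0.9 * expLens)
        }
    }
    new("Line1Annotation",
        tsdLen = call@tsdEnd - call@tsdStart,
        utr5 = c(0L, as.integer(orf1[1])),
        orf1 = as.integer(orf1),
        spacerLen = as.integer(orf2[1] - orf1[2]),
        orf2 = as.integer(orf2),
        utr3 = c(as.integer(orf2[2]), as.integer(L - polya)),
        polyaLen = as.integer(polya),
        orientation = orient, fullLength = full)
}
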