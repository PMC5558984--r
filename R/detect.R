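# Breakpoint detection from the insertion signature described for the
# discovery data: a short interval of doubled read depth (both target-site
# copies of the donor mapping onto the single reference copy) bracketed by
# a right-clip cluster at the TSD end and a left-clip cluster at the TSD
# start. Visual IGV scanning is replaced by thresholded clustering of the
# same evidence.

# per-position majority consensus over clipped tails; right clips share
# their prefix (element 5' start), left clips share their suffix (element
# 3' end), so left-side tails are aligned from their right edge.
.clipConsensus <- function(seqs, align = c("prefix", "suffix")) {
    align <- match.arg(align)
    if (length(seqs) == 1L) return(seqs)
    if (align == "suffix")
        seqs <- vapply(seqs, function(s)
            paste(rev(strsplit(s, "")[[1]]), collapse = ""), "")
    n <- max(nchar(seqs))
    mat <- matrix("", nrow = length(seqs), ncol = n)
    for (i in seq_along(seqs)) {
        ch <- strsplit(seqs[i], "")[[1]]
        mat[i, seq_along(ch)] <- ch
    }
    cons <- apply(mat, 2L, function(col) {
        col <- col[nzchar(col)]
        names(sort(table(col), decreasing = TRUE))[1L]
    })
    out <- paste(cons, collapse = "")
    if (align == "suffix")
        out <- paste(rev(strsplit(out, "")[[1]]), collapse = "")
    out
}

#' Cluster terminal soft-clip events by side and coordinate
#'
#' Events of one side are merged greedily along the coordinate axis
#' (adjacent events within \code{posTol} joined); clusters whose support
#' falls below \code{minSupport} are discarded, and members farther than
#' \code{posTol} from the cluster's modal coordinate are trimmed. The
#' cluster consensus clip is the per-position majority over the member
#' clipped sequences.
#'
#' @param events clip-event data.frame from \code{\link{clipEvents}}.
#' @param minSupport minimum reads per cluster.
#' @param posTol coordinate tolerance in bp (aligner clip placement may
#'   wobble by a base or two).
#' @return data.frame with columns \code{side, refCoord} (modal),
#'   \code{support, consensusClip}.
#' @export
clusterClips <- function(events, minSupport = 3L, posTol = 2L) {
    empty <- data.frame(side = character(), refCoord = integer(),
                        support = integer(), consensusClip = character(),
                        stringsAsFactors = FALSE)
    if (!nrow(events)) return(empty)
    res <- list(empty)
    for (sd in c("left", "right")) {
        ev <- events[events$side == sd, , drop = FALSE]
        if (!nrow(ev)) next
        ev <- ev[order(ev$refCoord), , drop = FALSE]
        grp <- cumsum(c(1L, diff(ev$refCoord) > posTol))
        for (g in unique(grp)) {
            mem <- ev[grp == g, , drop = FALSE]
            tab <- sort(table(mem$refCoord), decreasing = TRUE)
            modal <- as.integer(names(tab)[1L])
            mem <- mem[abs(mem$refCoord - modal) <= posTol, , drop = FALSE]
            if (nrow(mem) < minSupport) next
            res[[length(res) + 1L]] <- data.frame(
                side = sd, refCoord = modal, support = nrow(mem),
                consensusClip = .clipConsensus(
                    mem$clippedSeq,
                    if (sd == "left") "suffix" else "prefix"),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, res)
}

#' Pair clip clusters into candidate insertion calls
#'
#' Geometry contract: reads entering the element from the left flank clip
#' on their right at the TSD \emph{end}; reads exiting into the right flank
#' clip on their left at the TSD \emph{start}. Every (right cluster at e,
#' left cluster at s) pair with \code{s <= e} and \code{e - s <= maxTsd}
#' is a candidate; candidates sharing a cluster are resolved by the highest
#' combined support, then the smallest TSD (deterministic), and the losers
#' are reported via \code{message}.
#'
#' @param clusters cluster data.frame from \code{\link{clusterClips}}.
#' @param maxTsd largest admissible target-site duplication (bp); LINE-1
#'   TSDs are short, and the bound excludes tandem-duplication artifacts.
#' @param refName reference name recorded in the calls.
#' @return list of \code{\linkS4class{InsertionCall}} (TSD sequence and
#'   depth ratio unset until \code{\link{inferTsd}} /
#'   \code{\link{detectInsertions}}).
#' @export
pairBreakpoints <- function(clusters, maxTsd = 50L, refName = "ref") {
    rights <- clusters[clusters$side == "right", , drop = FALSE]
    lefts <- clusters[clusters$side == "left", , drop = FALSE]
    if (!nrow(rights) || !nrow(lefts)) return(list())
    cand <- expand.grid(r = seq_len(nrow(rights)), l = seq_len(nrow(lefts)))
    s <- lefts$refCoord[cand$l]
    e <- rights$refCoord[cand$r]
    keep <- s <= e & e - s <= maxTsd
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) return(list())
    cand$support <- rights$support[cand$r] + lefts$support[cand$l]
    cand$tsd <- rights$refCoord[cand$r] - lefts$refCoord[cand$l]
    cand <- cand[order(-cand$support, cand$tsd, lefts$refCoord[cand$l]), ,
                 drop = FALSE]
    usedR <- logical(nrow(rights)); usedL <- logical(nrow(lefts))
    calls <- list()
    for (i in seq_len(nrow(cand))) {
        ri <- cand$r[i]; li <- cand$l[i]
        if (usedR[ri] || usedL[li]) {
            message(sprintf(
                "dropping overlapping candidate at [%d,%d) (support %d): shares a cluster with a stronger call",
                lefts$refCoord[li], rights$refCoord[ri], cand$support[i]))
            next
        }
        usedR[ri] <- TRUE; usedL[li] <- TRUE
        calls[[length(calls) + 1L]] <- new("InsertionCall",
            refName = refName,
            tsdStart = as.integer(lefts$refCoord[li]),
            tsdEnd = as.integer(rights$refCoord[ri]),
            tsdSeq = "", leftSupport = as.integer(lefts$support[li]),
            rightSupport = as.integer(rights$support[ri]),
            depthRatio = NA_real_,
            clipTails = c(fivePrime = rights$consensusClip[ri],
                          threePrime = lefts$consensusClip[li]))
    }
    calls
}

#' Read the target-site-duplication sequence off the reference
#'
#' @param reference reference window (\code{DNAStringSet} or character).
#' @param call an \code{\linkS4class{InsertionCall}}.
#' @return the call with \code{tsdSeq} filled in (the reference slice
#'   \code{[tsdStart, tsdEnd)}; empty for a blunt insertion).
#' @export
inferTsd <- function(reference, call) {
    ref <- as.character(reference)[[1]]
    if (call@tsdStart < 0L || call@tsdEnd > nchar(ref))
        stop("call coordinates outside the reference")
    call@tsdSeq <- substr(ref, call@tsdStart + 1L, call@tsdEnd)
    call
}

#' Detect mobile-element insertions from aligned reads
#'
#' The full detection composition: terminal soft-clip extraction, clip
#' clustering, breakpoint pairing, TSD inference, and a depth-ratio
#' annotation (median depth over the TSD divided by the median flanking
#' depth over +/- \code{flank} bp, excluding the TSD). Read order is
#' irrelevant; events are sorted internally.
#'
#' @param reads aligned read data.frame (see \code{\link{readSam}}).
#' @param reference reference window.
#' @param minClipLen,minSupport,posTol,maxTsd detector thresholds.
#' @param flank flank width for the depth ratio.
#' @param refName reference sequence name; defaults to the name of
#'   \code{reference}.
#' @return list of \code{\linkS4class{InsertionCall}}.
#' @export
detectInsertions <- function(reads, reference, minClipLen = 5L,
                             minSupport = 3L, posTol = 2L, maxTsd = 50L,
                             flank = 500L, refName = NULL) {
    if (is.null(refName)) {
        refName <- names(as.character(reference))[1]
        if (is.null(refName) || is.na(refName)) refName <- "ref"
    }
    ev <- clipEvents(reads, minClipLen = minClipLen)
    cl <- clusterClips(ev, minSupport = minSupport, posTol = posTol)
    calls <- pairBreakpoints(cl, maxTsd = maxTsd, refName = refName)
    reflen <- nchar(as.character(reference)[[1]])
    lapply(calls, function(call) {
        call <- inferTsd(reference, call)
        lo <- max(0L, call@tsdStart - flank)
        hi <- min(reflen, call@tsdEnd + flank)
        tr <- pileup(reads, refName, c(lo, hi))
        d <- depth(tr)
        idx <- seq.int(lo, hi - 1L)
        inTsd <- idx >= call@tsdStart & idx < call@tsdEnd
        flankMed <- stats::median(d[!inTsd])
        tsdMed <- if (any(inTsd)) stats::median(d[inTsd]) else NA_real_
        call@depthRatio <- if (!is.na(tsdMed) && flankMed > 0)
            tsdMed / flankMed else NA_real_
        call
    })
}

#' Serialize insertion calls as symbolic VCF records
#'
#' Calls are emitted as \code{<INS:ME:LINE1>} records with INFO keys
#' \code{TSD} (the duplicated sequence) and \code{SVLEN} (\code{"."} when
#' the element length is still unknown at detection time).
#'
#' @param calls list of \code{\linkS4class{InsertionCall}}.
#' @param reference reference window (for the REF base at the breakpoint).
#' @param svlen optional known element length(s).
#' @return a VariantRecord data.frame (see \code{\link{readVcfRecords}}).
#' @export
callsToVcf <- function(calls, reference, svlen = NULL) {
    ref <- as.character(reference)[[1]]
    n <- length(calls)
    sv <- if (is.null(svlen)) rep(".", n) else as.character(svlen)
    out <- data.frame(
        chrom = vapply(calls, function(x) x@refName, ""),
        pos = vapply(calls, function(x) x@tsdStart, 0L) + 1L,
        id = sprintf("MEI_%d", seq_len(max(n, 0L))),
        ref = vapply(calls, function(x)
            substr(ref, x@tsdStart + 1L, x@tsdStart + 1L), ""),
        alt = rep("<INS:ME:LINE1>", n),
        qual = rep(".", n), filter = rep("PASS", n),
        info = vapply(seq_len(n), function(i) sprintf(
            "SVLEN=%s;TSD=%s;MEINFO=LINE1,1,%s,+", sv[i],
            if (nzchar(calls[[i]]@tsdSeq)) calls[[i]]@tsdSeq else ".",
            sv[i]), ""),
        stringsAsFactors = FALSE)
    attr(out, "samples") <- character()
    attr(out, "gt") <- matrix(character(), nrow = n, ncol = 0L)
    out
}

#' Case-exclusive homozygous variant screen over a region
#'
#' Keeps the variants at which every case is homozygous for one allele and
#' every control homozygous for a different allele; any missing genotype
#' among the compared samples drops the site.
#'
#' @param variants VariantRecord data.frame with genotypes (see
#'   \code{\link{readVcfRecords}}).
#' @param caseIds,controlIds sample names to compare.
#' @return the retained subset of \code{variants} (genotype matrix
#'   re-attached).
#' @export
prioritizeRegionVariants <- function(variants, caseIds, controlIds) {
    if (!length(caseIds) || !length(controlIds))
        stop("caseIds and controlIds must be non-empty")
    gt <- attr(variants, "gt")
    samples <- attr(variants, "samples")
    miss <- setdiff(c(caseIds, controlIds), samples)
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    homAllele <- function(g) {
        if (is.na(g)) return(NA_character_)
        a <- strsplit(g, "[/|]")[[1]]
        if (length(a) == 2L && a[1L] == a[2L] && a[1L] != ".") a[1L]
        else NA_character_
    }
    keep <- vapply(seq_len(nrow(variants)), function(i) {
        ca <- vapply(gt[i, caseIds], homAllele, "")
        co <- vapply(gt[i, controlIds], homAllele, "")
        if (anyNA(ca) || anyNA(co)) return(FALSE)
        length(unique(ca)) == 1L && length(unique(co)) == 1L &&
            ca[1L] != co[1L]
    }, logical(1))
    out <- variants[keep, , drop = FALSE]
    attr(out, "samples") <- samples
    attr(out, "gt") <- gt[keep, , drop = FALSE]
    out
}
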