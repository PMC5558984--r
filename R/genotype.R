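# In-silico genotyping at a detected insertion locus: the wet-lab
# three-primer competitive assay is replaced by counting reads that
# support the reference allele (clean spanning alignments) versus the
# insertion allele (breakpoint-clipped reads). Genotype categories and
# their downstream use are identical to a fragment-analysis assay.

#' Count reference- and insertion-supporting reads at a call
#'
#' A read supports the reference allele when its alignment covers the TSD
#' with \code{pad} bp to spare on both sides and carries no terminal soft
#' clip of 5+ bp; it supports the insertion when it is soft-clipped within
#' \code{posTol} bp of either breakpoint (left clips at the TSD start,
#' right clips at the TSD end). No read is counted twice; reads qualifying
#' as neither are ignored. Unmapped mate evidence can be added with
#' \code{includeMateEvidence}, but is off by default since clip counts
#' alone keep the heterozygote allele balance near 1:1.
#'
#' @param reads one individual's aligned reads.
#' @param call an \code{\linkS4class{InsertionCall}}.
#' @param posTol breakpoint tolerance (bp).
#' @param pad required spanning margin around the TSD (bp).
#' @param minClipLen clip length threshold.
#' @param includeMateEvidence also count unmapped reads whose mates map
#'   within 1 kb of the call as insertion support.
#' @param anchorMin smallest aligned anchor a mapper places (bounds the
#'   clip-capture window; used only for the window-width correction).
#' @return list with \code{refReads}, \code{insReads}, \code{total}, and
#'   \code{insDosage}: the window-corrected insertion allele balance. The
#'   two read classes are captured by windows of different widths (a clip
#'   at either breakpoint versus a clean spanning alignment), so the raw
#'   fraction is biased away from dose/2; dividing each count by its
#'   capture width makes the expected balance 0, 1/2 and 1 for the three
#'   genotypes.
#' @export
countAlleleSupport <- function(reads, call, posTol = 2L, pad = 5L,
                               minClipLen = 5L, includeMateEvidence = FALSE,
                               anchorMin = 20L) {
    if (!nrow(reads))
        return(list(refReads = 0L, insReads = 0L, total = 0L,
                    insDosage = NA_real_))
    mp <- reads$mapped & !is.na(reads$pos0)
    r <- reads[mp, , drop = FALSE]
    ins <- character()
    refN <- 0L
    if (nrow(r)) {
        cl <- .terminalClips(r$cigar)
        rl <- .refLenFast(r$cigar)
        spans <- r$pos0 <= call@tsdStart - pad &
                 r$pos0 + rl >= call@tsdEnd + pad
        clean <- cl$left < minClipLen & cl$right < minClipLen
        refN <- sum(spans & clean)
        hitL <- cl$left >= minClipLen &
            abs(r$pos0 - call@tsdStart) <= posTol
        hitR <- cl$right >= minClipLen &
            abs(r$pos0 + rl - call@tsdEnd) <= posTol
        ins <- unique(r$qname[hitL | hitR])
    }
    if (includeMateEvidence) {
        un <- reads[!reads$mapped, , drop = FALSE]
        near <- !is.na(un$pnext0) &
            un$pnext0 >= call@tsdStart - 1000L &
            un$pnext0 <= call@tsdEnd + 1000L
        ins <- unique(c(ins, un$qname[near]))
    }
    insN <- length(ins)
    L <- stats::median(nchar(reads$seq))
    tsdLen <- call@tsdEnd - call@tsdStart
    wIns <- 2 * max(1L, L - minClipLen - anchorMin + 1L)
    wRef <- max(1L, L - (tsdLen + 2L * pad) + 1L)
    iN <- insN / wIns; rN <- refN / wRef
    list(refReads = as.integer(refN), insReads = as.integer(insN),
         total = as.integer(refN + insN),
         insDosage = if (insN + refN > 0L) iN / (iN + rN) else NA_real_)
}

#' Threshold allele support into a genotype call
#'
#' \code{NOCALL} below \code{minDepth} total informative reads; otherwise
#' the insertion allele balance (window-corrected \code{insDosage} when
#' available, else the raw insertion-read fraction) is thresholded by
#' \code{hetBand}: below the band is \code{WT}, above it \code{HOM},
#' inside it \code{HET}.
#'
#' @param support output of \code{\link{countAlleleSupport}}.
#' @param minDepth minimum informative reads for a call.
#' @param hetBand numeric \code{c(lo, hi)} with \code{0 < lo < hi < 1}.
#' @return list with \code{genotype}, \code{insFraction} (raw), the
#'   balance used for the call, and the support counts.
#' @export
callGenotype <- function(support, minDepth = 8L, hetBand = c(0.2, 0.8)) {
    if (length(hetBand) != 2L || hetBand[1L] <= 0 || hetBand[2L] >= 1 ||
        hetBand[1L] >= hetBand[2L])
        stop("hetBand must satisfy 0 < lo < hi < 1")
    tot <- support$total
    frac <- if (tot > 0L) support$insReads / tot else NA_real_
    bal <- if (!is.null(support$insDosage) && !is.na(support$insDosage))
        support$insDosage else frac
    geno <- if (tot < minDepth) "NOCALL"
        else if (bal < hetBand[1L]) "WT"
        else if (bal > hetBand[2L]) "HOM"
        else "HET"
    list(genotype = geno, insFraction = frac, balance = bal,
         refReads = support$refReads, insReads = support$insReads,
         total = tot)
}

#' Genotype a cohort at an insertion call
#'
#' Calls each individual from its read support and aggregates the calls
#' into a 2x3 case/control genotype table. NOCALL individuals are excluded
#' from the table (exclusion count reported, never imputed).
#'
#' @param readsList named list of per-individual read data.frames.
#' @param call the \code{\linkS4class{InsertionCall}} to genotype at.
#' @param phenotypes data.frame with columns \code{id} and \code{phenotype}
#'   (\code{"case"}/\code{"control"}), e.g. from
#'   \code{\link{simulateCohort}}.
#' @param minDepth,hetBand,posTol see \code{\link{callGenotype}} and
#'   \code{\link{countAlleleSupport}}.
#' @param study,marker labels for the aggregated table.
#' @return list with \code{calls} (per-individual data.frame),
#'   \code{table} (a \code{\linkS4class{GenotypeTable}}), and
#'   \code{nExcluded}.
#' @export
genotypeCohort <- function(readsList, call, phenotypes, minDepth = 8L,
                           hetBand = c(0.2, 0.8), posTol = 2L,
                           study = "sim", marker = "L1") {
    ids <- names(readsList)
    if (is.null(ids)) stop("readsList must be named by individual id")
    calls <- do.call(rbind, lapply(ids, function(id) {
        g <- callGenotype(countAlleleSupport(readsList[[id]], call,
                                             posTol = posTol),
                          minDepth = minDepth, hetBand = hetBand)
        data.frame(id = id, genotype = g$genotype, refReads = g$refReads,
                   insReads = g$insReads, insFraction = g$insFraction,
                   stringsAsFactors = FALSE)
    }))
    calls <- merge(calls, phenotypes[, c("id", "phenotype")], by = "id",
                   sort = TRUE)
    usable <- calls$genotype != "NOCALL"
    nEx <- sum(!usable)
    if (!any(usable))
        stop("no individual could be genotyped (all NOCALL)")
    if (nEx)
        message(nEx, " individual(s) excluded as NOCALL")
    cnt <- function(ph) vapply(c("WT", "HET", "HOM"), function(g)
        sum(usable & calls$phenotype == ph & calls$genotype == g), integer(1))
    list(calls = calls,
         table = genotypeTable(cnt("case"), cnt("control"), study = study,
                               marker = marker),
         nExcluded = nEx)
}

#' Predict diagnostic amplicon sizes across an insertion
#'
#' Locates a primer pair on the wild-type template (forward primer on the
#' plus strand, reverse primer as its reverse complement) and reports the
#' wild-type product size and the insertion-allele product size
#' (\code{wt + elementLen + tsdLen}).
#'
#' @param template wild-type template sequence spanning both primer sites.
#' @param primerFwd,primerRev primer sequences, 5'->3' on their own strands.
#' @param elementLen,tsdLen inserted element and target-site-duplication
#'   lengths (bp).
#' @return list with \code{wtSize} and \code{insSize}.
#' @export
predictAmplicons <- function(template, primerFwd, primerRev, elementLen,
                             tsdLen) {
    tmpl <- toupper(as.character(template)[[1]])
    findOnce <- function(pat, label) {
        m <- gregexpr(pat, tmpl, fixed = TRUE)[[1]]
        if (m[1L] == -1L) stop(label, " primer site not found on the template")
        if (length(m) > 1L) stop(label, " primer site is not unique")
        m[1L]
    }
    fStart <- findOnce(toupper(primerFwd), "forward")
    rcRev <- .revcomp(toupper(primerRev))
    rStart <- findOnce(rcRev, "reverse")
    wt <- (rStart + nchar(rcRev) - 1L) - fStart + 1L
    if (wt <= 0L) stop("primer sites are in the wrong orientation")
    list(wtSize = as.integer(wt),
         insSize = as.integer(wt + elementLen + tsdLen))
}
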