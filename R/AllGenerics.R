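#' @rdname PileupTrack-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("depth", function(x) standardGeneric("depth"))

#' @rdname PileupTrack-class
#' @export
setGeneric("refName", function(x) standardGeneric("refName"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("studyLabel", function(x) standardGeneric("studyLabel"))

#' @rdname InsertionCall-class
#' @export
setGeneric("tsdStart", function(x) standardGeneric("tsdStart"))

#' @rdname InsertionCall-class
#' @export
setGeneric("tsdEnd", function(x) standardGeneric("tsdEnd"))

#' @rdname InsertionCall-class
#' @export
setGeneric("tsdSeq", function(x) standardGeneric("tsdSeq"))

#' @rdname InsertionCall-class
#' @export
setGeneric("tsdLength", function(x) standardGeneric("tsdLength"))

#' @rdname AssembledContig-class
#' @export
setGeneric("contigSeq", function(x) standardGeneric("contigSeq"))

#' @rdname Line1Annotation-class
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname AssociationResult-class
#' @export
setGeneric("exactP", function(x) standardGeneric("exactP"))

#' @rdname AssociationResult-class
#' @export
setGeneric("orPerAllele", function(x) standardGeneric("orPerAllele"))

# ---- accessors -------------------------------------------------------------

#' @rdname PileupTrack-class
#' @export
setMethod("depth", "PileupTrack", function(x) x@depth)

#' @rdname PileupTrack-class
#' @export
setMethod("refName", "PileupTrack", function(x) x@refName)

#' @rdname GenotypeTable-class
#' @export
setMethod("genotypeCounts", "GenotypeTable", function(x) x@counts)

#' @rdname GenotypeTable-class
#' @export
setMethod("studyLabel", "GenotypeTable", function(x) x@study)

#' @rdname InsertionCall-class
#' @export
setMethod("tsdStart", "InsertionCall", function(x) x@tsdStart)

#' @rdname InsertionCall-class
#' @export
setMethod("tsdEnd", "InsertionCall", function(x) x@tsdEnd)

#' @rdname InsertionCall-class
#' @export
setMethod("tsdSeq", "InsertionCall", function(x) x@tsdSeq)

#' @rdname InsertionCall-class
#' @export
setMethod("tsdLength", "InsertionCall", function(x) x@tsdEnd - x@tsdStart)

#' @rdname AssembledContig-class
#' @export
setMethod("contigSeq", "AssembledContig", function(x) x@sequence)

#' @rdname Line1Annotation-class
#' @export
setMethod("orientation", "Line1Annotation", function(x) x@orientation)

#' @rdname AssociationResult-class
#' @export
setMethod("exactP", "AssociationResult", function(x) x@exactP)

#' @rdname AssociationResult-class
#' @export
setMethod("orPerAllele", "AssociationResult", function(x) x@orPerAllele)

# ---- show ------------------------------------------------------------------

setMethod("show", "PileupTrack", function(object) {
    cat(sprintf("PileupTrack on %s [%d, %d): median depth %g\n",
        object@refName, object@start, object@start + length(object@depth),
        stats::median(object@depth)))
})

setMethod("show", "GenotypeTable", function(object) {
    cat(sprintf("GenotypeTable '%s' (%s)\n", object@study, object@marker))
    print(object@counts)
})

setMethod("show", "InsertionCall", function(object) {
    cat(sprintf(
        "InsertionCall %s:[%d,%d) TSD %d bp '%s'\n  support left/right %d/%d, depth ratio %.2f\n",
        object@refName, object@tsdStart, object@tsdEnd,
        object@tsdEnd - object@tsdStart, object@tsdSeq,
        object@leftSupport, object@rightSupport, object@depthRatio))
})

setMethod("show", "AssembledContig", function(object) {
    cat(sprintf("AssembledContig: %d bp from %d reads (%s)\n",
        nchar(object@sequence), object@nReadsUsed, object@terminatedBy))
})

setMethod("show", "Line1Annotation", function(object) {
    spanlen <- function(sp) if (anyNA(sp)) NA_integer_ else sp[2L] - sp[1L]
    cat("Line1Annotation\n")
    cat(sprintf("  TSD      %4d bp\n", object@tsdLen))
    cat(sprintf("  5'UTR    %4d bp\n", spanlen(object@utr5)))
    cat(sprintf("  ORF1     %4d bp\n", spanlen(object@orf1)))
    cat(sprintf("  spacer   %4d bp\n", object@spacerLen))
    cat(sprintf("  ORF2     %4d bp\n", spanlen(object@orf2)))
    cat(sprintf("  3'UTR    %4d bp\n", spanlen(object@utr3)))
    cat(sprintf("  poly-A  >=%3d bp\n", object@polyaLen))
    cat(sprintf("  orientation %s, full length: %s\n",
        object@orientation, object@fullLength))
})

setMethod("show", "AssociationResult", function(object) {
    cat("AssociationResult for studies:", paste(object@studies, collapse = ", "), "\n")
    if (length(object@exactP)) {
        cat("  exact (Freeman-Halton) P:\n")
        for (n in names(object@exactP))
            cat(sprintf("    %-8s %.3g\n", n, object@exactP[[n]]))
    }
    cat(sprintf("  per-allele OR %.2f (95%% CI %.2f-%.2f), Wald P %.3g, LRT-vs-null P %.3g\n",
        object@orPerAllele, object@ciLo, object@ciHi, object@waldP,
        object@lrtNullP))
    cat(sprintf("  model shape LRT (general vs per-allele): chi2 %.2f, df %d, P %.3g\n",
        object@lrtStat, object@lrtDf, object@lrtP))
    cc <- object@concordance
    if (length(cc))
        cat(sprintf("  concordance: %d/%d homozygotes affected; %.0f%% of cases and %.0f%% of controls discordant\n",
            cc$homAffected, cc$homTotal, cc$pctCasesDiscordant,
            cc$pctControlsDiscordant))
})
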