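#' @import methods
#' @importFrom stats median pchisq pnorm rbinom rnorm runif setNames var
#' @importFrom utils head read.delim write.table
NULL

#' PileupTrack: per-base read depth over a reference interval
#'
#' Holds the read depth for every base of a queried interval, computed from
#' the reference-consuming CIGAR operations of a set of aligned reads.
#' Coordinates are 0-based half-open, as everywhere inside this package.
#'
#' @slot refName name of the reference sequence the track was computed on.
#' @slot start 0-based start of the interval.
#' @slot depth integer vector, one cell per reference base.
#' @export
setClass("PileupTrack",
    representation(refName = "character", start = "integer",
                   depth = "integer"))

setValidity("PileupTrack", function(object) {
    if (length(object@refName) != 1L) return("refName must be length 1")
    if (any(object@depth < 0L)) return("depths must be >= 0")
    TRUE
})

#' GenotypeTable: a 2x3 case/control by genotype count table
#'
#' The unit of analysis of the association battery: counts of cases and
#' controls in the three diploid genotype classes (wild-type, heterozygote,
#' homozygote for the insertion or risk allele).
#'
#' @slot counts 2x3 integer matrix; rows \code{case}, \code{control},
#'   columns \code{WT}, \code{HET}, \code{HOM}.
#' @slot study study label (e.g. cohort of origin).
#' @slot marker name of the variant the genotypes refer to.
#' @export
setClass("GenotypeTable",
    representation(counts = "matrix", study = "character",
                   marker = "character"))

setValidity("GenotypeTable", function(object) {
    m <- object@counts
    if (!all(dim(m) == c(2L, 3L))) return("counts must be 2x3")
    if (any(m < 0) || any(m != round(m))) return("counts must be non-negative integers")
    if (sum(m) == 0) return("table is empty")
    if (!identical(rownames(m), c("case", "control")))
        return("rows must be named case, control")
    if (!identical(colnames(m), c("WT", "HET", "HOM")))
        return("columns must be named WT, HET, HOM")
    TRUE
})

#' InsertionCall: a candidate mobile-element insertion locus
#'
#' A breakpoint pair inferred from bilateral soft-clip clusters, bracketing
#' the (possibly empty) target site duplication, together with its read
#' support and depth evidence.
#'
#' @slot refName reference sequence name.
#' @slot tsdStart,tsdEnd 0-based half-open bounds of the duplicated target
#'   site (equal for a blunt insertion).
#' @slot tsdSeq target-site sequence taken from the reference.
#' @slot leftSupport,rightSupport supporting read counts of the left-clip
#'   and right-clip clusters.
#' @slot depthRatio read depth over the TSD divided by the median flanking
#'   depth (about 2 for a homozygous carrier, since both target-site copies
#'   of the donor map onto the single reference copy).
#' @slot clipTails named character vector: \code{fivePrime} (consensus of
#'   right-clipped tails, the start of the inserted element) and
#'   \code{threePrime} (consensus of left-clipped tails, its end).
#' @export
setClass("InsertionCall",
    representation(refName = "character", tsdStart = "integer",
                   tsdEnd = "integer", tsdSeq = "character",
                   leftSupport = "integer", rightSupport = "integer",
                   depthRatio = "numeric", clipTails = "character"))

setValidity("InsertionCall", function(object) {
    if (object@tsdEnd < object@tsdStart) return("tsdEnd < tsdStart")
    if (!is.na(object@tsdSeq) && nzchar(object@tsdSeq) &&
        nchar(object@tsdSeq) != object@tsdEnd - object@tsdStart)
        return("tsdSeq length disagrees with breakpoints")
    TRUE
})

#' AssembledContig: result of greedy overlap consensus assembly
#'
#' @slot sequence assembled sequence (character).
#' @slot nReadsUsed number of reads merged into the contig.
#' @slot terminatedBy why extension stopped: \code{"polyA-run"} when the
#'   growing 3' end entered a homopolymer A-run (the element's poly-A tail),
#'   else \code{"read-exhaustion"}.
#' @export
setClass("AssembledContig",
    representation(sequence = "character", nReadsUsed = "integer",
                   terminatedBy = "character"))

setValidity("AssembledContig", function(object) {
    if (!nzchar(object@sequence)) return("contig is empty")
    if (!object@terminatedBy %in% c("polyA-run", "read-exhaustion"))
        return("unknown termination cause")
    TRUE
})

#' Line1Annotation: structural decomposition of an assembled LINE-1 allele
#'
#' Segment layout of a full-length LINE-1: 5'UTR, ORF1, intergenic spacer,
#' ORF2, 3'UTR and poly-A tail, plus the target-site-duplication length and
#' the element's orientation relative to the host gene. Spans are 0-based
#' half-open on the contig in element orientation; absent segments are NA.
#'
#' @slot tsdLen length of the target site duplication (bp).
#' @slot utr5,orf1,orf2,utr3 integer start/end pairs.
#' @slot spacerLen gap between ORF1 stop and ORF2 start (bp).
#' @slot polyaLen length of the terminal A-run; a lower bound when assembly
#'   terminated inside the tail.
#' @slot orientation \code{"+"} if the element runs in the same direction as
#'   the host gene, else \code{"-"}.
#' @slot fullLength TRUE when both ORFs are present at >= 90\% of the length
#'   expected from the classifying repeat consensus.
#' @export
setClass("Line1Annotation",
    representation(tsdLen = "integer", utr5 = "integer", orf1 = "integer",
                   spacerLen = "integer", orf2 = "integer", utr3 = "integer",
                   polyaLen = "integer", orientation = "character",
                   fullLength = "logical"))

setValidity("Line1Annotation", function(object) {
    if (!object@orientation %in% c("+", "-")) return("orientation must be +/-")
    for (s in c("utr5", "orf1", "orf2", "utr3")) {
        sp <- slot(object, s)
        if (length(sp) != 2L) return(sprintf("%s must be a start/end pair", s))
        if (!anyNA(sp) && sp[2L] < sp[1L]) return(sprintf("%s end < start", s))
    }
    TRUE
})

#' AssociationResult: the association battery for one or more study sets
#'
#' @slot studies study labels the result was computed from.
#' @slot exactP named vector of two-sided Freeman-Halton exact P-values, one
#'   per study table, plus \code{"pooled"} when more than one study entered.
#' @slot orPerAllele odds ratio per copy of the insertion allele from the
#'   study-adjusted per-allele logistic model.
#' @slot ciLo,ciHi 95\% Wald confidence bounds for the odds ratio.
#' @slot waldP Wald P-value of the per-allele coefficient.
#' @slot lrtNullP likelihood-ratio P of the per-allele model against the
#'   study-only null (1 df).
#' @slot lrtStat,lrtDf,lrtP likelihood-ratio test of the general (genotypic)
#'   model against the per-allele model; small P indicates a non-additive
#'   (e.g. recessive) shape.
#' @slot concordance list with discordance percentages and the penetrance
#'   fraction among homozygotes (see \code{\link{concordanceSummary}}).
#' @export
setClass("AssociationResult",
    representation(studies = "character", exactP = "numeric",
                   orPerAllele = "numeric", ciLo = "numeric",
                   ciHi = "numeric", waldP = "numeric", lrtNullP = "numeric",
                   lrtStat = "numeric", lrtDf = "integer", lrtP = "numeric",
                   concordance = "list"))

setValidity("AssociationResult", function(object) {
    if (!is.na(object@orPerAllele) &&
        (object@ciLo > object@orPerAllele || object@ciHi < object@orPerAllele))
        return("confidence interval does not bracket the odds ratio")
    if (!is.na(object@lrtStat) && object@lrtStat < -1e-8)
        return("negative LRT statistic")
    TRUE
})
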