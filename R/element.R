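# Synthetic full-length LINE-1 element. The default layout mirrors the
# structure of the canine element recovered in the retinopathy study:
# 6,401 bp total with a 900 bp ORF1, a 49 bp intergenic spacer, a 3,828 bp
# ORF2 and a terminal poly-A run; the 15 bp target site duplication is
# added when the element is planted into a reference, not here.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Parameterise a synthetic LINE-1 element
#'
#' The 3'UTR is the residual: \code{totalLen - (utr5 + orf1 + spacer + orf2
#' + polyA)}; it must be non-negative. ORF lengths include the stop codon,
#' must be divisible by 3 and leave room for start + stop (>= 9 bp).
#'
#' @param totalLen total element length in bp.
#' @param tsdLen target-site-duplication length used when planting.
#' @param utr5Len,orf1Len,spacerLen,orf2Len,polyaLen segment lengths in bp.
#' @param orientation element orientation relative to the host gene.
#' @return a validated list of class \code{"ElementModel"}.
#' @export
elementModel <- function(totalLen = 6401L, tsdLen = 15L, utr5Len = 1300L,
                         orf1Len = 900L, spacerLen = 49L, orf2Len = 3828L,
                         polyaLen = 30L, orientation = "+") {
    m <- list(totalLen = as.integer(totalLen), tsdLen = as.integer(tsdLen),
              utr5Len = as.integer(utr5Len), orf1Len = as.integer(orf1Len),
              spacerLen = as.integer(spacerLen), orf2Len = as.integer(orf2Len),
              polyaLen = as.integer(polyaLen), orientation = orientation)
    m$utr3Len <- m$totalLen - (m$utr5Len + m$orf1Len + m$spacerLen +
                               m$orf2Len + m$polyaLen)
    if (m$utr3Len < 0L)
        stop(sprintf(paste0(
            "inconsistent element lengths: utr5 (%d) + orf1 (%d) + spacer ",
            "(%d) + orf2 (%d) + polyA (%d) = %d exceeds totalLen (%d)"),
            m$utr5Len, m$orf1Len, m$spacerLen, m$orf2Len, m$polyaLen,
            m$totalLen - m$utr3Len, m$totalLen))
    for (f in c("orf1Len", "orf2Len")) {
        if (m[[f]] %% 3L != 0L)
            stop(f, " must be divisible by 3")
        if (m[[f]] < 9L)
            stop(f, " leaves no room for a start and a stop codon")
    }
    if (!orientation %in% c("+", "-")) stop("orientation must be '+' or '-'")
    if (m$tsdLen < 0L) stop("tsdLen must be >= 0")
    class(m) <- "ElementModel"
    m
}

# Random DNA without long A-homopolymers (maxARun caps the run length so
# the genuine poly-A tail stays unambiguous for the assembler/detector).
.randDna <- function(n, maxARun = 9L) {
    if (n == 0L) return("")
    x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    repeat {
        r <- rle(x)
        bad <- which(r$values == "A" & r$lengths > maxARun)
        if (!length(bad)) break
        ends <- cumsum(r$lengths)
        for (b in bad) {
            pos <- (ends[b] - r$lengths[b] + 1L):ends[b]
            fix <- pos[seq.int(maxARun + 1L, length(pos), by = maxARun + 1L)]
            x[fix] <- sample(c("C", "G", "T"), length(fix), replace = TRUE)
        }
    }
    paste(x, collapse = "")
}

# A genuine ORF of exactly `len` bp: ATG, internally stop-free codons with
# no AAA codons adjacent (keeps A-runs short), terminal stop.
.randOrf <- function(len) {
    stopifnot(len %% 3L == 0L, len >= 9L)
    nCodon <- len %/% 3L - 2L
    bases <- c("A", "C", "G", "T")
    all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    sense <- setdiff(all64, c(.STOP_CODONS, "AAA"))
    body <- sample(sense, nCodon, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), sample(.STOP_CODONS, 1L))
}

#' Build a synthetic full-length LINE-1 sequence
#'
#' Generates a sequence of exactly \code{model$totalLen} bp laid out as
#' 5'UTR, ORF1, spacer, ORF2, 3'UTR, poly-A tail. Both ORFs start with ATG,
#' end with a stop codon and are internally stop-free; an in-frame stop is
#' placed immediately upstream of each ORF so that open-reading-frame
#' scanning recovers the planted spans exactly. Draws are rejected until
#' \code{\link{findOrfs}} confirms the two longest forward-strand ORFs are
#' the planted ones and no spurious A-run of 10+ bp exists outside the
#' tail.
#'
#' @param model an \code{\link{elementModel}}.
#' @param seed integer RNG seed (mandatory: the element is part of the
#'   simulation truth).
#' @return a \code{DNAStringSet} of length 1 named \code{"LINE1_synthetic"}
#'   with the segment layout in \code{S4Vectors::metadata()$layout}
#'   (0-based half-open spans).
#' @export
makeElement <- function(model = elementModel(), seed) {
    stopifnot(inherits(model, "ElementModel"), !missing(seed))
    for (try in 1:100) {
        set.seed(.deriveSeed(seed, 7000L + try))
        utr5 <- .randDna(model$utr5Len)
        # last 3 bases of utr5 in-frame with ORF1: force a stop there so the
        # ORF cannot be extended to an upstream ATG
        if (model$utr5Len >= 3L)
            utr5 <- paste0(substr(utr5, 1L, model$utr5Len - 3L), "TAA")
        orf1 <- .randOrf(model$orf1Len)
        spacer <- .randDna(model$spacerLen)
        if (model$spacerLen >= 3L)
            spacer <- paste0(substr(spacer, 1L, model$spacerLen - 3L), "TAA")
        orf2 <- .randOrf(model$orf2Len)
        utr3 <- .randDna(model$utr3Len)
        seqc <- paste0(utr5, orf1, spacer, orf2, utr3,
                       strrep("A", model$polyaLen))
        stopifnot(nchar(seqc) == model$totalLen)
        # self-consistency: the annotator must see exactly the planted ORFs
        orfs <- findOrfs(seqc, minLen = 300L)
        fwd <- orfs[orfs$strand == "+", , drop = FALSE]
        fwd <- fwd[order(-fwd$length), , drop = FALSE]
        o1s <- model$utr5Len
        o2s <- model$utr5Len + model$orf1Len + model$spacerLen
        wanted <- nrow(fwd) >= 2L &&
            setequal(paste(fwd$start[1:2], fwd$length[1:2]),
                     paste(c(o2s, o1s), c(model$orf2Len, model$orf1Len)))
        body <- substr(seqc, 1L, model$totalLen - model$polyaLen)
        cleanA <- !grepl("AAAAAAAAAA", body, fixed = TRUE)
        if (wanted && cleanA) {
            out <- Biostrings::DNAStringSet(setNames(seqc, "LINE1_synthetic"))
            S4Vectors::metadata(out)$layout <- data.frame(
                segment = c("utr5", "orf1", "spacer", "orf2", "utr3", "polyA"),
                start = c(0L, o1s, o1s + model$orf1Len, o2s,
                          o2s + model$orf2Len,
                          model$totalLen - model$polyaLen),
                end = c(o1s, o1s + model$orf1Len, o2s, o2s + model$orf2Len,
                        model$totalLen - model$polyaLen, model$totalLen),
                stringsAsFactors = FALSE)
            S4Vectors::metadata(out)$model <- model
            return(out)
        }
    }
    stop("failed to draw an element satisfying the ORF layout; ",
         "check the model segment lengths")
}

# reverse complement for plain character strings
.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
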