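# Cohort and read simulation. The generator emulates the study conditions
# of the discovery data set: a reference window containing a gene intron, a
# full-length LINE-1 planted with a 15 bp target site duplication, diploid
# individuals drawn at a configurable insertion-allele frequency with a
# recessive, incompletely penetrant phenotype, and 100 bp paired-end reads
# at ~21x depth whose truth alignments to the *reference* (not the donor)
# are written by construction -- no external aligner is involved.

#' Simulate a reference window
#'
#' Uniform-random DNA with no A-homopolymer of 10+ bp, so that the genuine
#' poly-A tail of a planted element cannot be confounded.
#'
#' @param windowLen window length in bp (>= 2 kb).
#' @param seed RNG seed.
#' @param name sequence id.
#' @return a \code{DNAStringSet} of length 1.
#' @export
makeReference <- function(windowLen = 20000L, seed, name = "refwin") {
    stopifnot(!missing(seed))
    if (windowLen < 2000L) stop("windowLen must be >= 2 kb")
    set.seed(.deriveSeed(seed, 1L))
    Biostrings::DNAStringSet(setNames(.randDna(as.integer(windowLen)), name))
}

#' Plant an element with a target site duplication into a reference
#'
#' The donor haplotype is \code{flank + TSD + element + TSD + flank}: the
#' target site \code{reference[site, site + tsdLen)} appears on both sides
#' of the inserted element, so the donor exceeds the reference by
#' \code{elementLen + tsdLen} bp.
#'
#' @param reference reference window (\code{DNAStringSet} of length 1 or
#'   character).
#' @param element element sequence (same types).
#' @param site 0-based position of the target site start.
#' @param tsdLen target-site-duplication length (0 gives a blunt insertion).
#' @param edgeMargin minimum distance of \code{site} from either window
#'   edge; defaults to read length + mean insert size so that every
#'   junction can be spanned by simulated fragments.
#' @return list with \code{donor} (\code{DNAStringSet}), and the truth
#'   fields \code{leftBp}, \code{rightBp} (0-based TSD bounds on the
#'   reference), \code{tsdSeq}, \code{elementLen}, \code{site}.
#' @export
plantInsertion <- function(reference, element, site, tsdLen = 15L,
                           edgeMargin = 450L) {
    ref <- as.character(reference)[[1]]
    ele <- as.character(element)[[1]]
    site <- as.integer(site); tsdLen <- as.integer(tsdLen)
    if (site + tsdLen > nchar(ref)) stop("site + tsdLen exceeds the reference")
    if (site < edgeMargin || site > nchar(ref) - edgeMargin)
        stop(sprintf("site %d is closer than %d bp to a window edge", site,
                     edgeMargin))
    tsd <- substr(ref, site + 1L, site + tsdLen)
    donor <- paste0(substr(ref, 1L, site + tsdLen), ele,
                    substr(ref, site + 1L, nchar(ref)))
    stopifnot(nchar(donor) == nchar(ref) + nchar(ele) + tsdLen)
    list(donor = Biostrings::DNAStringSet(setNames(donor, "donor")),
         leftBp = site, rightBp = site + tsdLen, tsdSeq = tsd,
         elementLen = nchar(ele), site = site)
}

#' Cohort configuration
#'
#' Defaults encode the study conditions: penetrance among insertion
#' homozygotes 0.83 (57 affected of 69 homozygotes in the pooled study
#' sets) and a phenocopy rate of 0.084 (16 affected among 190
#' non-homozygotes).
#'
#' @param nIndividuals cohort size.
#' @param insertionAlleleFreq insertion allele frequency in [0,1].
#' @param penetranceHom P(case | HOM).
#' @param phenocopyRate P(case | not HOM).
#' @param studyLabel cohort label.
#' @param seed RNG seed (mandatory).
#' @return list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nIndividuals, insertionAlleleFreq,
                         penetranceHom = 0.83, phenocopyRate = 0.084,
                         studyLabel = "sim", seed) {
    stopifnot(!missing(seed))
    p <- c(insertionAlleleFreq, penetranceHom, phenocopyRate)
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
    structure(list(nIndividuals = as.integer(nIndividuals),
                   insertionAlleleFreq = insertionAlleleFreq,
                   penetranceHom = penetranceHom,
                   phenocopyRate = phenocopyRate,
                   studyLabel = studyLabel, seed = as.integer(seed)),
              class = "CohortConfig")
}

#' Draw a diploid cohort with a recessive, incompletely penetrant phenotype
#'
#' Genotypes follow Hardy-Weinberg proportions at the configured insertion
#' allele frequency; an individual is a case with probability
#' \code{penetranceHom} if homozygous for the insertion, else with the
#' phenocopy rate.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return data.frame with columns \code{id, genotype (WT/HET/HOM),
#'   phenotype (case/control), study}.
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "CohortConfig"))
    n <- config$nIndividuals
    if (n == 0L)
        return(data.frame(id = character(), genotype = character(),
                          phenotype = character(), study = character(),
                          stringsAsFactors = FALSE))
    set.seed(.deriveSeed(config$seed, 2L))
    q <- config$insertionAlleleFreq
    geno <- sample(c("WT", "HET", "HOM"), n, replace = TRUE,
                   prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    pCase <- ifelse(geno == "HOM", config$penetranceHom, config$phenocopyRate)
    pheno <- ifelse(runif(n) < pCase, "case", "control")
    data.frame(id = sprintf("%s_ind%03d", config$studyLabel, seq_len(n)),
               genotype = geno, phenotype = pheno, study = config$studyLabel,
               stringsAsFactors = FALSE)
}

#' Read-simulation configuration
#'
#' @param readLen read length in bp.
#' @param meanDepth mean haploid-pair depth over the individual.
#' @param insertMean,insertSd fragment length distribution (bp).
#' @param substErrorRate per-base substitution error rate.
#' @param seed RNG seed (mandatory).
#' @return list of class \code{"ReadSimConfig"}.
#' @export
readSimConfig <- function(readLen = 100L, meanDepth = 21, insertMean = 350L,
                          insertSd = 50L, substErrorRate = 0.001, seed) {
    stopifnot(!missing(seed))
    if (readLen > insertMean) stop("readLen must not exceed insertMean")
    if (substErrorRate < 0 || substErrorRate > 1)
        stop("substErrorRate must lie in [0, 1]")
    if (meanDepth <= 0) stop("meanDepth must be positive")
    structure(list(readLen = as.integer(readLen), meanDepth = meanDepth,
                   insertMean = as.integer(insertMean),
                   insertSd = as.integer(insertSd),
                   substErrorRate = substErrorRate, seed = as.integer(seed)),
              class = "ReadSimConfig")
}

# Truth alignment of donor-haplotype fragments against the reference.
# a,b: 0-based half-open read interval on the donor; E1/E2: element bounds
# on the donor; shift = elementLen + tsdLen. minAnchor: smallest aligned
# segment a mapper would place (shorter ends are emitted unmapped).
.donorReadAlign <- function(a, b, E1, E2, shift, minAnchor = 20L) {
    n <- length(a)
    pos0 <- rep(NA_integer_, n)
    cigar <- rep("*", n)
    mapped <- rep(FALSE, n)
    rl <- b - a
    # fully left of / right of the element
    i <- b <= E1
    pos0[i] <- a[i]; cigar[i] <- paste0(rl[i], "M"); mapped[i] <- TRUE
    i <- a >= E2
    pos0[i] <- a[i] - shift; cigar[i] <- paste0(rl[i], "M"); mapped[i] <- TRUE
    # crossing the left junction: anchor on the left flank, clip the rest
    i <- a < E1 & b > E1 & b <= E2
    m <- E1 - a[i]
    ok <- m >= minAnchor
    ii <- i; ii[i] <- ok
    pos0[ii] <- a[ii]
    cigar[ii] <- paste0(m[ok], "M", rl[ii] - m[ok], "S")
    mapped[ii] <- TRUE
    # crossing the right junction: anchor starts at the TSD start
    i <- a >= E1 & a < E2 & b > E2
    m <- b[i] - E2
    ok <- m >= minAnchor
    ii <- i; ii[i] <- ok
    pos0[ii] <- E2 - shift  # TSD start on the reference
    cigar[ii] <- paste0(rl[ii] - m[ok], "S", m[ok], "M")
    mapped[ii] <- TRUE
    list(pos0 = pos0, cigar = cigar, mapped = mapped)
}

# apply substitution errors in place (vector of sequences)
.addSubstErrors <- function(seqs, rate) {
    if (rate <= 0) return(seqs)
    nerr <- rbinom(length(seqs), nchar(seqs), rate)
    for (i in which(nerr > 0L)) {
        s <- strsplit(seqs[i], "")[[1]]
        pos <- sample.int(length(s), nerr[i])
        for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
        seqs[i] <- paste(s, collapse = "")
    }
    seqs
}

#' Simulate paired-end reads for one individual, with truth alignments
#'
#' Fragments are drawn from the individual's two haplotypes (reference
#' and/or donor according to genotype; a heterozygote uses both at 50:50
#' expectation). The truth SAM expresses each read's alignment to the
#' \emph{reference}: reads fully inside the element are unmapped with a
#' mapped mate where possible; reads straddling a breakpoint carry soft
#' clips at the correct reference coordinate; reads from the second
#' target-site copy map onto the single reference copy (producing the
#' characteristic depth spike over the TSD). Substitution errors are
#' applied at the configured rate. Fully deterministic given the seed.
#'
#' @param genotype \code{"WT"}, \code{"HET"} or \code{"HOM"}.
#' @param reference reference window (\code{DNAStringSet} or character).
#' @param planted result of \code{\link{plantInsertion}} (may be NULL for a
#'   WT-only simulation, in which case all reads are plain matches).
#' @param config a \code{\link{readSimConfig}}.
#' @param id read-name prefix / individual id.
#' @param seedOffset stream offset so each individual's reads can be
#'   regenerated independently of the rest of the cohort.
#' @return list with \code{reads} (truth-SAM data.frame, header attached),
#'   and \code{fastq1}, \code{fastq2} (data.frames with \code{name, seq}).
#' @export
simulateReads <- function(genotype, reference, planted = NULL, config,
                          id = "ind", seedOffset = 0L) {
    stopifnot(inherits(config, "ReadSimConfig"),
              genotype %in% c("WT", "HET", "HOM"))
    refc <- as.character(reference)[[1]]
    refName <- names(as.character(reference))[1]
    if (is.null(refName) || is.na(refName)) refName <- "refwin"
    if (genotype != "WT" && is.null(planted))
        stop("an insertion haplotype is required for genotype ", genotype)
    donorc <- if (!is.null(planted)) as.character(planted$donor)[[1]] else NULL
    haps <- switch(genotype,
        WT = c("ref", "ref"), HET = c("ref", "donor"),
        HOM = c("donor", "donor"))
    set.seed(.deriveSeed(config$seed, 100000L + seedOffset))
    L <- config$readLen
    out <- vector("list", 2L)
    for (h in 1:2) {
        hap <- if (haps[h] == "ref") refc else donorc
        hlen <- nchar(hap)
        nFrag <- as.integer(round(config$meanDepth / 2 * hlen / (2 * L)))
        if (nFrag <= 0L) stop("configured depth yields no fragments")
        fl <- as.integer(round(rnorm(nFrag, config$insertMean, config$insertSd)))
        fl <- pmin(pmax(fl, L), hlen)
        s0 <- floor(runif(nFrag, 0, hlen - fl + 1))  # 0-based fragment start
        a1 <- s0; b1 <- s0 + L                      # forward read interval
        a2 <- s0 + fl - L; b2 <- s0 + fl            # reverse read interval
        r1 <- substring(hap, a1 + 1L, b1)
        r2fwd <- substring(hap, a2 + 1L, b2)  # haplotype-forward orientation
        if (haps[h] == "ref") {
            al1 <- list(pos0 = a1, cigar = paste0(L, "M"),
                        mapped = rep(TRUE, nFrag))
            al2 <- list(pos0 = a2, cigar = paste0(L, "M"),
                        mapped = rep(TRUE, nFrag))
        } else {
            E1 <- planted$rightBp          # element start on the donor
            E2 <- E1 + planted$elementLen  # element end on the donor
            shift <- planted$elementLen + (planted$rightBp - planted$leftBp)
            al1 <- .donorReadAlign(a1, b1, E1, E2, shift)
            al2 <- .donorReadAlign(a2, b2, E1, E2, shift)
        }
        nm <- sprintf("%s_h%d_f%06d", id, h, seq_len(nFrag))
        mk <- function(al, alm, seqs, first) {
            flag <- rep(1L, nFrag) +                       # paired
                ifelse(first, 64L, 128L) +
                ifelse(first, 32L, 16L) * 1L               # FR orientation
            flag <- flag + ifelse(al$mapped, 0L, 4L) +
                ifelse(alm$mapped, 0L, 8L)
            data.frame(
                qname = nm, flag = flag,
                rname = ifelse(al$mapped | alm$mapped, refName, "*"),
                pos0 = ifelse(al$mapped, al$pos0,
                              ifelse(alm$mapped, alm$pos0, NA_integer_)),
                mapq = ifelse(al$mapped, 60L, 0L),
                cigar = ifelse(al$mapped, al$cigar, "*"),
                rnext = ifelse(alm$mapped | al$mapped, "=", "*"),
                pnext0 = ifelse(alm$mapped, alm$pos0,
                                ifelse(al$mapped, al$pos0, NA_integer_)),
                tlen = 0L, seq = seqs, qual = strrep("I", L), tags = "",
                stringsAsFactors = FALSE)
        }
        e1 <- .addSubstErrors(r1, config$substErrorRate)
        e2fwd <- .addSubstErrors(r2fwd, config$substErrorRate)
        e2rc <- .revcomp(e2fwd)               # as sequenced (reverse read)
        d1 <- mk(al1, al2, e1, TRUE)
        # SAM stores mapped reads in reference-forward orientation and
        # unmapped reads as sequenced
        d2 <- mk(al2, al1, ifelse(al2$mapped, e2fwd, e2rc), FALSE)
        d2$fastqSeq <- e2rc
        out[[h]] <- list(d1 = d1, d2 = d2)
    }
    d1 <- rbind(out[[1]]$d1, out[[2]]$d1)
    d2 <- rbind(out[[1]]$d2, out[[2]]$d2)
    fq2 <- d2$fastqSeq
    d2$fastqSeq <- NULL
    reads <- rbind(d1, d2)
    reads$mapped <- bitwAnd(reads$flag, 4L) == 0L
    reads$strand <- ifelse(bitwAnd(reads$flag, 16L) != 0L, "-", "+")
    reads <- reads[order(reads$qname, bitwAnd(reads$flag, 128L),
                         method = "radix"), ]
    rownames(reads) <- NULL
    attr(reads, "header") <- .samHeader(refName, nchar(refc))
    list(reads = reads,
         fastq1 = data.frame(name = paste0(d1$qname, "/1"), seq = d1$seq,
                             stringsAsFactors = FALSE),
         fastq2 = data.frame(name = paste0(d2$qname, "/2"), seq = fq2,
                             stringsAsFactors = FALSE))
}
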