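# Shared simulation fixtures, built once per test run and cached by their
# parameters. Small windows keep the default suite fast; the acceptance
# tests use the full-size defaults where the check demands them.

.fixtureCache <- new.env(parent = emptyenv())

`%+%` <- paste0

mkClu <- function(side, coord, support) {
    data.frame(side = side, refCoord = as.integer(coord),
               support = as.integer(support), consensusClip = "ACGTACGT",
               stringsAsFactors = FALSE)
}

simFixture <- function(seed = 1L, genotype = "HOM", windowLen = 6000L,
                       site = 3000L, errorRate = 0.001, meanDepth = 21) {
    key <- paste(seed, genotype, windowLen, site, errorRate, meanDepth,
                 sep = "|")
    if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
    el <- makeElement(elementModel(), seed = seed)
    ref <- makeReference(windowLen, seed = seed)
    pl <- plantInsertion(ref, el, site = site, tsdLen = 15L)
    rc <- readSimConfig(substErrorRate = errorRate, meanDepth = meanDepth,
                        seed = seed)
    sim <- simulateReads(genotype, ref,
                         planted = if (genotype == "WT") NULL else pl,
                         config = rc, id = genotype, seedOffset = 1L)
    out <- list(element = el, reference = ref, planted = pl, config = rc,
                reads = sim$reads, fastq1 = sim$fastq1, fastq2 = sim$fastq2)
    assign(key, out, envir = .fixtureCache)
    out
}

truthCall <- function(fx) {
    new("InsertionCall", refName = "refwin",
        tsdStart = as.integer(fx$planted$leftBp),
        tsdEnd = as.integer(fx$planted$rightBp),
        tsdSeq = fx$planted$tsdSeq, leftSupport = 0L, rightSupport = 0L,
        depthRatio = NA_real_,
        clipTails = c(fivePrime = "", threePrime = ""))
}

randomReads <- function(n, seed = 1L, refLen = 5000L, readLen = 50L) {
    if (n == 0L) {
        d <- data.frame(qname = character(), flag = integer(),
                        rname = character(), pos0 = integer(),
                        mapq = integer(), cigar = character(),
                        rnext = character(), pnext0 = integer(),
                        tlen = integer(), seq = character(),
                        qual = character(), tags = character(),
                        mapped = logical(), strand = character(),
                        stringsAsFactors = FALSE)
        attr(d, "header") <- c("@HD\tVN:1.6",
                               sprintf("@SQ\tSN:chr\tLN:%d", refLen))
        return(d)
    }
    set.seed(seed)
    pos <- sample.int(refLen - readLen, n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), readLen, replace = TRUE),
              collapse = ""), "")
    d <- data.frame(
        qname = sprintf("r%04d", seq_len(n)), flag = 0L, rname = "chr",
        pos0 = pos, mapq = 60L, cigar = paste0(readLen, "M"),
        rnext = "*", pnext0 = NA_integer_, tlen = 0L, seq = seqs,
        qual = strrep("I", readLen), tags = "", mapped = TRUE,
        strand = "+", stringsAsFactors = FALSE)
    attr(d, "header") <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:chr\tLN:%d", refLen))
    d
}
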