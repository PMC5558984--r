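mkEvents <- function(coords, side = "right", seqs = NULL) {
    data.frame(side = rep(side, length(coords)),
               refCoord = as.integer(coords),
               clippedSeq = if (is.null(seqs))
                   rep(strrep("ACGT", 5), length(coords)) else seqs,
               readName = sprintf("r%d", seq_along(coords)),
               stringsAsFactors = FALSE)
}

test_that("clip clustering thresholds support and finds the modal coordinate", {
    cl <- clusterClips(mkEvents(rep(160, 5)), minSupport = 3)
    expect_equal(nrow(cl), 1L)
    expect_equal(cl$refCoord, 160L)
    expect_equal(cl$support, 5L)

    expect_equal(nrow(clusterClips(mkEvents(rep(160, 2)), minSupport = 3)), 0L)

    cl <- clusterClips(mkEvents(c(160, 160, 161)), minSupport = 3,
                       posTol = 2)
    expect_equal(nrow(cl), 1L)
    expect_equal(cl$refCoord, 160L)
    expect_equal(cl$support, 3L)

    # consensus is the per-position majority
    cl <- clusterClips(mkEvents(rep(10, 3),
                                seqs = c("ACGTT", "ACGTA", "ACGTT")),
                       minSupport = 3)
    expect_equal(cl$consensusClip, "ACGTT")
    expect_equal(nrow(clusterClips(mkEvents(integer()))), 0L)
})

test_that("breakpoint pairing respects TSD geometry and the maxTsd bound", {
    cl <- rbind(mkClu("right", 1015, 8), mkClu("left", 1000, 6))
    calls <- pairBreakpoints(cl, maxTsd = 50)
    expect_length(calls, 1L)
    expect_equal(tsdStart(calls[[1]]), 1000L)
    expect_equal(tsdEnd(calls[[1]]), 1015L)
    expect_equal(tsdLength(calls[[1]]), 15L)

    blunt <- pairBreakpoints(rbind(mkClu("right", 500, 4),
                                   mkClu("left", 500, 4)))
    expect_equal(tsdLength(blunt[[1]]), 0L)

    far <- pairBreakpoints(rbind(mkClu("right", 1200, 4),
                                 mkClu("left", 1000, 4)), maxTsd = 50)
    expect_length(far, 0L)

    # shared clusters resolve to the highest combined support
    multi <- rbind(mkClu("right", 1015, 8), mkClu("left", 1000, 6),
                   mkClu("left", 1010, 3))
    expect_message(res <- pairBreakpoints(multi), "overlapping")
    expect_length(res, 1L)
    expect_equal(tsdStart(res[[1]]), 1000L)
})

test_that("the TSD sequence is read off the reference at the call", {
    ref <- Biostrings::DNAStringSet(c(r = strrep("ACGTG", 300)))
    call <- new("InsertionCall", refName = "r", tsdStart = 100L,
                tsdEnd = 115L, tsdSeq = "", leftSupport = 3L,
                rightSupport = 3L, depthRatio = NA_real_,
                clipTails = c(fivePrime = "", threePrime = ""))
    call <- inferTsd(ref, call)
    expect_equal(tsdSeq(call), substr(strrep("ACGTG", 300), 101, 115))
    empty <- new("InsertionCall", refName = "r", tsdStart = 100L,
                 tsdEnd = 100L, tsdSeq = "", leftSupport = 3L,
                 rightSupport = 3L, depthRatio = NA_real_,
                 clipTails = c(fivePrime = "", threePrime = ""))
    expect_equal(tsdSeq(inferTsd(ref, empty)), "")
    bad <- new("InsertionCall", refName = "r", tsdStart = 1490L,
               tsdEnd = 1600L, tsdSeq = "", leftSupport = 3L,
               rightSupport = 3L, depthRatio = NA_real_,
               clipTails = c(fivePrime = "", threePrime = ""))
    expect_error(inferTsd(ref, bad), "outside")
})

test_that("detection recovers the planted insertion and nothing on wild type", {
    fx <- simFixture(genotype = "HOM", windowLen = 20000L, site = 10000L)
    calls <- detectInsertions(fx$reads, fx$reference)
    expect_length(calls, 1L)
    call <- calls[[1]]
    expect_lte(abs(tsdStart(call) - fx$planted$leftBp), 2L)
    expect_lte(abs(tsdEnd(call) - fx$planted$rightBp), 2L)
    expect_equal(tsdLength(call), 15L)
    expect_identical(tsdSeq(call), fx$planted$tsdSeq)

    wt <- simFixture(genotype = "WT", windowLen = 20000L, site = 10000L)
    expect_length(detectInsertions(wt$reads, wt$reference), 0L)

    # heterozygote: called, with a lower depth ratio than the homozygote
    # (only one haplotype contributes doubled TSD coverage)
    het <- simFixture(genotype = "HET", windowLen = 20000L, site = 10000L)
    hetCalls <- detectInsertions(het$reads, het$reference)
    expect_length(hetCalls, 1L)
    expect_lt(hetCalls[[1]]@depthRatio, call@depthRatio)

    # invariant to read order
    shuf <- fx$reads[sample.int(nrow(fx$reads)), ]
    attr(shuf, "header") <- attr(fx$reads, "header")
    calls2 <- detectInsertions(shuf, fx$reference)
    expect_equal(tsdStart(calls2[[1]]), tsdStart(call))
    expect_equal(tsdEnd(calls2[[1]]), tsdEnd(call))
})

test_that("the region screen keeps exactly the case-exclusive homozygous sites", {
    expect_error(prioritizeRegionVariants(data.frame(), character(), "c"),
                 "non-empty")

    mkPanel <- function(n, samples, seed) {
        set.seed(seed)
        gtPool <- c("0/0", "0/1", "1/1", NA)
        gt <- matrix(sample(gtPool, n * length(samples), replace = TRUE,
                            prob = c(0.4, 0.2, 0.3, 0.1)),
                     nrow = n, dimnames = list(NULL, samples))
        rec <- data.frame(chrom = "c", pos = seq_len(n), id = ".",
                          ref = "A", alt = "T", qual = ".", filter = ".",
                          info = ".", stringsAsFactors = FALSE)
        attr(rec, "samples") <- samples
        attr(rec, "gt") <- gt
        rec
    }
    samples <- c("case1", "ctl1", "ctl2", "ctl3")
    # hand-built: kept, het case dropped, missing dropped
    rec <- mkPanel(3, samples, 1)
    gt <- attr(rec, "gt")
    gt[1, ] <- c("1/1", "0/0", "0/0", "0/0")  # kept
    gt[2, ] <- c("0/1", "0/0", "0/0", "0/0")  # het case -> dropped
    gt[3, ] <- c("1/1", "0/0", NA, "0/0")     # missing -> dropped
    attr(rec, "gt") <- gt
    out <- prioritizeRegionVariants(rec, "case1", c("ctl1", "ctl2", "ctl3"))
    expect_equal(out$pos, 1L)

    # 500-site random panel equals an independent per-site re-scan
    rec <- mkPanel(500, samples, 99)
    out <- prioritizeRegionVariants(rec, "case1", c("ctl1", "ctl2", "ctl3"))
    gt <- attr(rec, "gt")
    oracle <- vapply(seq_len(500), function(i) {
        g <- gt[i, ]
        if (anyNA(g)) return(FALSE)
        al <- strsplit(g, "/")
        hom <- vapply(al, function(a) a[1] == a[2], logical(1))
        if (!all(hom)) return(FALSE)
        caseAl <- al[[1]][1]
        ctlAl <- unique(vapply(al[-1], `[`, "", 1))
        length(ctlAl) == 1L && ctlAl != caseAl
    }, logical(1))
    expect_equal(out$pos, which(oracle))
})
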