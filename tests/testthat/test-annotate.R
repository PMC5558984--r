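test_that("ORF finding matches its definition and a brute-force scan", {
    o <- findOrfs("ATGAAATAA", minLen = 9)
    expect_equal(nrow(o[o$strand == "+", ]), 1L)
    expect_equal(o$length[o$strand == "+"], 9L)
    expect_equal(o$start[o$strand == "+"], 0L)

    expect_equal(nrow(findOrfs("CCCCCCCCC", minLen = 9)), 0L)
    expect_error(findOrfs("ACGT", minLen = 10), "multiple of 3")

    # brute force: every ATG walked to its first in-frame stop; the
    # outermost ATG per (strand, stop) is the longest such span
    bruteOrfs <- function(s, minLen) {
        L <- nchar(s)
        res <- list()
        for (strand in c("+", "-")) {
            str <- if (strand == "+") s else
                as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(s)))
            for (i in seq_len(L - 2)) {
                if (substr(str, i, i + 2) != "ATG") next
                j <- i
                stopAt <- NA
                while (j + 2 <= L) {
                    if (substr(str, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
                        stopAt <- j + 2
                        break
                    }
                    j <- j + 3
                }
                e <- if (!is.na(stopAt)) stopAt else {
                    k <- i
                    while (k + 5 <= L) k <- k + 3
                    k + 2
                }
                res[[length(res) + 1L]] <- data.frame(
                    strand = strand, key = paste(strand, e),
                    b0 = i - 1, e0 = e, len = e - i + 1,
                    stringsAsFactors = FALSE)
            }
        }
        if (!length(res)) return(data.frame(start = integer(),
                                            end = integer(),
                                            strand = character(),
                                            length = integer()))
        d <- do.call(rbind, res)
        keep <- do.call(rbind, lapply(split(d, d$key), function(g)
            g[which.max(g$len), ]))
        keep <- keep[keep$len >= minLen, ]
        out <- data.frame(
            start = ifelse(keep$strand == "+", keep$b0,
                           nchar(s) - keep$e0),
            end = ifelse(keep$strand == "+", keep$e0,
                         nchar(s) - keep$b0),
            strand = keep$strand, length = keep$len,
            stringsAsFactors = FALSE)
        out <- out[order(out$start, out$end), ]
        rownames(out) <- NULL
        out
    }
    set.seed(31)
    for (rep in 1:25) {
        s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                   collapse = "")
        got <- findOrfs(s, minLen = 30)
        rownames(got) <- NULL
        expect_equal(got, bruteOrfs(s, 30))
    }
})

test_that("insert-read harvest captures the element and only the element", {
    fx <- simFixture(genotype = "HOM", errorRate = 0)
    calls <- detectInsertions(fx$reads, fx$reference)
    harv <- collectInsertReads(fx$reads, calls[[1]])
    elc <- as.character(fx$element)[[1]]
    donor <- as.character(fx$planted$donor)[[1]]
    # error-free harvest: every clipped tail is an exact element substring
    ev <- clipEvents(fx$reads)
    tails <- ev$clippedSeq[abs(ev$refCoord - tsdEnd(calls[[1]])) <= 5 &
                           ev$side == "right"]
    expect_true(all(vapply(tails, function(t)
        grepl(t, elc, fixed = TRUE), logical(1))))
    # harvested mass covers the element at >= 0.8 of the expected depth
    expCov <- 21 * 6401
    expect_gte(sum(nchar(harv)) / 2, 0.8 * expCov)  # /2: both orientations

    # a wild-type sample yields at most noise
    wt <- simFixture(genotype = "WT", errorRate = 0)
    expect_lte(length(collectInsertReads(wt$reads, calls[[1]])), 4L)
})

test_that("greedy overlap assembly is exact, deterministic and poly-A aware", {
    one <- assembleConsensus("ACGTACGTCC", minOverlap = 4)
    expect_equal(contigSeq(one), "ACGTACGTCC")

    two <- assembleConsensus(c("ACGTACGTAA", "GTAACCCC"), minOverlap = 4)
    expect_equal(contigSeq(two), "ACGTACGTAACCCC")

    # identical multiset in any order gives an identical contig
    fx <- simFixture(genotype = "HOM")
    calls <- detectInsertions(fx$reads, fx$reference)
    harv <- collectInsertReads(fx$reads, calls[[1]])
    seed5 <- calls[[1]]@clipTails[["fivePrime"]]
    c1 <- assembleConsensus(harv, seedContigs = seed5)
    c2 <- assembleConsensus(rev(harv), seedContigs = seed5)
    expect_identical(contigSeq(c1), contigSeq(c2))

    # homozygote contig recovers the element length to within the poly-A
    # truncation allowance
    expect_equal(c1@terminatedBy, "polyA-run")
    expect_lte(abs(nchar(contigSeq(c1)) - 6401L), 25L)
})

test_that("repeat classification scores identity over the aligned span", {
    el <- makeElement(elementModel(), seed = 6)
    lib <- makeRepeatLibrary(el, seed = 6)
    elc <- as.character(el)[[1]]

    hits <- classifyRepeat(elc, lib)
    expect_equal(hits$libraryId[1], "L1_synthetic")
    expect_equal(hits$identityPct[1], 100)
    expect_equal(hits$alignedLen[1], 6401L)
    expect_equal(hits$strand[1], "+")

    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(elc)))
    hitsRc <- classifyRepeat(rc, lib)
    expect_equal(hitsRc$strand[1], "-")
    expect_equal(hitsRc$identityPct[1], 100)

    # known mutation count: identity equals 1 - k/L over the full span
    set.seed(8)
    ch <- strsplit(elc, "")[[1]]
    k <- round(0.01 * length(ch))
    pos <- sample.int(length(ch), k)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    mut <- paste(ch, collapse = "")
    hitsMut <- classifyRepeat(mut, lib)
    expect_gte(hitsMut$identityPct[1], 98)
    expect_lte(hitsMut$identityPct[1], 100)
    expect_equal(hitsMut$identityPct[1], 100 * (1 - k / length(ch)),
                 tolerance = 1e-8)

    expect_error(classifyRepeat(elc, Biostrings::DNAStringSet()), "empty")
})

test_that("structural annotation recovers the planted LINE-1 layout", {
    fx <- simFixture(genotype = "HOM")
    calls <- detectInsertions(fx$reads, fx$reference)
    harv <- collectInsertReads(fx$reads, calls[[1]])
    contig <- assembleConsensus(harv,
        seedContigs = calls[[1]]@clipTails[["fivePrime"]])
    lib <- makeRepeatLibrary(fx$element, seed = 1)
    ann <- annotateLine1(contig, calls[[1]], lib)
    expect_equal(ann@tsdLen, 15L)
    expect_equal(ann@orf1[2] - ann@orf1[1], 900L)
    expect_equal(ann@spacerLen, 49L)
    expect_equal(ann@orf2[2] - ann@orf2[1], 3828L)
    expect_equal(orientation(ann), "+")
    expect_true(ann@fullLength)
    expect_gte(ann@polyaLen, 15L)

    # element assembled in reverse orientation relative to the host gene
    rcContig <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(contigSeq(contig))))
    annRc <- annotateLine1(rcContig, calls[[1]], lib)
    expect_equal(orientation(annRc), "-")

    # contig truncated before ORF2 cannot be full length
    trunc <- substr(contigSeq(contig), 1, 2300)
    annTr <- annotateLine1(trunc, calls[[1]], lib)
    expect_false(annTr@fullLength)
})
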