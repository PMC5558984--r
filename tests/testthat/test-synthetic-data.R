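test_that("element model enforces its layout arithmetic", {
    m <- elementModel()
    expect_equal(m$totalLen, 6401L)
    expect_equal(m$utr3Len, 6401L - 1300L - 900L - 49L - 3828L - 30L)
    expect_error(elementModel(orf1Len = 6), "room")
    expect_error(elementModel(orf1Len = 901), "divisible")
    expect_error(elementModel(utr5Len = 3000), "exceeds totalLen")
})

test_that("the synthetic element has the planted LINE-1 anatomy", {
    el <- makeElement(elementModel(), seed = 3)
    expect_equal(Biostrings::width(el), 6401L)
    seqc <- as.character(el)[[1]]
    # genuine ORFs of exactly the configured lengths, recoverable by the
    # annotator
    orfs <- findOrfs(seqc, minLen = 300)
    fwd <- orfs[orfs$strand == "+", ]
    expect_true(any(fwd$length == 900L & fwd$start == 1300L))
    expect_true(any(fwd$length == 3828L & fwd$start == 2249L))
    # terminal poly-A tail, and no confounding A-run in the body
    expect_equal(substr(seqc, 6372, 6401), strrep("A", 30))
    expect_lt(line1scan:::.longestRun(substr(seqc, 1, 6371), "A"), 10L)
    # deterministic under the seed
    el2 <- makeElement(elementModel(), seed = 3)
    expect_identical(as.character(el2), as.character(el))
})

test_that("the reference window is clean, sized and reproducible", {
    ref <- makeReference(20000, seed = 11)
    expect_equal(Biostrings::width(ref), 20000L)
    expect_lt(line1scan:::.longestRun(as.character(ref)[[1]], "A"), 10L)
    expect_identical(as.character(makeReference(20000, seed = 11)),
                     as.character(ref))
    expect_false(identical(as.character(makeReference(20000, seed = 12)),
                           as.character(ref)))
    expect_error(makeReference(1500, seed = 1), "2 kb")
})

test_that("planting an element duplicates the target site and is invertible", {
    ref <- makeReference(8000, seed = 2)
    el <- makeElement(elementModel(), seed = 2)
    pl <- plantInsertion(ref, el, site = 4000, tsdLen = 15)
    refc <- as.character(ref)[[1]]
    donor <- as.character(pl$donor)[[1]]
    expect_equal(nchar(donor), 8000L + 6401L + 15L)
    expect_equal(pl$tsdSeq, substr(refc, 4001, 4015))
    # the TSD flanks the element on both sides of the donor
    expect_equal(substr(donor, 4001, 4015), pl$tsdSeq)
    expect_equal(substr(donor, 4016 + 6401, 4030 + 6401), pl$tsdSeq)
    # inverse operation: deleting element + one TSD copy restores the
    # reference
    restored <- paste0(substr(donor, 1, 4000),
                       substr(donor, 4016 + 6401, nchar(donor)))
    expect_identical(restored, refc)

    # blunt insertion
    bl <- plantInsertion(ref, el, site = 4000, tsdLen = 0)
    expect_equal(nchar(as.character(bl$donor)[[1]]), 8000L + 6401L)
    expect_error(plantInsertion(ref, el, site = 100), "edge")
})

test_that("cohort genotypes follow Hardy-Weinberg and the phenotype model", {
    # degenerate probabilities: penetrance 1, no phenocopies
    co <- simulateCohort(cohortConfig(500, 0.5, penetranceHom = 1,
                                      phenocopyRate = 0, seed = 4))
    expect_true(all(co$phenotype[co$genotype == "HOM"] == "case"))
    expect_true(all(co$phenotype[co$genotype != "HOM"] == "control"))

    # HOM fraction within 3 s.e. of q^2 at q = 0.5
    big <- simulateCohort(cohortConfig(10000, 0.5, seed = 5))
    pHom <- mean(big$genotype == "HOM")
    expect_lt(abs(pHom - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))

    # case rate among homozygotes near the default penetrance
    nHom <- sum(big$genotype == "HOM")
    caseRate <- mean(big$phenotype[big$genotype == "HOM"] == "case")
    expect_lt(abs(caseRate - 0.83), 3 * sqrt(0.83 * 0.17 / nHom))
    # and near the phenocopy rate elsewhere
    nOther <- sum(big$genotype != "HOM")
    pcRate <- mean(big$phenotype[big$genotype != "HOM"] == "case")
    expect_lt(abs(pcRate - 0.084), 3 * sqrt(0.084 * 0.916 / nOther))

    expect_equal(nrow(simulateCohort(cohortConfig(0, 0.5, seed = 1))), 0L)
    expect_identical(simulateCohort(cohortConfig(100, 0.3, seed = 9)),
                     simulateCohort(cohortConfig(100, 0.3, seed = 9)))
})

test_that("simulated reads carry the truth insertion signature", {
    fx <- simFixture(genotype = "HOM", windowLen = 20000L, site = 10000L)
    ev <- clipEvents(fx$reads)
    s <- fx$planted$leftBp; e <- fx$planted$rightBp
    # right-clip cluster at the TSD end, left-clip cluster at the TSD start
    expect_gte(sum(ev$side == "right" & ev$refCoord == e), 5L)
    expect_gte(sum(ev$side == "left" & ev$refCoord == s), 5L)

    # a wild-type individual shows no clip pileup at the planted site
    wt <- simFixture(genotype = "WT", windowLen = 20000L, site = 10000L)
    evWt <- clipEvents(wt$reads)
    expect_lte(sum(evWt$refCoord >= s - 2 & evWt$refCoord <= e + 2), 2L)
    # and its reads spanning the would-be TSD midpoint are plain matches
    mid <- (s + e) %/% 2
    spanning <- wt$reads$mapped & wt$reads$pos0 <= mid - 50 &
        wt$reads$pos0 + 100 > mid + 50
    expect_true(all(wt$reads$cigar[spanning] == "100M"))

    # realized flank depth within 15% of the configured mean
    tr <- pileup(fx$reads, "refwin", c(500, 8500))
    expect_lt(abs(median(depth(tr)) - 21) / 21, 0.15)

    # homozygote depth over the TSD approaches twice the flank depth: both
    # target-site copies of the donor map onto the single reference copy
    # (junction reads below the mapping anchor stay unmapped, so the ratio
    # sits below the ideal 2)
    win <- pileup(fx$reads, "refwin", c(9000, 11015))
    d <- depth(win); idx <- seq.int(9000, 11014)
    inTsd <- idx >= s & idx < e
    ratio <- mean(d[inTsd]) / mean(d[!inTsd])
    expect_gt(ratio, 1.5)
    expect_lt(ratio, 2.5)
})

test_that("read simulation is byte-deterministic under the seed", {
    fx <- simFixture(genotype = "HET")
    rc <- fx$config
    again <- simulateReads("HET", fx$reference, fx$planted, rc,
                           id = "HET", seedOffset = 1L)
    expect_identical(again$reads, fx$reads)
    expect_identical(again$fastq1, fx$fastq1)
    f1 <- tempfile(); f2 <- tempfile()
    writeFastq(fx$fastq1$seq, fx$fastq1$name, f1)
    writeFastq(again$fastq1$seq, again$fastq1$name, f2)
    expect_identical(readLines(f1), readLines(f2))
    s1 <- tempfile(); s2 <- tempfile()
    writeSam(fx$reads, s1); writeSam(again$reads, s2)
    expect_identical(readLines(s1), readLines(s2))
})

test_that("the packaged genotype tables carry the published margins", {
    tabs <- table1Fixtures()
    expect_setequal(names(tabs), c("UK-SNP", "UK-L1", "FIN-SNP", "FIN-L1"))
    expect_equal(unname(rowSums(genotypeCounts(tabs[["UK-L1"]]))),
                 c(24, 97))
    expect_equal(unname(rowSums(genotypeCounts(tabs[["FIN-L1"]]))),
                 c(49, 89))
    expect_equal(sum(genotypeCounts(tabs[["FIN-L1"]])[, "HOM"]), 52)
    pooled <- genotypeCounts(tabs[["UK-L1"]]) +
        genotypeCounts(tabs[["FIN-L1"]])
    expect_equal(pooled["case", "HOM"], 57)
    expect_equal(sum(pooled[, "HOM"]), 69)
})
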