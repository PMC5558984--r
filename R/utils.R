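# One global seed per run; subsystem streams are derived with fixed offsets
# so that e.g. the cohort and the reads of one individual can be
# regenerated independently. Kept below 2^31 - 1 (R integers are 32-bit).
.deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483629) + 1L
}

# longest run of a given base in a string (0 when absent)
.longestRun <- function(x, base = "A") {
    m <- gregexpr(paste0(base, "+"), x)[[1]]
    if (m[1L] == -1L) 0L else max(attr(m, "match.length"))
}

# length of the homopolymer run at the very end of a string
.trailingRun <- function(x, base = "A") {
    m <- regexpr(paste0(base, "+$"), x)
    if (m == -1L) 0L else attr(m, "match.length")
}
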