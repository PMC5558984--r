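# Minimal VCF 4.2 text I/O covering what the pipeline emits and screens:
# plain SNV/indel records with GT genotypes, and symbolic mobile-element
# insertion records (<INS:ME:LINE1>) with INFO keys SVLEN, TSD, MEINFO.
# Coordinates are 1-based in the file (VCF convention) and kept 1-based in
# the VariantRecord data.frame's `pos` column; conversion to the package's
# 0-based internal system happens where records are consumed.

.VCF_META <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVLEN,Number=1,Type=String,Description=\"Insertion length, or . when unknown\">",
    "##INFO=<ID=TSD,Number=1,Type=String,Description=\"Target site duplication sequence\">",
    "##INFO=<ID=MEINFO,Number=4,Type=String,Description=\"Mobile element info: NAME,START,END,POLARITY\">",
    "##ALT=<ID=INS:ME:LINE1,Description=\"LINE-1 mobile element insertion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")

#' Read and write a minimal multi-sample VCF 4.2
#'
#' \code{readVcfRecords} parses a plain-text VCF into a variant table with a
#' genotype matrix; \code{writeVcfRecords} writes one back. The supported
#' fields (CHROM, POS, ID, REF, ALT including symbolic
#' \code{<INS:ME:LINE1>}, INFO keys SVLEN/TSD/MEINFO, and the GT field)
#' round-trip identically. Missing genotypes (\code{./.}) become \code{NA}.
#'
#' @param path VCF file.
#' @param records data.frame with columns \code{chrom, pos} (1-based),
#'   \code{id, ref, alt, qual, filter, info} and a character genotype matrix
#'   in \code{attr(,"gt")} (variants x samples, entries like \code{"0/1"}).
#' @param samples sample names (column order of the genotype matrix).
#' @return \code{readVcfRecords}: the records data.frame, with samples in
#'   \code{attr(,"samples")} and genotypes in \code{attr(,"gt")}.
#'   \code{writeVcfRecords}: the path, invisibly.
#' @export
readVcfRecords <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    chromLn <- which(startsWith(lines, "#CHROM"))
    if (!length(chromLn))
        stop("VCF format error: missing #CHROM header line in ", path)
    hdr <- strsplit(lines[chromLn[1L]], "\t", fixed = TRUE)[[1]]
    samples <- if (length(hdr) > 9L) hdr[-(1:9)] else character()
    rec <- lines[seq_along(lines) > chromLn[1L] & !startsWith(lines, "#") &
                 nzchar(lines)]
    gt <- matrix(character(), nrow = length(rec), ncol = length(samples),
                 dimnames = list(NULL, samples))
    if (!length(rec)) {
        out <- data.frame(chrom = character(), pos = integer(),
                          id = character(), ref = character(),
                          alt = character(), qual = character(),
                          filter = character(), info = character(),
                          stringsAsFactors = FALSE)
        attr(out, "samples") <- samples
        attr(out, "gt") <- gt
        return(out)
    }
    fields <- strsplit(rec, "\t", fixed = TRUE)
    g <- function(i) vapply(fields, `[`, "", i)
    out <- data.frame(chrom = g(1L), pos = as.integer(g(2L)), id = g(3L),
                      ref = g(4L), alt = g(5L), qual = g(6L),
                      filter = g(7L), info = g(8L), stringsAsFactors = FALSE)
    if (length(samples)) {
        fmt <- strsplit(g(9L), ":", fixed = TRUE)
        for (j in seq_along(samples)) {
            raw <- vapply(fields, `[`, "", 9L + j)
            gtIdx <- vapply(fmt, function(f) match("GT", f), integer(1))
            val <- mapply(function(x, k) strsplit(x, ":", fixed = TRUE)[[1]][k],
                          raw, gtIdx, USE.NAMES = FALSE)
            val[val %in% c("./.", ".|.", ".")] <- NA_character_
            gt[, j] <- val
        }
    }
    nAlt <- vapply(strsplit(out$alt, ",", fixed = TRUE), length, integer(1))
    if (length(samples) && nrow(out)) {
        idx <- suppressWarnings(
            lapply(seq_len(nrow(out)), function(i) {
                as.integer(unlist(strsplit(gt[i, !is.na(gt[i, ]), drop = TRUE],
                                           "[/|]")))
            }))
        bad <- vapply(seq_along(idx), function(i)
            any(idx[[i]] > nAlt[i], na.rm = TRUE), logical(1))
        if (any(bad))
            stop("genotype allele index exceeds ALT count at record ",
                 which(bad)[1L])
    }
    attr(out, "samples") <- samples
    attr(out, "gt") <- gt
    out
}

#' @rdname readVcfRecords
#' @export
writeVcfRecords <- function(records, samples = attr(records, "samples"),
                            path) {
    gt <- attr(records, "gt")
    if (is.null(samples)) samples <- character()
    lines <- .VCF_META
    cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    if (length(samples)) cols <- c(cols, "FORMAT", samples)
    lines <- c(lines, paste(cols, collapse = "\t"))
    if (nrow(records)) {
        body <- paste(records$chrom, records$pos, records$id, records$ref,
                      records$alt, records$qual, records$filter,
                      records$info, sep = "\t")
        if (length(samples)) {
            gtTxt <- gt
            gtTxt[is.na(gtTxt)] <- "./."
            body <- paste(body, "GT", apply(gtTxt, 1L, paste, collapse = "\t"),
                          sep = "\t")
        }
        lines <- c(lines, body)
    }
    writeLines(lines, path)
    invisible(path)
}

# Parse an INFO string into a named character vector.
.parseInfo <- function(info) {
    if (is.na(info) || info == ".") return(character())
    kv <- strsplit(info, ";", fixed = TRUE)[[1]]
    has <- grepl("=", kv, fixed = TRUE)
    out <- rep(NA_character_, length(kv))
    nm <- kv
    nm[has] <- sub("=.*", "", kv[has])
    out[has] <- sub("^[^=]+=", "", kv[has])
    out[!has] <- ""
    names(out) <- nm
    out
}

# Genotype string "a/b" -> insertion-dosage given the risk allele index.
.gtToDose <- function(gt, riskAllele = 1L) {
    vapply(gt, function(g) {
        if (is.na(g)) return(NA_integer_)
        a <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
        if (anyNA(a)) return(NA_integer_)
        sum(a == riskAllele)
    }, integer(1), USE.NAMES = FALSE)
}
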