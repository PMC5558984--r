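#' Construct a 2x3 genotype count table
#'
#' @param cases,controls integer vectors of length 3: counts of (WT, HET,
#'   HOM) individuals.
#' @param study study label.
#' @param marker marker name.
#' @return a \code{\linkS4class{GenotypeTable}}.
#' @examples
#' genotypeTable(c(3, 6, 15), c(28, 67, 2), study = "UK", marker = "L1")
#' @export
genotypeTable <- function(cases, controls, study = "study", marker = "marker") {
    m <- rbind(case = as.integer(cases), control = as.integer(controls))
    colnames(m) <- c("WT", "HET", "HOM")
    new("GenotypeTable", counts = m, study = study, marker = marker)
}

#' Published case/control genotype tables for the Vallhund retinopathy locus
#'
#' The four 2x3 genotype count tables of the retinopathy study sets,
#' packaged as a plain-text fixture: the top GWAS SNP and the intronic
#' LINE-1 insertion, each genotyped in the UK cohort (24 cases, 97
#' controls) and the Finnish cohort (49 cases, 89 controls).
#'
#' @return named list of four \code{\linkS4class{GenotypeTable}} objects:
#'   \code{UK-SNP}, \code{UK-L1}, \code{FIN-SNP}, \code{FIN-L1}.
#' @examples
#' tabs <- table1Fixtures()
#' rowSums(genotypeCounts(tabs[["UK-L1"]]))  # 24 cases, 97 controls
#' @export
table1Fixtures <- function() {
    path <- system.file("extdata", "table1_genotype_counts.tsv",
                        package = "line1scan", mustWork = TRUE)
    d <- read.delim(path, stringsAsFactors = FALSE)
    out <- list()
    for (key in unique(paste(d$study, d$marker, sep = "-"))) {
        parts <- strsplit(key, "-", fixed = TRUE)[[1]]
        sub <- d[d$study == parts[1] & d$marker == parts[2], ]
        out[[key]] <- genotypeTable(
            unlist(sub[sub$phenotype == "case", c("WT", "HET", "HOM")]),
            unlist(sub[sub$phenotype == "control", c("WT", "HET", "HOM")]),
            study = parts[1], marker = parts[2])
    }
    out
}

# pooled counts across a list of GenotypeTable objects
.poolTables <- function(tables) {
    Reduce(`+`, lapply(tables, genotypeCounts))
}
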