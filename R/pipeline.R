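# End-to-end orchestration: simulate -> detect -> annotate -> genotype ->
# associate, as one reproducible, seeded run, plus the fixture-driven
# reproduction of the published association statistics.

.defaultRunConfig <- function() {
    list(
        seed = 1L,
        outDir = NULL,
        reference = list(windowLen = 20000L, site = 10000L),
        element = list(totalLen = 6401L, tsdLen = 15L, utr5Len = 1300L,
                       orf1Len = 900L, spacerLen = 49L, orf2Len = 3828L,
                       polyaLen = 30L, orientation = "+"),
        cohort = list(nIndividuals = 40L, insertionAlleleFreq = 0.4,
                      penetranceHom = 0.83, phenocopyRate = 0.084,
                      studyLabel = "sim"),
        reads = list(readLen = 100L, meanDepth = 21, insertMean = 350L,
                     insertSd = 50L, substErrorRate = 0.001),
        detector = list(minClipLen = 5L, minSupport = 3L, posTol = 2L,
                        maxTsd = 50L),
        genotyper = list(minDepth = 8L, hetBandLo = 0.2, hetBandHi = 0.8),
        assembler = list(minOverlap = 31L, polyaStop = 15L))
}

#' Build or load a pipeline run configuration
#'
#' Starts from the built-in defaults (the simulated study conditions:
#' 6,401 bp element with a 15 bp target site, 100 bp read pairs at 21x,
#' recessive phenotype with 0.83 penetrance and 0.084 phenocopy rate),
#' overlays a YAML file if given, then overlays \code{...}. Unknown keys
#' are rejected.
#'
#' @param yaml optional path to a YAML configuration.
#' @param ... named overrides of top-level sections (each a list merged
#'   into the section) or of \code{seed}/\code{outDir}.
#' @return nested configuration list of class \code{"RunConfig"}.
#' @export
runConfig <- function(yaml = NULL, ...) {
    cfg <- .defaultRunConfig()
    overlay <- function(base, upd, path = "") {
        bad <- setdiff(names(upd), names(base))
        if (length(bad))
            stop("unknown configuration key(s): ",
                 paste0(path, bad, collapse = ", "))
        for (nm in names(upd)) {
            val <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
                overlay(base[[nm]], upd[[nm]], paste0(path, nm, "."))
            else upd[[nm]]
            base[nm] <- list(val)   # keeps explicit NULLs (e.g. outDir)
        }
        base
    }
    if (!is.null(yaml))
        cfg <- overlay(cfg, yaml::read_yaml(yaml))
    dots <- list(...)
    if (length(dots)) cfg <- overlay(cfg, dots)
    class(cfg) <- "RunConfig"
    cfg
}

#' @rdname runConfig
#' @param config a \code{RunConfig}.
#' @param path output YAML path.
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

.configHash <- function(config) {
    tf <- tempfile()
    on.exit(unlink(tf))
    yaml::write_yaml(unclass(config), tf)
    unname(tools::md5sum(tf))
}

#' Run the full pipeline on simulated data
#'
#' Simulates the reference window, the element and the cohort; detects the
#' insertion from the reads of a discovery individual (the first insertion
#' homozygote, mirroring discovery from a single affected genome); harvests
#' and assembles the insertion allele and annotates its LINE-1 structure;
#' genotypes every individual at the call; and runs the association
#' battery on the resulting genotype table. When the cohort carries no
#' insertion allele (or no call is made), the downstream stages are
#' skipped with a notice. Artifacts (FASTA, SAM, TSV, VCF, JSON report)
#' are written under \code{config$outDir} when set.
#'
#' @param config a \code{\link{runConfig}}.
#' @return list of class \code{"RunReport"}: per-stage summaries,
#'   genotype table, association result, annotation, config hash.
#' @export
runAll <- function(config = runConfig()) {
    stopifnot(inherits(config, "RunConfig"))
    seed <- config$seed
    t0 <- Sys.time()
    report <- list(configHash = .configHash(config),
                   version = as.character(utils::packageVersion("line1scan")),
                   stages = list())
    stage <- function(name, ...) {
        report$stages[[name]] <<- list(...)
        message(sprintf("[%s] %s", name,
                        paste(names(list(...)), unlist(list(...)),
                              sep = "=", collapse = " ")))
    }

    # -- simulate ------------------------------------------------------------
    model <- do.call(elementModel, config$element)
    element <- makeElement(model, seed = seed)
    ref <- makeReference(config$reference$windowLen, seed = seed)
    planted <- plantInsertion(ref, element, site = config$reference$site,
                              tsdLen = model$tsdLen)
    cohort <- simulateCohort(do.call(cohortConfig,
        c(config$cohort, list(seed = seed))))
    rcfg <- do.call(readSimConfig, c(config$reads, list(seed = seed)))
    readsList <- list()
    for (i in seq_len(nrow(cohort))) {
        readsList[[cohort$id[i]]] <- simulateReads(
            cohort$genotype[i], ref,
            planted = if (cohort$genotype[i] == "WT") NULL else planted,
            config = rcfg, id = cohort$id[i], seedOffset = i)$reads
    }
    stage("simulate", individuals = nrow(cohort),
          carriers = sum(cohort$genotype != "WT"),
          homozygotes = sum(cohort$genotype == "HOM"))
    report$cohort <- cohort

    # -- detect --------------------------------------------------------------
    disc <- which(cohort$genotype == "HOM")
    if (!length(disc)) disc <- which(cohort$genotype == "HET")
    if (!length(disc)) {
        stage("detect", calls = 0L,
              note = "no insertion carrier in the cohort; downstream stages skipped")
        message("association stage skipped: nothing to genotype")
        class(report) <- "RunReport"
        return(report)
    }
    discId <- cohort$id[disc[1L]]
    det <- config$detector
    calls <- detectInsertions(readsList[[discId]], ref,
        minClipLen = det$minClipLen, minSupport = det$minSupport,
        posTol = det$posTol, maxTsd = det$maxTsd)
    stage("detect", discovery = discId, calls = length(calls))
    if (!length(calls)) {
        message("association stage skipped: no insertion call")
        class(report) <- "RunReport"
        return(report)
    }
    call <- calls[[1L]]
    report$call <- call
    report$detection <- list(
        tsdLen = tsdLength(call),
        breakpointError = abs(tsdStart(call) - planted$leftBp),
        tsdMatchesTruth = identical(tsdSeq(call), planted$tsdSeq))

    # -- annotate ------------------------------------------------------------
    lib <- makeRepeatLibrary(element, seed = seed)
    harvested <- collectInsertReads(readsList[[discId]], call)
    contig <- assembleConsensus(harvested,
        minOverlap = config$assembler$minOverlap,
        seedContigs = call@clipTails[["fivePrime"]],
        polyaStop = config$assembler$polyaStop)
    annot <- annotateLine1(contig, call, lib)
    report$contig <- contig
    report$annotation <- annot
    stage("annotate", contigLen = nchar(contigSeq(contig)),
          fullLength = annot@fullLength)

    # -- genotype ------------------------------------------------------------
    gcall <- genotypeCohort(readsList, call, cohort,
        minDepth = config$genotyper$minDepth,
        hetBand = c(config$genotyper$hetBandLo, config$genotyper$hetBandHi),
        posTol = det$posTol, study = config$cohort$studyLabel)
    truthOk <- merge(gcall$calls, cohort[, c("id", "genotype")], by = "id",
                     suffixes = c("", ".truth"))
    concord <- sum(truthOk$genotype == truthOk$genotype.truth)
    report$genotypes <- gcall$calls
    report$genotypeTable <- gcall$table
    report$genotypeConcordance <- c(concordant = concord,
                                    total = nrow(truthOk))
    stage("genotype", concordant = concord, total = nrow(truthOk),
          excluded = gcall$nExcluded)

    # -- associate -----------------------------------------------------------
    assoc <- tryCatch(associationBattery(gcall$table),
                      warning = function(w) {
                          message("association warning: ",
                                  conditionMessage(w))
                          suppressWarnings(associationBattery(gcall$table))
                      })
    report$association <- assoc
    stage("associate",
          exactP = signif(exactP(assoc)[[1L]], 3),
          orPerAllele = round(orPerAllele(assoc), 2))

    report$elapsedSec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    class(report) <- "RunReport"
    if (!is.null(config$outDir)) .writeRunArtifacts(report, config, ref,
                                                    element, readsList)
    report
}

.writeRunArtifacts <- function(report, config, ref, element, readsList) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    od <- function(f) file.path(config$outDir, f)
    writeFasta(ref, od("reference.fasta"))
    writeFasta(element, od("element.fasta"))
    write.table(report$cohort, od("truth_individuals.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    writeRunConfig(config, od("config.yaml"))
    if (!is.null(report$call)) {
        discId <- report$stages$detect$discovery
        writeSam(readsList[[discId]], od("discovery_reads.sam"))
        writeVcfRecords(callsToVcf(list(report$call), ref,
                                   svlen = nchar(contigSeq(report$contig))),
                        path = od("calls.vcf"))
        writeFasta(setNames(contigSeq(report$contig), "insertion_contig"),
                   od("contig.fasta"))
        write.table(report$genotypes, od("genotypes.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(reportSummary(report), od("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(config$outDir)
}

#' Plain-list summary of a pipeline run report
#'
#' @param report a \code{RunReport} from \code{\link{runAll}}.
#' @return a list of plain values suitable for JSON serialization.
#' @export
reportSummary <- function(report) {
    out <- list(configHash = report$configHash, version = report$version,
                stages = report$stages)
    if (!is.null(report$detection)) out$detection <- report$detection
    if (!is.null(report$annotation)) {
        a <- report$annotation
        out$annotation <- list(
            tsdLen = a@tsdLen,
            orf1Len = if (anyNA(a@orf1)) NA else a@orf1[2] - a@orf1[1],
            spacerLen = a@spacerLen,
            orf2Len = if (anyNA(a@orf2)) NA else a@orf2[2] - a@orf2[1],
            polyaLen = a@polyaLen, orientation = a@orientation,
            fullLength = a@fullLength,
            contigLen = nchar(contigSeq(report$contig)))
    }
    if (!is.null(report$genotypeConcordance))
        out$genotypeConcordance <- as.list(report$genotypeConcordance)
    if (!is.null(report$association)) {
        r <- report$association
        out$association <- list(exactP = as.list(exactP(r)),
                                orPerAllele = r@orPerAllele,
                                ciLo = r@ciLo, ciHi = r@ciHi,
                                lrtP = r@lrtP)
    }
    out
}

#' @export
print.RunReport <- function(x, ...) {
    cat("line1scan run report (config ", substr(x$configHash, 1, 8), ")\n",
        sep = "")
    for (nm in names(x$stages))
        cat(sprintf("  %-10s %s\n", nm,
            paste(names(x$stages[[nm]]), unlist(x$stages[[nm]]),
                  sep = "=", collapse = " ")))
    if (!is.null(x$association)) show(x$association)
    invisible(x)
}

#' Reproduce the published association statistics from packaged tables
#'
#' Runs the association battery on the packaged case/control genotype
#' tables: the per-study exact tests for the SNP and the LINE-1 insertion,
#' and for the pooled LINE-1 tables the study-adjusted per-allele odds
#' ratio with its Wald interval, the model-shape likelihood-ratio test,
#' and the concordance/penetrance summary.
#'
#' @return list with \code{exactP} (named per-table vector), \code{snp}
#'   and \code{l1} \code{\linkS4class{AssociationResult}} objects for the
#'   pooled analyses.
#' @examples
#' stats <- reproducePublishedStats()
#' signif(stats$exactP, 2)
#' @export
reproducePublishedStats <- function() {
    tabs <- table1Fixtures()
    ep <- vapply(tabs, fisherExactRxC, numeric(1))
    l1 <- associationBattery(list(tabs[["UK-L1"]], tabs[["FIN-L1"]]))
    snp <- associationBattery(list(tabs[["UK-SNP"]], tabs[["FIN-SNP"]]))
    out <- list(exactP = ep, l1 = l1, snp = snp)
    class(out) <- "publishedStats"
    out
}

#' @export
print.publishedStats <- function(x, ...) {
    cat("Exact (Freeman-Halton) P-values:\n")
    for (nm in names(x$exactP))
        cat(sprintf("  %-8s %.2g\n", nm, x$exactP[[nm]]))
    cat("\nPooled LINE-1 analysis:\n")
    show(x$l1)
    invisible(x)
}
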