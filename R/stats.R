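# The association battery, implemented from first principles: the
# Freeman-Halton exact conditional test on r x c tables, genotype-dosage
# LD r-squared, maximum-likelihood logistic regression by iteratively
# reweighted least squares (grouped, weighted input), the per-allele
# odds-ratio model with study adjustment, the general-vs-per-allele
# likelihood-ratio test of association shape, and concordance/penetrance
# summaries. stats::fisher.test and stats::glm serve only as independent
# cross-checks in the test suite.

#' Freeman-Halton exact test on an r x c contingency table
#'
#' The exact conditional test generalising Fisher's 2x2 test: all tables
#' with the observed margins are enumerated, each assigned its multivariate
#' hypergeometric probability (computed through log-gamma), and the
#' two-sided P-value is the total probability of tables no more probable
#' than the observed one (with relative tolerance 1e-12 to absorb floating
#' point ties). Rows or columns with a zero margin are collapsed away with
#' a warning before testing.
#'
#' @param table integer matrix of counts (a
#'   \code{\linkS4class{GenotypeTable}} is accepted).
#' @return the two-sided exact P-value.
#' @examples
#' fisherExactRxC(rbind(case = c(3, 6, 15), control = c(28, 67, 2)))
#' @export
fisherExactRxC <- function(table) {
    if (is(table, "GenotypeTable")) table <- genotypeCounts(table)
    m <- as.matrix(table)
    if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
    storage.mode(m) <- "integer"
    rz <- rowSums(m) == 0L; cz <- colSums(m) == 0L
    if (any(rz) || any(cz)) {
        warning("collapsing zero-margin row(s)/column(s) before testing")
        m <- m[!rz, !cz, drop = FALSE]
    }
    if (nrow(m) < 2L || ncol(m) < 2L) return(1)
    rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
    const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
    logPObs <- const - sum(lgamma(m + 1))
    cut <- logPObs + log1p(1e-12)
    total <- 0
    nr <- nrow(m); nc <- ncol(m)
    # recursive enumeration over rows; the last row is determined
    recurse <- function(rowIdx, colRemain, acc) {
        if (rowIdx == nr) {
            lp <- const - (acc + sum(lgamma(colRemain + 1)))
            if (lp <= cut) total <<- total + exp(lp)
            return(invisible())
        }
        comps <- .rowCompositions(rs[rowIdx], colRemain)
        for (j in seq_len(nrow(comps))) {
            row <- comps[j, ]
            recurse(rowIdx + 1L, colRemain - row,
                    acc + sum(lgamma(row + 1)))
        }
        invisible()
    }
    recurse(1L, cs, 0)
    min(1, total)
}

# all compositions of `total` into length(bounds) non-negative cells with
# cell j <= bounds[j]; returns a matrix, one composition per row
.rowCompositions <- function(total, bounds) {
    k <- length(bounds)
    if (k == 1L) {
        if (total <= bounds[1L]) return(matrix(total, 1L, 1L))
        return(matrix(integer(), 0L, 1L))
    }
    out <- list()
    lo <- max(0L, total - sum(bounds[-1L]))
    hi <- min(bounds[1L], total)
    if (hi < lo) return(matrix(integer(), 0L, k))
    for (v in lo:hi) {
        rest <- .rowCompositions(total - v, bounds[-1L])
        if (nrow(rest)) out[[length(out) + 1L]] <- cbind(v, rest)
    }
    do.call(rbind, out)
}

#' Squared genotype-dosage correlation between two variants
#'
#' Linkage-disequilibrium r-squared as used by standard GWAS toolkits: the
#' squared Pearson correlation of per-individual genotype dosages (0/1/2)
#' at two variants, computed from individual-level joint genotypes.
#'
#' @param dosagesA,dosagesB equal-length dosage vectors over \{0, 1, 2\}.
#' @return list with \code{r2} and \code{nIndividuals}.
#' @export
genotypeR2 <- function(dosagesA, dosagesB) {
    a <- as.numeric(dosagesA); b <- as.numeric(dosagesB)
    if (length(a) != length(b)) stop("dosage vectors differ in length")
    if (!all(c(a, b) %in% 0:2)) stop("dosages must be 0, 1 or 2")
    n <- length(a)
    ma <- sum(a) / n; mb <- sum(b) / n
    va <- sum((a - ma)^2); vb <- sum((b - mb)^2)
    if (va == 0 || vb == 0)
        stop("LD undefined: a variant has zero genotype variance")
    cab <- sum((a - ma) * (b - mb))
    list(r2 = cab^2 / (va * vb), nIndividuals = n)
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Newton-Raphson / iteratively reweighted least squares on (optionally
#' grouped) binary data. Convergence is declared when the maximum absolute
#' score falls below \code{tol}; complete or quasi-complete separation is
#' flagged when a coefficient diverges beyond 15 on the logit scale, in
#' which case the fit is returned with \code{converged = FALSE}. The
#' covariance is the inverse observed information.
#'
#' @param X design matrix (full rank).
#' @param y outcomes in \{0, 1\}.
#' @param weights non-negative case weights (cell counts for grouped
#'   input).
#' @param tol score convergence tolerance.
#' @param maxIter iteration cap.
#' @return list of class \code{"logisticFit"}: \code{coefficients},
#'   \code{vcov}, \code{logLik}, \code{converged}, \code{nIter},
#'   \code{separation}.
#' @export
fitLogistic <- function(X, y, weights = rep(1, length(y)), tol = 1e-10,
                        maxIter = 50L) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == length(y), length(weights) == length(y),
              all(y %in% c(0, 1)), all(weights >= 0))
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
    beta <- rep(0, ncol(X))
    ll <- function(b) {
        eta <- drop(X %*% b)
        # log(1 + e^eta) without overflow
        sum(weights * (y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))))
    }
    llCur <- ll(beta)
    converged <- FALSE
    separation <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        eta <- drop(X %*% beta)
        mu <- stats::plogis(eta)
        score <- drop(crossprod(X, weights * (y - mu)))
        if (max(abs(score)) < tol) { converged <- TRUE; break }
        W <- weights * mu * (1 - mu)
        info <- crossprod(X, X * W)
        step <- tryCatch(solve(info, score), error = function(e) NULL)
        if (is.null(step)) { separation <- TRUE; break }
        # step-halving safeguard
        h <- 1
        repeat {
            cand <- beta + h * step
            llNew <- ll(cand)
            if (llNew >= llCur - 1e-12 || h < 1e-4) break
            h <- h / 2
        }
        beta <- beta + h * step
        llCur <- ll(beta)
        if (max(abs(beta)) > 15) { separation <- TRUE; break }
    }
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- weights * mu * (1 - mu)
    info <- crossprod(X, X * W)
    vc <- tryCatch(solve(info), error = function(e)
        matrix(NA_real_, ncol(X), ncol(X)))
    dimnames(vc) <- list(colnames(X), colnames(X))
    structure(list(coefficients = setNames(beta, colnames(X)), vcov = vc,
                   logLik = llCur, converged = converged && !separation,
                   nIter = iter, separation = separation),
              class = "logisticFit")
}

#' @export
print.logisticFit <- function(x, ...) {
    cat(sprintf("logisticFit: logLik %.4f after %d iterations (%s)\n",
        x$logLik, x$nIter,
        if (x$separation) "separation flagged"
        else if (x$converged) "converged" else "not converged"))
    se <- sqrt(diag(x$vcov))
    print(cbind(estimate = x$coefficients, se = se))
    invisible(x)
}

# genotype count tables -> grouped per-cell data with dosages
.tablesToGrouped <- function(tables) {
    if (is(tables, "GenotypeTable")) tables <- list(tables)
    rows <- lapply(tables, function(tab) {
        m <- genotypeCounts(tab)
        data.frame(study = studyLabel(tab),
                   dose = rep(0:2, 2L),
                   case = rep(c(1, 0), each = 3L),
                   w = c(m["case", ], m["control", ]),
                   stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d[d$w > 0, , drop = FALSE]
}

# design matrices for the three nested models on grouped data
.assocDesigns <- function(d) {
    studies <- unique(d$study)
    S <- if (length(studies) > 1L) {
        sapply(studies[-1L], function(s) as.numeric(d$study == s))
    } else NULL
    mk <- function(core, nm) {
        X <- cbind(1, core, S)
        colnames(X) <- c("(Intercept)", nm,
                         if (!is.null(S)) paste0("study", studies[-1L]))
        X
    }
    list(linear = mk(d$dose, "dose"),
         general = mk(cbind(as.numeric(d$dose == 1L),
                            as.numeric(d$dose == 2L)), c("het", "hom")),
         null = {
             X <- cbind(rep(1, nrow(d)), S)
             colnames(X) <- c("(Intercept)",
                              if (!is.null(S)) paste0("study", studies[-1L]))
             X
         })
}

#' Per-allele odds ratio with study adjustment
#'
#' Fits the per-allele (additive) logistic model
#' \eqn{logit P(case) = \alpha + \beta \cdot dose + \gamma \cdot study}
#' on one or more genotype count tables (one indicator per additional
#' study) and reports \eqn{OR = e^\beta} with its 95\% Wald interval, the
#' Wald P-value, and the 1-df likelihood-ratio P against the study-only
#' null model.
#'
#' @param tables a \code{\linkS4class{GenotypeTable}} or list of them.
#' @return list with \code{or, ciLo, ciHi, waldP, lrtNullP, fit, fitNull}.
#' @export
perAlleleOr <- function(tables) {
    d <- .tablesToGrouped(tables)
    X <- .assocDesigns(d)
    fit <- fitLogistic(X$linear, d$case, d$w)
    if (!fit$converged)
        warning("per-allele model did not converge (possible separation)")
    b <- fit$coefficients["dose"]
    se <- sqrt(fit$vcov["dose", "dose"])
    fit0 <- fitLogistic(X$null, d$case, d$w)
    lrt0 <- max(0, 2 * (fit$logLik - fit0$logLik))
    list(or = exp(unname(b)), ciLo = exp(unname(b) - 1.96 * se),
         ciHi = exp(unname(b) + 1.96 * se),
         waldP = 2 * stats::pnorm(-abs(unname(b) / se)),
         lrtNullP = stats::pchisq(lrt0, df = 1L, lower.tail = FALSE),
         fit = fit, fitNull = fit0)
}

#' Likelihood-ratio test of association shape
#'
#' Compares the general (genotypic) model, with separate heterozygote and
#' homozygote effects, against the nested linear per-allele model: LRT =
#' 2(l_general - l_linear) on 1 df. A small P indicates a non-additive
#' shape -- for a recessive locus, the heterozygote effect falls off the
#' per-allele line.
#'
#' @param tables a \code{\linkS4class{GenotypeTable}} or list of them
#'   (study-adjusted when several).
#' @return list with \code{stat}, \code{df}, \code{p}, and both fits.
#' @export
modelShapeLrt <- function(tables) {
    d <- .tablesToGrouped(tables)
    X <- .assocDesigns(d)
    fitL <- fitLogistic(X$linear, d$case, d$w)
    fitG <- fitLogistic(X$general, d$case, d$w)
    if (!fitL$converged || !fitG$converged)
        stop("model-shape LRT requires both fits to converge")
    stat <- max(0, 2 * (fitG$logLik - fitL$logLik))
    list(stat = stat, df = 1L,
         p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
         fitLinear = fitL, fitGeneral = fitG)
}

#' Genotype-phenotype concordance and penetrance summary
#'
#' On pooled 2x3 counts: the percentage of cases that are not insertion
#' homozygotes (discordant cases), the percentage of controls that are
#' (discordant controls), and the penetrance fraction among homozygotes.
#' Percentages are rounded half away from zero only in the rounded fields;
#' raw fractions are always retained.
#'
#' @param tables a \code{\linkS4class{GenotypeTable}} or list of them
#'   (pooled before summarising).
#' @return list with \code{pctCasesDiscordant, pctControlsDiscordant}
#'   (raw), their \code{...Rounded} forms, \code{homAffected, homTotal},
#'   and \code{penetranceHom}.
#' @export
concordanceSummary <- function(tables) {
    if (is(tables, "GenotypeTable")) tables <- list(tables)
    m <- .poolTables(tables)
    nCases <- sum(m["case", ]); nControls <- sum(m["control", ])
    homTotal <- sum(m[, "HOM"]); homAffected <- m["case", "HOM"]
    halfUp <- function(x) if (is.na(x)) NA else floor(x + 0.5)
    pcd <- if (nCases > 0) 100 * (nCases - homAffected) / nCases else NA_real_
    pct <- if (nControls > 0) 100 * m["control", "HOM"] / nControls else NA_real_
    pen <- if (homTotal > 0) homAffected / homTotal else NA_real_
    if (anyNA(c(pcd, pct, pen)))
        warning("zero denominator: some concordance fields are undefined")
    list(pctCasesDiscordant = pcd, pctControlsDiscordant = pct,
         pctCasesDiscordantRounded = halfUp(pcd),
         pctControlsDiscordantRounded = halfUp(pct),
         homAffected = as.integer(homAffected),
         homTotal = as.integer(homTotal), penetranceHom = pen)
}

#' Run the full association battery on genotype count tables
#'
#' Per-study (and pooled) Freeman-Halton exact P-values, the per-allele
#' odds ratio with Wald interval and LRT-vs-null P, the general-vs-linear
#' model-shape LRT, and the concordance summary, collected into an
#' \code{\linkS4class{AssociationResult}}.
#'
#' @param tables a \code{\linkS4class{GenotypeTable}} or list of them.
#' @return an \code{\linkS4class{AssociationResult}}.
#' @examples
#' tabs <- table1Fixtures()
#' associationBattery(list(tabs[["UK-L1"]], tabs[["FIN-L1"]]))
#' @export
associationBattery <- function(tables) {
    if (is(tables, "GenotypeTable")) tables <- list(tables)
    studies <- vapply(tables, studyLabel, "")
    ep <- vapply(tables, fisherExactRxC, numeric(1))
    names(ep) <- studies
    if (length(tables) > 1L) {
        pooled <- .poolTables(tables)
        ep <- c(ep, pooled = fisherExactRxC(pooled))
    }
    pa <- perAlleleOr(tables)
    shape <- tryCatch(modelShapeLrt(tables), error = function(e) {
        warning("model-shape LRT unavailable: ", conditionMessage(e))
        list(stat = NA_real_, df = 1L, p = NA_real_)
    })
    cc <- concordanceSummary(tables)
    new("AssociationResult", studies = studies, exactP = ep,
        orPerAllele = pa$or, ciLo = pa$ciLo, ciHi = pa$ciHi,
        waldP = pa$waldP, lrtNullP = pa$lrtNullP,
        lrtStat = shape$stat, lrtDf = shape$df, lrtP = shape$p,
        concordance = cc)
}
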