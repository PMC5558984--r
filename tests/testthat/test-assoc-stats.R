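test_that("the exact r x c test agrees with independent references", {
    # degenerate margins: a single possible table
    expect_warning(p <- fisherExactRxC(rbind(c(5, 0, 0), c(5, 0, 0))),
                   "zero-margin")
    expect_equal(p, 1)

    # hand-enumerable table checked against an independent implementation
    tab <- rbind(c(2, 0, 2), c(0, 4, 0))
    expect_equal(fisherExactRxC(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-12)

    # exhaustive sweep: every 2x3 table with N <= 10
    enumAll <- function(N) {
        out <- list()
        for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b))
            for (d in 0:(N - a - b - c)) for (e in 0:(N - a - b - c - d)) {
                f <- N - a - b - c - d - e
                out[[length(out) + 1L]] <- matrix(c(a, b, c, d, e, f),
                                                  2, 3, byrow = TRUE)
            }
        out
    }
    set.seed(1)
    for (N in c(6L, 10L)) {
        tables <- enumAll(N)
        if (N == 10L) tables <- tables[sample.int(length(tables), 400L)]
        for (m in tables) {
            if (sum(m) == 0) next
            mine <- suppressWarnings(fisherExactRxC(m))
            rs <- rowSums(m); cs <- colSums(m)
            m2 <- m[rs > 0, cs > 0, drop = FALSE]
            ref <- if (nrow(m2) < 2 || ncol(m2) < 2) 1
                   else stats::fisher.test(m2)$p.value
            expect_equal(mine, ref, tolerance = 1e-8)
        }
    }

    # random larger tables up to N = 30
    set.seed(2)
    for (i in 1:100) {
        m <- matrix(rmultinom(1, sample(12:30, 1), prob = runif(6)), 2, 3)
        mine <- suppressWarnings(fisherExactRxC(m))
        rs <- rowSums(m); cs <- colSums(m)
        m2 <- m[rs > 0, cs > 0, drop = FALSE]
        ref <- if (nrow(m2) < 2 || ncol(m2) < 2) 1
               else stats::fisher.test(m2)$p.value
        expect_equal(mine, ref, tolerance = 1e-8)
    }
})

test_that("genotype-dosage r2 matches the covariance formula", {
    expect_equal(genotypeR2(c(0, 1, 2, 0), c(0, 1, 2, 0))$r2, 1)
    # perfect negative correlation squares to 1
    expect_equal(genotypeR2(c(0, 1, 2, 0), c(2, 1, 0, 2))$r2, 1)
    expect_error(genotypeR2(c(0, 0, 0), c(0, 1, 2)), "zero genotype variance")
    expect_error(genotypeR2(c(0, 1), c(0, 1, 2)), "length")
    expect_error(genotypeR2(c(0, 3, 1), c(0, 1, 2)), "0, 1 or 2")

    set.seed(5)
    for (i in 1:20) {
        a <- sample(0:2, 50, replace = TRUE)
        b <- pmin(2, pmax(0, a + sample(-1:1, 50, replace = TRUE,
                                        prob = c(0.2, 0.6, 0.2))))
        if (var(a) == 0 || var(b) == 0) next
        expect_equal(genotypeR2(a, b)$r2, stats::cor(a, b)^2,
                     tolerance = 1e-12)
    }
})

test_that("IRLS logistic regression matches closed forms and glm", {
    # 2x2 closed form: slope odds ratio equals the cross-product ratio of
    # the cells (10, 5; 2, 20): rows exposure, columns (control, case)
    X <- cbind(1, c(0, 0, 1, 1))
    y <- c(0, 1, 0, 1)
    w <- c(10, 5, 2, 20)
    fit <- fitLogistic(X, y, w)
    expect_true(fit$converged)
    expect_equal(exp(fit$coefficients[2]), (10 * 20) / (5 * 2),
                 tolerance = 1e-8, ignore_attr = TRUE)

    # no association: slope 0
    flat <- fitLogistic(X, y, c(10, 10, 30, 30))
    expect_equal(unname(flat$coefficients[2]), 0, tolerance = 1e-8)

    # weight equivalence: duplicating all rows leaves estimates unchanged
    fit2 <- fitLogistic(rbind(X, X), c(y, y), c(w, w))
    expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)

    # random grouped problems against glm
    set.seed(6)
    for (i in 1:10) {
        d <- expand.grid(dose = 0:2, study = 0:1)
        d <- rbind(cbind(d, case = 1), cbind(d, case = 0))
        d$w <- sample(1:40, nrow(d), replace = TRUE)
        Xd <- cbind(1, d$dose, d$study)
        mine <- fitLogistic(Xd, d$case, d$w)
        ref <- suppressWarnings(stats::glm(case ~ dose + study,
            family = stats::binomial(), weights = w, data = d))
        expect_equal(unname(mine$coefficients), unname(stats::coef(ref)),
                     tolerance = 1e-6)
        expect_equal(mine$logLik, as.numeric(stats::logLik(ref)),
                     tolerance = 1e-6)
        expect_equal(unname(diag(mine$vcov)),
                     unname(diag(stats::vcov(ref))), tolerance = 1e-4)
    }

    # permutation invariance in row order
    perm <- sample(nrow(X))
    fitP <- fitLogistic(X[perm, ], y[perm], w[perm])
    expect_equal(fitP$coefficients, fit$coefficients, tolerance = 1e-10)

    # complete separation is flagged, not silently reported
    sep <- fitLogistic(cbind(1, c(0, 1)), c(0, 1), c(10, 10))
    expect_false(sep$converged)
    expect_true(sep$separation)

    expect_error(fitLogistic(cbind(c(1, 1), c(1, 1)), c(0, 1)), "rank")
})

test_that("per-allele model recovers known odds ratios", {
    # no dose effect: OR 1
    tab <- genotypeTable(c(10, 20, 10), c(10, 20, 10))
    expect_equal(perAlleleOr(tab)$or, 1, tolerance = 1e-6)

    # collapsing HET+HOM against WT into 2x2 equals the cross-product
    tab2 <- genotypeTable(c(5, 0, 20), c(25, 0, 10))
    pa <- perAlleleOr(genotypeTable(c(5, 40, 0), c(25, 20, 0)))
    cross <- (40 * 25) / (5 * 20)
    expect_equal(pa$or, cross, tolerance = 1e-6)

    # parameter recovery: Wald coverage at n = 2000
    set.seed(7)
    beta <- log(2); alpha <- -1; q <- 0.3
    hits <- 0L
    for (r in 1:100) {
        dose <- sample(0:2, 2000, replace = TRUE,
                       prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
        pcase <- stats::plogis(alpha + beta * dose)
        case <- stats::rbinom(2000, 1, pcase)
        cnt <- table(factor(dose, 0:2), factor(case, 0:1))
        tab <- genotypeTable(cnt[, "1"], cnt[, "0"])
        fit <- perAlleleOr(tab)
        bhat <- log(fit$or)
        se <- (log(fit$ciHi) - log(fit$ciLo)) / (2 * 1.96)
        if (abs(bhat - beta) < 3 * se) hits <- hits + 1L
    }
    expect_gte(hits, 95L)
})

test_that("the shape LRT distinguishes additive from recessive risk", {
    simTab <- function(n, q, linkFun, seed) {
        set.seed(seed)
        dose <- sample(0:2, n, replace = TRUE,
                       prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
        case <- stats::rbinom(n, 1, linkFun(dose))
        cnt <- table(factor(dose, 0:2), factor(case, 0:1))
        genotypeTable(cnt[, "1"], cnt[, "0"])
    }
    # type-I error under an additive truth: about 5% rejections
    rej <- 0L; done <- 0L
    for (r in 1:200) {
        tab <- simTab(5000, 0.3, function(d) stats::plogis(-1 + 0.4 * d),
                      seed = 1000 + r)
        res <- tryCatch(modelShapeLrt(tab), error = function(e) NULL)
        if (is.null(res)) next
        done <- done + 1L
        if (res$p < 0.05) rej <- rej + 1L
    }
    expect_gte(done, 195L)
    expect_gte(rej, 2L)
    expect_lte(rej, 20L)

    # power under a recessive truth at n = 500
    pow <- 0L
    for (r in 1:100) {
        tab <- simTab(500, 0.4,
                      function(d) ifelse(d == 2, 0.5, 0.08), seed = 2000 + r)
        res <- tryCatch(modelShapeLrt(tab), error = function(e) NULL)
        if (!is.null(res) && res$p < 0.05) pow <- pow + 1L
    }
    expect_gt(pow, 80L)
})

test_that("concordance summaries handle degenerate tables", {
    tidy <- genotypeTable(c(0, 0, 30), c(20, 10, 0))
    cc <- concordanceSummary(tidy)
    expect_equal(cc$pctCasesDiscordant, 0)
    expect_equal(cc$pctControlsDiscordant, 0)
    expect_equal(cc$penetranceHom, 1)

    noCase <- genotypeTable(c(0, 0, 0), c(5, 5, 5))
    expect_warning(cc2 <- concordanceSummary(noCase), "denominator")
    expect_true(is.na(cc2$pctCasesDiscordant))
})

test_that("the battery assembles per-study and pooled results coherently", {
    tabs <- table1Fixtures()
    res <- associationBattery(list(tabs[["UK-L1"]], tabs[["FIN-L1"]]))
    expect_s4_class(res, "AssociationResult")
    expect_named(exactP(res), c("UK", "FIN", "pooled"))
    expect_true(res@ciLo <= orPerAllele(res) &&
                orPerAllele(res) <= res@ciHi)
    expect_gte(res@lrtStat, 0)
    expect_equal(res@concordance$homTotal, 69L)
})
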