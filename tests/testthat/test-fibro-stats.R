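test_that("Spearman stage correlation handles monotone, null and degenerate input", {
    d <- data.frame(stage = 0:4, ttp = c(60, 70, 75, 80, 90))
    expect_equal(spearmanStageCorrelation(d, "ttp")$rho, 1)
    null_d <- withr::with_seed(5, data.frame(stage = rep(0:4, each = 40),
                                             ttp = rnorm(200)))
    expect_lt(abs(spearmanStageCorrelation(null_d, "ttp")$rho), 0.15)
    expect_error(spearmanStageCorrelation(
        data.frame(stage = 0:4, ttp = rep(1, 5)), "ttp"), "constant")
})

test_that("Mann-Whitney is exact for separated small groups and null on identical ones", {
    # fully separated 5 vs 5: enumeration over C(10,5) arrangements gives
    # a two-sided p of exactly 2/252
    res <- mannWhitney(1:5, 11:15)
    expect_true(res$exact)
    expect_equal(res$p_raw, 2 / 252, tolerance = 1e-12)
    expect_equal(res$statistic, 0)          # no x exceeds any y
    # independent enumeration oracle: rank-sum distribution by brute force
    combos <- combn(10, 5)
    pooled <- c(1:5, 11:15)
    u_obs <- 0
    u_all <- apply(combos, 2, function(ix)
        sum(rank(pooled)[ix]) - 5 * 6 / 2)
    p_enum <- mean(u_all <= u_obs | u_all >= 25 - u_obs + 0)
    expect_equal(res$p_raw, p_enum, tolerance = 1e-12)
    # identical groups: nothing to detect
    same <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
    expect_equal(same$p_raw, 1, tolerance = 1e-9)
    expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("Bonferroni correction respects its bound and family size", {
    res <- mannWhitney(1:5, 11:15, family_size = 4)
    expect_equal(res$p_bonferroni, min(1, res$p_raw * 4))
    res2 <- mannWhitney(c(1, 3), c(2, 4), family_size = 100)
    expect_gte(res2$p_bonferroni, res2$p_raw)
    expect_equal(res2$p_bonferroni, 1)
})

test_that("grouped-stage splits separate a perfect parameter and not a permuted one", {
    d <- data.frame(stage = rep(0:4, c(16, 11, 13, 13, 10)))
    d$ttp <- d$stage
    res <- groupedStageTests(d, "ttp")
    expect_named(res, c("S0 vs S1-4", "S0-1 vs S2-4", "S0-2 vs S3-4",
                        "S0-3 vs S4"))
    for (r in res) expect_lt(r$p_raw, 1e-4)
    # permuted labels: the family should rarely reject
    rejections <- withr::with_seed(8, vapply(seq_len(200), function(i) {
        d$perm <- sample(rnorm(nrow(d)))
        any(vapply(groupedStageTests(d, "perm"),
                   function(r) r$p_bonferroni < 0.05, logical(1)))
    }, logical(1)))
    expect_lte(mean(rejections), 0.10)
})

test_that("ROC analysis is exact on separated, uninformative and oriented data", {
    d <- data.frame(stage = rep(c(0, 2), each = 10),
                    ttp = c(rnorm(10, 0), rnorm(10, 100)))
    r <- rocAnalysis(d, "ttp", ">=1")
    expect_equal(r$auc, 1)
    expect_equal(r$sensitivity, 100)
    expect_equal(r$specificity, 100)
    # all-equal values: AUC exactly 0.5 by the tie rule
    d$flat <- 1
    expect_equal(rocAnalysis(d, "flat", ">=1")$auc, 0.5)
    # a lower-is-positive parameter is auto-oriented
    d$pei <- -d$ttp
    r2 <- rocAnalysis(d, "pei", ">=1")
    expect_equal(r2$auc, 1)
    expect_equal(r2$polarity, "lower-is-positive")
    expect_error(rocAnalysis(d[d$stage == 0, ], "ttp", ">=1"), "non-empty")
})

test_that("AUC equals U/(n1 n2) from the rank test, ties included", {
    withr::with_seed(12, {
        for (i in 1:10) {
            n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
            x <- sample(1:8, n1, replace = TRUE)   # heavy ties
            y <- sample(3:10, n2, replace = TRUE)
            d <- data.frame(stage = rep(c(0, 1), c(n1, n2)),
                            v = c(x, y))
            auc_raw <- spleenDCE:::.rankAuc(d$v, d$stage >= 1)
            u <- mannWhitney(y, x)$statistic   # pairs where pos > neg
            expect_equal(auc_raw, u / (n1 * n2), tolerance = 1e-12)
        }
    })
})

test_that("reported sensitivity/specificity are attained at the reported cutoff", {
    withr::with_seed(19, {
        for (i in 1:10) {
            d <- data.frame(stage = rep(c(0, 3), c(15, 12)),
                            v = c(rnorm(15, 10, 3), rnorm(12, 13, 3)))
            r <- rocAnalysis(d, "v", ">=3")
            pos <- d$stage >= 3
            call_pos <- if (r$polarity == "higher-is-positive")
                d$v >= r$cutoff else d$v <= r$cutoff
            expect_equal(r$sensitivity, 100 * mean(call_pos[pos]))
            expect_equal(r$specificity, 100 * mean(!call_pos[!pos]))
        }
    })
})

test_that("ROC agrees with an independent implementation", {
    skip_if_not_installed("pROC")
    withr::with_seed(23, {
        d <- data.frame(stage = rep(c(0, 4), c(20, 18)),
                        v = c(rnorm(20, 5, 2), rnorm(18, 8, 2)))
        r <- rocAnalysis(d, "v", "4")
        ref <- pROC::roc(d$stage >= 4, d$v, quiet = TRUE,
                         direction = "<")
        expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
        best <- pROC::coords(ref, "best", best.method = "youden",
                             transpose = FALSE)
        expect_equal(r$sensitivity / 100, best$sensitivity[1],
                     tolerance = 1e-9)
        expect_equal(r$specificity / 100, best$specificity[1],
                     tolerance = 1e-9)
    })
})

test_that("ICC(A,1) is 1 on identical raters, penalizes offsets, near 0 on noise", {
    x <- c(5, 7, 9, 11, 13, 15, 18, 20)
    expect_equal(iccInterobserver(x, x)$icc, 1)
    off <- iccInterobserver(x, x + 4)
    expect_lt(off$icc, 1)
    expect_gt(off$icc, 0)           # systematic offset penalized, not fatal
    nulls <- withr::with_seed(31, vapply(seq_len(200), function(i)
        iccInterobserver(rnorm(12), rnorm(12))$icc, numeric(1)))
    expect_lt(abs(mean(nulls)), 0.1)
    expect_error(iccInterobserver(rep(1, 5), rep(1, 5)), "variance")
})

test_that("ICC converges to the variance-component ratio at large n", {
    # subjects var 9, error var 1, no rater effect: ICC(A,1) -> 0.9
    withr::with_seed(37, {
        subj <- rnorm(4000, sd = 3)
        icc <- iccInterobserver(subj + rnorm(4000), subj + rnorm(4000))
        expect_equal(icc$icc, 0.9, tolerance = 0.02)
        expect_true(icc$ci["lower"] < icc$icc & icc$icc < icc$ci["upper"])
    })
})

test_that("Pearson intra-observer correlation behaves at the extremes", {
    x <- c(1, 3, 4, 7, 9)
    expect_equal(pearsonIntraobserver(x, x)$r, 1)
    expect_equal(pearsonIntraobserver(x, -x)$r, -1)
    expect_error(pearsonIntraobserver(x, rep(2, 5)), "variance")
    # sampling distribution around a known correlation
    rs <- withr::with_seed(41, vapply(seq_len(2000), function(i) {
        z <- rnorm(13); e <- rnorm(13)
        pearsonIntraobserver(z, 0.9 * z + sqrt(1 - 0.81) * e)$r
    }, numeric(1)))
    expect_equal(mean(rs), 0.9, tolerance = 0.02)
})

test_that("kappa equals 1 on identity, near 0 on independence, bands partition", {
    a <- rep(0:4, 8)
    expect_equal(cohenKappa(a, a)$kappa, 1)
    expect_equal(cohenKappa(a, a)$band, "excellent")
    k0 <- withr::with_seed(43, cohenKappa(sample(0:4, 2000, TRUE),
                                          sample(0:4, 2000, TRUE)))
    expect_lt(abs(k0$kappa), 0.06)
    expect_equal(k0$band, "poor")
    expect_error(cohenKappa(rep(1, 10), rep(1, 10)), "undefined")
    # band edges: closed upper bounds at 0.60 and 0.80
    expect_equal(kappaBand(0.409), "poor")
    expect_equal(kappaBand(0.41), "moderate")
    expect_equal(kappaBand(0.60), "moderate")
    expect_equal(kappaBand(0.605), "good")
    expect_equal(kappaBand(0.80), "good")
    expect_equal(kappaBand(0.81), "excellent")
})

test_that("kappa value matches an independent implementation", {
    skip_if_not_installed("e1071")
    withr::with_seed(47, {
        a <- sample(0:4, 60, TRUE)
        b <- ifelse(runif(60) < 0.6, a, sample(0:4, 60, TRUE))
        tab <- table(factor(a, 0:4), factor(b, 0:4))
        ref <- e1071::classAgreement(tab)$kappa
        expect_equal(cohenKappa(a, b)$kappa, ref, tolerance = 1e-12)
    })
})

test_that("staging report is deterministic, sized correctly, and flags flat input", {
    coh <- simulateCohort(seed = 13, measurement = "analytic")
    rep1 <- stagingReport(coh)
    expect_equal(unname(rep1$group_sizes), c(16, 11, 13, 13, 10))
    expect_equal(nrow(rep1$roc), 16)        # 4 parameters x 4 splits
    tmp <- withr::local_tempdir()
    writeStagingReport(rep1, file.path(tmp, "a"))
    writeStagingReport(rep1, file.path(tmp, "b"))
    for (f in list.files(file.path(tmp, "a"))) {
        expect_identical(unname(tools::md5sum(file.path(tmp, "a", f))),
                         unname(tools::md5sum(file.path(tmp, "b", f))))
    }
    coh$msd <- 1                            # uninformative column
    rep2 <- stagingReport(coh)
    flat <- rep2$roc[rep2$roc$parameter == "msd", ]
    expect_true(all(flat$auc == 0.5))
    expect_true(all(flat$note == "uninformative"))
    expect_error(stagingReport(coh[, c("stage", "ttp")]),
                 "missing columns")
})
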