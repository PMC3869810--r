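# Staging statistics: stage correlation, nonparametric group comparisons
# with Bonferroni correction, ROC cutoff analysis and observer agreement.

.checkStaged <- function(data, parameter) {
    .stopIfNot(is.data.frame(data) && all(c("stage", parameter) %in%
               names(data)),
               "data must contain columns 'stage' and '", parameter, "'")
    .stopIfNot(all(data$stage %in% 0:4), "stages must lie in 0..4")
    data[[parameter]]
}

#' Spearman correlation between a parameter and fibrosis stage
#'
#' Rank correlation with average-rank tie handling for the repeated stage
#' labels; the p value uses the t approximation with `n - 2` degrees of
#' freedom.
#'
#' @param data data.frame with a `stage` column (0..4) and the parameter
#' @param parameter column name, e.g. `"ttp"`
#' @return list with `rho`, `p` and `n`
#' @export
spearmanStageCorrelation <- function(data, parameter) {
    v <- .checkStaged(data, parameter)
    .stopIfNot(length(v) >= 3L, "need at least 3 observations")
    .stopIfNot(length(unique(data$stage)) >= 2L,
               "need at least 2 distinct stages")
    if (stats::sd(v) == 0)
        stop("parameter is constant; correlation undefined")
    ct <- suppressWarnings(stats::cor.test(v, data$stage,
                                           method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(v))
}

#' Mann-Whitney U test with Bonferroni correction
#'
#' Two-sided rank-sum comparison of two groups: exact p by enumeration
#' when `n1 * n2 <= 400` and the pooled data are tie-free, otherwise the
#' normal approximation with tie and continuity corrections.  The reported
#' U counts pairs where a value of `x` exceeds one of `y` (ties half).
#'
#' @param x,y group values (non-empty)
#' @param family_size Bonferroni family size (default 1: no correction)
#' @return a `TestResult` list: `statistic` (U), `p_raw`, `p_bonferroni`,
#'   `n1`, `n2`, `family_size`
#' @export
mannWhitney <- function(x, y, family_size = 1L) {
    .stopIfNot(length(x) > 0 && length(y) > 0, "both groups must be non-empty")
    .stopIfNot(family_size >= 1, "family_size must be >= 1")
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) * length(y) <= 400) && !ties
    if (stats::sd(c(x, y)) == 0) {
        # degenerate pooled-constant input: no evidence of a difference
        return(structure(list(statistic = length(x) * length(y) / 2,
                              p_raw = 1, p_bonferroni = 1,
                              n1 = length(x), n2 = length(y),
                              family_size = family_size, exact = FALSE),
                         class = "TestResult"))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    structure(list(statistic = unname(wt$statistic), p_raw = wt$p.value,
                   p_bonferroni = min(1, wt$p.value * family_size),
                   n1 = length(x), n2 = length(y),
                   family_size = family_size, exact = exact),
              class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
    cat(sprintf(
        "Mann-Whitney U = %.4g (n1 = %d, n2 = %d, %s), p = %.4g, Bonferroni (x%d) p = %.4g\n",
        x$statistic, x$n1, x$n2, if (x$exact) "exact" else "approximate",
        x$p_raw, x$family_size, x$p_bonferroni))
    invisible(x)
}

# the four grouped-stage splits used for staging
.stageSplits <- function() list(
    "S0 vs S1-4"   = 1L,
    "S0-1 vs S2-4" = 2L,
    "S0-2 vs S3-4" = 3L,
    "S0-3 vs S4"   = 4L)

#' Grouped-stage comparisons of one parameter
#'
#' Mann-Whitney tests of the four adjacent grouped-stage splits
#' (S0 vs S1-4, S0-1 vs S2-4, S0-2 vs S3-4, S0-3 vs S4) with a common
#' Bonferroni family.
#'
#' @param data data.frame with `stage` and the parameter column
#' @param parameter column name
#' @param family_size Bonferroni family size (default 4, the number of
#'   splits per parameter)
#' @return named list of four `TestResult`
#' @export
groupedStageTests <- function(data, parameter, family_size = 4L) {
    v <- .checkStaged(data, parameter)
    lapply(.stageSplits(), function(k) {
        lo <- v[data$stage < k]
        hi <- v[data$stage >= k]
        mannWhitney(lo, hi, family_size = family_size)
    })
}

# rank-method empirical AUC of `values` for the positive class `pos`
# (ties count one half); equals U / (n1 * n2)
.rankAuc <- function(values, pos) {
    n1 <- sum(pos); n0 <- sum(!pos)
    r <- rank(values)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis of one parameter for a stage split
#'
#' Empirical AUC by the rank method (ties count one half), with the
#' positive class being the higher fibrosis stages of the split.  The
#' polarity is auto-oriented so the reported AUC is at least 0.5 and is
#' recorded (`"higher-is-positive"` or `"lower-is-positive"`).  The cutoff
#' maximizes the Youden index over midpoints between adjacent observed
#' values (ties broken towards higher specificity); the reported
#' sensitivity and specificity are exactly those attained on the data when
#' thresholding at the cutoff with the reported polarity.
#'
#' @param data data.frame with `stage` and the parameter column
#' @param parameter column name
#' @param split `">=1"`, `">=2"`, `">=3"` or `"4"`
#' @return an `RocResult` list: `auc`, `cutoff`, `sensitivity` and
#'   `specificity` (percent), `polarity`, `split`, `n_pos`, `n_neg`
#' @export
rocAnalysis <- function(data, parameter,
                        split = c(">=1", ">=2", ">=3", "4")) {
    split <- match.arg(split)
    k <- c(">=1" = 1L, ">=2" = 2L, ">=3" = 3L, "4" = 4L)[[split]]
    v <- .checkStaged(data, parameter)
    pos <- data$stage >= k
    .stopIfNot(any(pos) && any(!pos),
               "both classes of the split must be non-empty")
    auc_raw <- .rankAuc(v, pos)
    higher <- auc_raw >= 0.5
    auc <- if (higher) auc_raw else 1 - auc_raw
    ov <- if (higher) v else -v        # oriented: positive class is high
    u <- sort(unique(ov))
    thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
             u[length(u)] + 1)
    sens <- vapply(thr, function(c0) mean(ov[pos] >= c0), numeric(1))
    spec <- vapply(thr, function(c0) mean(ov[!pos] < c0), numeric(1))
    youden <- sens + spec - 1
    best <- which(youden == max(youden))
    best <- best[which.max(spec[best])]     # tie -> higher specificity
    cutoff <- if (higher) thr[best] else -thr[best]
    structure(list(
        auc = auc, cutoff = cutoff,
        sensitivity = 100 * sens[best], specificity = 100 * spec[best],
        polarity = if (higher) "higher-is-positive" else "lower-is-positive",
        split = split, n_pos = sum(pos), n_neg = sum(!pos)),
        class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
    cat(sprintf(
        "ROC split %s (%s): AUC %.3f, cutoff %.4g, sens %.1f%%, spec %.1f%% (n+ %d, n- %d)\n",
        x$split, x$polarity, x$auc, x$cutoff, x$sensitivity, x$specificity,
        x$n_pos, x$n_neg))
    invisible(x)
}

#' Inter-observer agreement: intraclass correlation
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (ICC(A,1)), with a 95 percent confidence interval from the
#' F-distribution bounds.
#'
#' @param obs1,obs2 paired measurements by two observers (n >= 3)
#' @return list with `icc`, `ci` (length 2) and `n`
#' @export
iccInterobserver <- function(obs1, obs2) {
    .stopIfNot(length(obs1) == length(obs2), "observations must be paired")
    n <- length(obs1)
    .stopIfNot(n >= 3L, "need at least 3 paired observations")
    m <- cbind(obs1, obs2)
    if (stats::var(as.vector(m)) == 0)
        stop("zero total variance; ICC undefined")
    k <- 2
    row_m <- rowMeans(m); col_m <- colMeans(m); grand <- mean(m)
    msr <- k * sum((row_m - grand)^2) / (n - 1)
    msc <- n * sum((col_m - grand)^2) / (k - 1)
    mse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # F-based CI (two-way random, absolute agreement, single measure)
    alpha <- 0.05
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    fj <- msc / mse
    v <- (a * fj + b)^2 /
         (a^2 * fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    list(icc = icc, ci = c(lower = max(-1, lower), upper = min(1, upper)),
         n = n)
}

#' Intra-observer agreement: Pearson correlation
#'
#' @param meas1,meas2 paired repeated measurements (n >= 3)
#' @return list with `r`, `p` and `n`
#' @export
pearsonIntraobserver <- function(meas1, meas2) {
    .stopIfNot(length(meas1) == length(meas2), "measurements must be paired")
    .stopIfNot(length(meas1) >= 3L, "need at least 3 paired measurements")
    if (stats::sd(meas1) == 0 || stats::sd(meas2) == 0)
        stop("zero variance; correlation undefined")
    ct <- stats::cor.test(meas1, meas2)
    list(r = unname(ct$estimate), p = ct$p.value, n = length(meas1))
}

#' Agreement band for a kappa value
#'
#' The conventional interpretation bands: below 0.41 poor, 0.41-0.60
#' moderate, above 0.60 up to 0.80 good, above 0.80 excellent (upper
#' bounds closed, so 0.80 is still "good").
#'
#' @param kappa a kappa value in `[-1, 1]`
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"`
#' @export
kappaBand <- function(kappa) {
    if (kappa < 0.41) "poor"
    else if (kappa <= 0.60) "moderate"
    else if (kappa <= 0.80) "good"
    else "excellent"
}

#' Cohen's kappa for paired ordinal stage labels
#'
#' Unweighted kappa with an asymptotic (Fleiss) standard error for the 95
#' percent confidence interval, and the conventional interpretation band.
#'
#' @param labelsA,labelsB paired categorical labels (e.g. METAVIR stages
#'   from two graders)
#' @return list with `kappa`, `ci`, `band`, `n`
#' @export
cohenKappa <- function(labelsA, labelsB) {
    .stopIfNot(length(labelsA) == length(labelsB), "labels must be paired")
    n <- length(labelsA)
    lev <- sort(unique(c(labelsA, labelsB)))
    if (length(lev) < 2L)
        stop("a single common category gives expected agreement 1; ",
             "kappa undefined")
    tab <- table(factor(labelsA, lev), factor(labelsB, lev)) / n
    po <- sum(diag(tab))
    pa <- rowSums(tab); pb <- colSums(tab)
    pe <- sum(pa * pb)
    kappa <- (po - pe) / (1 - pe)
    # Fleiss-Cohen-Everitt asymptotic variance
    aa <- sum(diag(tab) * (1 - (pa + pb) * (1 - kappa))^2)
    bb <- 0
    for (i in seq_along(lev)) for (j in seq_along(lev)) if (i != j)
        bb <- bb + tab[i, j] * (pb[i] + pa[j])^2
    bb <- (1 - kappa)^2 * bb
    cc <- (kappa - pe * (1 - kappa))^2
    se <- sqrt(max(aa + bb - cc, 0) / (n * (1 - pe)^4))
    ci <- pmin(1, pmax(-1, kappa + c(-1, 1) * stats::qnorm(0.975) * se))
    list(kappa = kappa, ci = c(lower = ci[1], upper = ci[2]),
         band = kappaBand(kappa), n = n)
}

#' Simulate per-stage parameter values from a calibration
#'
#' Draws plain normal values per stage with the calibration means/SDs and
#' group sizes: the group-statistics simulation used to reproduce the
#' published correlation and ROC summaries.
#'
#' @param parameter `"ttp"`, `"pei"`, `"msi"` or `"msd"`
#' @param calib a [StageCalibration-class]
#' @param sizes optional per-stage sizes (default: the calibration's)
#' @param seed optional integer seed
#' @return data.frame with columns `stage` and `value`
#' @export
simulateStageValues <- function(parameter, calib = defaultStageCalibration(),
                                sizes = NULL, seed = NULL) {
    tb <- calib@table[order(calib@table$stage), ]
    if (is.null(sizes)) sizes <- tb$n
    mu <- tb[[paste0(parameter, "_mean")]]
    sd <- tb[[paste0(parameter, "_sd")]]
    .withSeed(seed, data.frame(
        stage = rep(0:4, sizes),
        value = stats::rnorm(sum(sizes), rep(mu, sizes), rep(sd, sizes))))
}

#' Replicate-averaged empirical AUC of a calibrated simulation
#'
#' Per replicate, draws per-stage values via [simulateStageValues()] and
#' computes the rank-method AUC for the given split; returns the mean over
#' replicates.
#'
#' @param parameter parameter name
#' @param split positive class is `stage >= split` (1..4)
#' @param n_rep number of replicates (default 2000)
#' @param calib a [StageCalibration-class]
#' @param sizes optional per-stage sizes
#' @param seed integer seed for the whole simulation
#' @return mean AUC
#' @export
simulateRocAuc <- function(parameter = "ttp", split = 1L, n_rep = 2000L,
                           calib = defaultStageCalibration(), sizes = NULL,
                           seed = NULL) {
    .withSeed(seed, {
        mean(vapply(seq_len(n_rep), function(i) {
            d <- simulateStageValues(parameter, calib, sizes)
            .rankAuc(d$value, d$stage >= split)
        }, numeric(1)))
    })
}

#' Replicate-averaged Spearman stage correlation of a calibrated simulation
#'
#' @inheritParams simulateRocAuc
#' @return mean Spearman rho between value and stage
#' @export
simulateStageRho <- function(parameter = "ttp", n_rep = 2000L,
                             calib = defaultStageCalibration(), sizes = NULL,
                             seed = NULL) {
    .withSeed(seed, {
        mean(vapply(seq_len(n_rep), function(i) {
            d <- simulateStageValues(parameter, calib, sizes)
            stats::cor(d$value, d$stage, method = "spearman")
        }, numeric(1)))
    })
}

#' Full staging report of a cohort
#'
#' Emits the standard summary of a staged cohort: per-stage group means and
#' SDs, grouped-stage Mann-Whitney p values with Bonferroni correction,
#' ROC summaries for the four stage splits, and the Spearman stage
#' correlations.  Repeat-stage observations are dropped first (so group
#' sizes match the deduplicated cohort) unless `dedup = FALSE`.
#'
#' @param cohort cohort data.frame (from [simulateCohort()] or a CSV with
#'   the same columns)
#' @param parameters parameter columns to report
#' @param dedup drop repeat-stage observations first
#' @param family_size Bonferroni family for the grouped tests
#' @return a `stagingReport` list with elements `group_sizes`,
#'   `group_stats`, `correlations`, `grouped_tests` and `roc`
#' @export
stagingReport <- function(cohort, parameters = c("ttp", "pei", "msi", "msd"),
                          dedup = TRUE, family_size = 4L) {
    need <- c("stage", parameters)
    miss <- setdiff(need, names(cohort))
    if (length(miss))
        stop("cohort is missing columns: ", paste(miss, collapse = ", "))
    if (dedup && "is_repeat_stage" %in% names(cohort))
        cohort <- deduplicateCohort(cohort)
    sizes <- table(factor(cohort$stage, levels = 0:4))
    gs <- do.call(rbind, lapply(parameters, function(p) {
        agg_m <- tapply(cohort[[p]], factor(cohort$stage, 0:4), mean)
        agg_s <- tapply(cohort[[p]], factor(cohort$stage, 0:4), stats::sd)
        data.frame(parameter = p, stage = 0:4,
                   n = as.integer(sizes), mean = as.numeric(agg_m),
                   sd = as.numeric(agg_s))
    }))
    corr <- do.call(rbind, lapply(parameters, function(p) {
        ct <- tryCatch(spearmanStageCorrelation(cohort, p),
                       error = function(e) list(rho = NA_real_,
                                                p = NA_real_))
        data.frame(parameter = p, rho = ct$rho, p = ct$p)
    }))
    grouped <- do.call(rbind, lapply(parameters, function(p) {
        res <- groupedStageTests(cohort, p, family_size = family_size)
        data.frame(parameter = p, split = names(res),
                   U = vapply(res, function(r) r$statistic, numeric(1)),
                   p_raw = vapply(res, function(r) r$p_raw, numeric(1)),
                   p_bonferroni = vapply(res, function(r) r$p_bonferroni,
                                         numeric(1)),
                   row.names = NULL)
    }))
    roc <- do.call(rbind, lapply(parameters, function(p) {
        do.call(rbind, lapply(c(">=1", ">=2", ">=3", "4"), function(s) {
            r <- rocAnalysis(cohort, p, s)
            data.frame(parameter = p, split = s, auc = r$auc,
                       cutoff = r$cutoff, sensitivity = r$sensitivity,
                       specificity = r$specificity, polarity = r$polarity,
                       note = if (r$auc == 0.5) "uninformative" else "")
        }))
    }))
    structure(list(group_sizes = stats::setNames(as.integer(sizes),
                                                 paste0("S", 0:4)),
                   group_stats = gs, correlations = corr,
                   grouped_tests = grouped, roc = roc),
              class = "stagingReport")
}

#' @export
print.stagingReport <- function(x, ...) {
    cat("Staging report\n  group sizes:",
        paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
              collapse = " "), "\n")
    cat("  correlations (Spearman rho vs stage):\n")
    print(x$correlations, row.names = FALSE, digits = 3)
    cat("  ROC (Youden cutoffs):\n")
    print(x$roc[c("parameter", "split", "auc", "cutoff", "sensitivity",
                  "specificity")], row.names = FALSE, digits = 3)
    invisible(x)
}

#' Write a staging report to disk
#'
#' Writes `report.json` plus one CSV per table (group statistics, grouped
#' tests, ROC summary, correlations) into `dir`.  Output is deterministic:
#' identical reports give byte-identical files.
#'
#' @param report a `stagingReport`
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
writeStagingReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(report$group_stats,
                     file.path(dir, "group_stats.csv"), row.names = FALSE)
    utils::write.csv(report$grouped_tests,
                     file.path(dir, "grouped_tests.csv"), row.names = FALSE)
    utils::write.csv(report$roc, file.path(dir, "roc.csv"),
                     row.names = FALSE)
    utils::write.csv(report$correlations,
                     file.path(dir, "correlations.csv"), row.names = FALSE)
    invisible(dir)
}
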