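#' Construct a cohort design
#'
#' @param n_animals animals at baseline
#' @param weekends follow-up weeks (first is baseline)
#' @param deaths deaths per inter-weekend interval
#' @param stage_counts weekends x 5 matrix of per-stage observation counts
#' @param repeat_counts weekends x 5 matrix of repeat-stage (starred) counts;
#'   defaults to all zero
#' @param weight_mean,weight_sd per-weekend body-weight normals in kg
#'   (decorative)
#' @return a [CohortDesign-class]
#' @export
CohortDesign <- function(n_animals, weekends, deaths, stage_counts,
                         repeat_counts = NULL, weight_mean = NULL,
                         weight_sd = NULL) {
    nw <- length(weekends)
    if (is.null(repeat_counts)) repeat_counts <- matrix(0, nw, 5)
    if (is.null(weight_mean)) weight_mean <- rep(23, nw)
    if (is.null(weight_sd)) weight_sd <- rep(2, nw)
    new("CohortDesign", n_animals = n_animals, weekends = weekends,
        deaths = deaths, stage_counts = as.matrix(stage_counts),
        repeat_counts = as.matrix(repeat_counts),
        weight_mean = weight_mean, weight_sd = weight_sd)
}

#' Default longitudinal design (published piglet cohort)
#'
#' Sixteen animals followed on weekends 0, 5, 9, 16 and 21 with 1, 2 and 4
#' deaths in the last three intervals; per-weekend stage composition and
#' repeat-stage counts as published.  Deduplicating repeat-stage
#' observations yields per-stage group sizes 16/11/13/13/10.
#'
#' @return a [CohortDesign-class]
#' @export
defaultCohortDesign <- function() {
    sc <- rbind(c(16, 0, 0, 0, 0),
                c(3, 8, 5, 0, 0),
                c(0, 3, 7, 5, 0),
                c(0, 1, 1, 7, 4),
                c(0, 1, 1, 1, 6))
    rc <- rbind(c(0, 0, 0, 0, 0),
                c(3, 0, 0, 0, 0),
                c(0, 0, 0, 0, 0),
                c(0, 1, 0, 0, 0),
                c(0, 1, 1, 0, 0))
    dimnames(sc) <- dimnames(rc) <- list(NULL, paste0("S", 0:4))
    CohortDesign(n_animals = 16, weekends = c(0, 5, 9, 16, 21),
                 deaths = c(0, 1, 2, 4), stage_counts = sc,
                 repeat_counts = rc,
                 weight_mean = c(22.0, 24.1, 24.0, 25.3, 23.5),
                 weight_sd   = c(1.31, 2.41, 2.45, 2.81, 1.78))
}

# Assign next-weekend stages to surviving animals given target stage counts
# and repeat ("star") counts.  Stars are filled from animals already at the
# stage; new-stage slots are filled from strictly lower stages, highest
# first, never dipping into animals reserved for a lower stage's own
# starred slots.  With `allow_fallback` any remainder is filled by
# same-stage animals (kept unflagged, matching the published table, which
# leaves one forced same-stage transition unstarred).  Returns NULL when
# infeasible.
.assignStages <- function(cur, target, stars, allow_fallback = FALSE) {
    ids <- names(cur)
    avail <- lapply(0:4, function(s) sample(ids[cur == s]))
    reserve <- as.integer(stars)               # star slots not yet filled
    names(avail) <- as.character(0:4)
    stage_out <- integer(0); id_out <- character(0); star_out <- logical(0)
    grab <- function(s, k, new_stage, is_star) {
        take <- avail[[as.character(s)]][seq_len(k)]
        avail[[as.character(s)]] <<- setdiff(avail[[as.character(s)]], take)
        id_out <<- c(id_out, take)
        stage_out <<- c(stage_out, rep(new_stage, k))
        star_out <<- c(star_out, rep(is_star, k))
    }
    for (s in 4:0) {
        need_star <- stars[s + 1]
        need_new <- target[s + 1] - need_star
        if (need_new < 0) return(NULL)
        if (length(avail[[as.character(s)]]) < need_star) return(NULL)
        if (need_star > 0) {
            grab(s, need_star, s, TRUE)
            reserve[s + 1] <- 0L
        }
        for (lower in rev(seq_len(s)) - 1) {   # s-1, s-2, ..., 0
            if (need_new == 0) break
            free <- length(avail[[as.character(lower)]]) - reserve[lower + 1]
            k <- min(need_new, max(free, 0))
            if (k > 0) {
                grab(lower, k, s, FALSE)
                need_new <- need_new - k
            }
        }
        if (need_new > 0) {                    # forced same-stage remainder
            if (!allow_fallback ||
                length(avail[[as.character(s)]]) < need_new) return(NULL)
            grab(s, need_new, s, FALSE)
        }
    }
    if (any(lengths(avail) > 0)) return(NULL)
    o <- order(id_out)
    list(stage = stats::setNames(stage_out[o], id_out[o]),
         star = stats::setNames(star_out[o], id_out[o]))
}

# pick d deaths among survivors such that the next transition is feasible;
# strict assignments are preferred, the same-stage fallback is a last
# resort; random tries first, then exhaustive enumeration
.chooseDeaths <- function(cur, d, target, stars, tries = 200L) {
    ids <- names(cur)
    attempt <- function(dead, fb) {
        a <- .assignStages(cur[setdiff(ids, dead)], target, stars,
                           allow_fallback = fb)
        if (!is.null(a)) list(dead = dead, assign = a) else NULL
    }
    if (d == 0) {
        res <- attempt(character(0), FALSE)
        if (is.null(res)) res <- attempt(character(0), TRUE)
        if (is.null(res)) stop("cohort design transition is infeasible")
        return(res)
    }
    combos <- NULL
    for (fb in c(FALSE, TRUE)) {
        for (i in seq_len(tries)) {
            res <- attempt(sample(ids, d), fb)
            if (!is.null(res)) return(res)
        }
        if (is.null(combos))
            combos <- sample(utils::combn(ids, d, simplify = FALSE))
        for (dead in combos) {
            res <- attempt(dead, fb)
            if (!is.null(res)) return(res)
        }
    }
    stop("cohort design transition is infeasible for any choice of deaths")
}

#' Simulate a longitudinal staged cohort
#'
#' Builds animal stage trajectories consistent with the design's per-weekend
#' stage and repeat-stage counts under monotone (non-decreasing) fibrosis
#' progression, assigns deaths to randomly chosen stage-consistent animals,
#' and attaches perfusion parameters to every observation: either the
#' analytic ground truth of a freshly calibrated model (`measurement =
#' "analytic"`), estimates from the model curve sampled on the protocol
#' grid (`"curve"`, the default), or estimates from a fully rendered
#' phantom measured with three-section spleen ROIs (`"rendered"`).
#'
#' @param design a [CohortDesign-class]
#' @param calib a [StageCalibration-class]
#' @param protocol an [AcquisitionProtocol-class]
#' @param seed optional integer seed for the whole simulation
#' @param measurement `"analytic"`, `"curve"` or `"rendered"`
#' @param noise_sd Gaussian noise SD for the `"curve"` and `"rendered"`
#'   paths (a.u.)
#' @param motion_jitter_px frame jitter for the `"rendered"` path
#' @param ... further arguments passed to [calibrateModel()] (e.g.
#'   `t_onset`, `pei_scale`, `slope_scale`)
#' @return a `data.frame` with one row per observation: `animal_id`,
#'   `weekend`, `stage`, `is_repeat_stage`, `body_weight`, `ttp`, `pei`,
#'   `msi`, `msd`
#' @export
#' @examples
#' coh <- simulateCohort(seed = 1)
#' nrow(coh)                                # 69 raw observations
#' table(coh$stage[!coh$is_repeat_stage])   # 16 11 13 13 10
simulateCohort <- function(design = defaultCohortDesign(),
                           calib = defaultStageCalibration(),
                           protocol = AcquisitionProtocol(), seed = NULL,
                           measurement = c("curve", "analytic", "rendered"),
                           noise_sd = 0, motion_jitter_px = 0, ...) {
    measurement <- match.arg(measurement)
    validObject(design)
    .withSeed(seed, {
        nw <- length(design@weekends)
        ids <- sprintf("A%02d", seq_len(design@n_animals))
        base_counts <- design@stage_counts[1, ]
        .stopIfNot(sum(base_counts) == design@n_animals,
                   "baseline stage counts must cover all animals")
        cur <- stats::setNames(rep(0:4, base_counts), sample(ids))
        cur <- cur[order(names(cur))]
        star <- stats::setNames(rep(FALSE, length(cur)), names(cur))
        rows <- list()
        for (w in seq_len(nw)) {
            if (w > 1) {
                prev_stage <- cur
                ch <- .chooseDeaths(cur, design@deaths[w - 1],
                                    design@stage_counts[w, ],
                                    design@repeat_counts[w, ])
                cur <- ch$assign$stage
                star <- ch$assign$star
                if (any(cur < prev_stage[names(cur)]))
                    stop("internal error: non-monotone stage assignment")
            }
            bw <- stats::rnorm(length(cur), design@weight_mean[w],
                               design@weight_sd[w])
            pars <- lapply(cur, function(s)
                .simulatedParams(s, calib, protocol, measurement,
                                 noise_sd, motion_jitter_px, ...))
            rows[[w]] <- data.frame(
                animal_id = names(cur),
                weekend = design@weekends[w],
                stage = unname(cur),
                is_repeat_stage = unname(star),
                body_weight = bw,
                do.call(rbind, lapply(pars, as.data.frame)),
                row.names = NULL)
        }
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out[c("animal_id", "weekend", "stage", "is_repeat_stage",
              "body_weight", "ttp", "pei", "msi", "msd")]
    })
}

# one simulated measurement for a stage
.simulatedParams <- function(stage, calib, protocol, measurement, noise_sd,
                             motion_jitter_px, pei_scale = 0.001,
                             slope_scale = 250, ...) {
    model <- calibrateModel(stage, calib, protocol, pei_scale = pei_scale,
                            slope_scale = slope_scale, ...)
    switch(measurement,
        analytic = analyticParams(model, protocol, pei_scale = pei_scale,
                                  slope_scale = slope_scale),
        curve = {
            y <- enhancementSignal(model, frameTimes(protocol))
            if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
            curveParams(SignalTimeCurve(frameTimes(protocol), y),
                        pei_scale = pei_scale, slope_scale = slope_scale)
        },
        rendered = {
            s <- renderSeries(model, protocol = protocol,
                              noise_sd = noise_sd,
                              motion_jitter_px = motion_jitter_px)
            measureSpleen(s, pei_scale = pei_scale,
                          slope_scale = slope_scale)
        })
}

#' Drop repeat-stage observations
#'
#' Keeps, per animal and stage, only the observation at which the stage was
#' first recorded (the repeat-stage flag of the design), giving the
#' deduplicated groups used for all between-stage statistics.
#'
#' @param cohort a cohort `data.frame` from [simulateCohort()]
#' @return the deduplicated `data.frame`
#' @export
deduplicateCohort <- function(cohort) {
    cohort[!cohort$is_repeat_stage, , drop = FALSE]
}

#' Per-stage group sizes of a cohort
#'
#' @param cohort a cohort `data.frame`
#' @param dedup drop repeat-stage observations first (default `TRUE`)
#' @return named integer vector of counts for stages 0..4
#' @export
stageGroupSizes <- function(cohort, dedup = TRUE) {
    if (dedup) cohort <- deduplicateCohort(cohort)
    counts <- table(factor(cohort$stage, levels = 0:4))
    stats::setNames(as.integer(counts), paste0("S", 0:4))
}
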