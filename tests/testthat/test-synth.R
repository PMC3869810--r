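test_that("protocol geometry yields the expected image count", {
    p <- std_protocol()
    expect_equal(nFrames(p), 40L)
    expect_equal(length(frameTimes(p)) * p@n_sections, 480)
    expect_error(AcquisitionProtocol(duration = 5), "4 frames")
    expect_error(AcquisitionProtocol(frame_interval = 0), "positive")
})

test_that("enhancement signal is baseline before onset and peaks by construction", {
    m <- std_model()
    expect_equal(enhancementSignal(m, c(0, 5, 10)), rep(100, 3))
    tt <- seq(0, 107.9, by = 0.01)
    s <- enhancementSignal(m, tt)
    expect_equal(max(s), 200)
    expect_equal(tt[which.max(s)], 64, tolerance = 1e-6)
    expect_error(enhancementSignal(m, -1), "negative")
})

test_that("washout branch matches the gamma-variate evaluated analytically", {
    # alpha = 2, full washout: enhancement at tau = 2 is A * 4 * exp(-2)
    m <- EnhancementModel(shape_alpha = 2, washout_fraction = 1,
                          amplitude = 50, t_onset = 10, t_peak_offset = 40)
    t2 <- 10 + 2 * 40
    expect_equal(enhancementSignal(m, t2) - 100, 50 * 4 * exp(-2),
                 tolerance = 1e-12)
    # partial washout blends towards the plateau, continuous at the peak
    m2 <- std_model()
    eps <- 1e-9
    expect_equal(enhancementSignal(m2, 64 - eps),
                 enhancementSignal(m2, 64 + eps), tolerance = 1e-6)
})

test_that("analytic parameters are exact for degenerate models and match a closed form", {
    p <- std_protocol()
    flat <- EnhancementModel(amplitude = 0)
    ap0 <- analyticParams(flat, p)
    expect_equal(ap0@pei, 0)
    expect_equal(ap0@msi, 0)
    expect_equal(ap0@msd, 0)
    m <- std_model()
    ap <- analyticParams(m, p)
    expect_equal(ap@ttp, 54)
    # dense-grid integral against the incomplete-gamma closed form
    expect_equal(ap@pei, closed_form_pei(m, max(frameTimes(p))),
                 tolerance = 1e-4)
    # grid refinement: 10x finer grid moves the integral by < 0.1%
    ap_fine <- analyticParams(m, p, grid_factor = 1000)
    expect_lt(abs(ap@pei - ap_fine@pei) / ap_fine@pei, 0.001)
})

test_that("calibration draws reproduce requested values and are deterministic", {
    calib <- defaultStageCalibration()
    # degenerate draw: zero SDs pin the model at the stage means
    tb <- calib@table
    tb$ttp_sd <- 0; tb$pei_sd <- 0
    m0 <- calibrateModel(0, StageCalibration(tb), seed = 1)
    expect_equal(m0@t_peak_offset, 63.97)
    expect_equal(analyticParams(m0)@pei, 6.78, tolerance = 0.005)
    # determinism
    m1 <- calibrateModel(3, seed = 42)
    m2 <- calibrateModel(3, seed = 42)
    expect_identical(m1, m2)
})

test_that("calibrated TTP draws converge to the truncated-normal mean", {
    calib <- defaultStageCalibration()
    p <- std_protocol()
    draws <- withr::with_seed(11, vapply(seq_len(10000), function(i)
        calibrateModel(4, calib, p)@t_peak_offset, numeric(1)))
    oracle <- spleenDCE:::.truncnormMean(88.29, 4.9,
                                         lower = 2 * 2.7,
                                         upper = 108 - 10)
    expect_lt(abs(mean(draws) - oracle), 0.5)
})

test_that("rendered series conserve image count and are noiseless-exact", {
    m <- std_model()
    s <- renderSeries(m)
    expect_equal(prod(dim(seriesData(s))[3:4]), 480)
    # a voxel inside the spleen (outside the vessel) carries the model curve
    g <- s@geometry
    k <- g$largest_sections[2]
    vox <- which(g$spleen[, , k] & !g$vessel[, , k], arr.ind = TRUE)[1, ]
    expect_equal(seriesData(s)[vox[1], vox[2], k, ],
                 enhancementSignal(m, frameTimes(s)), tolerance = 1e-12)
    # jitter and noise are reproducible under the same seed
    s1 <- renderSeries(m, noise_sd = 2, motion_jitter_px = 2, seed = 5)
    s2 <- renderSeries(m, noise_sd = 2, motion_jitter_px = 2, seed = 5)
    expect_identical(seriesData(s1), seriesData(s2))
    s3 <- renderSeries(m, noise_sd = 2, motion_jitter_px = 2, seed = 6)
    expect_false(identical(seriesData(s1), seriesData(s3)))
})

test_that("phantom geometry outside the field is rejected", {
    expect_error(phantomGeometry(width = 24, height = 24,
                                 spleen_semiaxes = c(16, 10)),
                 "outside the field")
})

test_that("default cohort reproduces the raw and deduplicated bookkeeping", {
    coh <- simulateCohort(seed = 3, measurement = "analytic")
    expect_equal(nrow(coh), 69)              # 16+16+15+13+9
    expect_equal(unname(stageGroupSizes(coh)), c(16, 11, 13, 13, 10))
    expect_equal(sum(coh$is_repeat_stage), 6)
    # monotone progression per animal
    for (id in unique(coh$animal_id)) {
        st <- coh$stage[coh$animal_id == id][order(coh$weekend[coh$animal_id == id])]
        expect_true(all(diff(st) >= 0))
    }
    # weekend survivor counts follow the death schedule
    expect_equal(as.integer(table(coh$weekend)), c(16, 16, 15, 13, 9))
})

test_that("cohort without deaths or progression flags every later observation", {
    sc <- matrix(rep(c(2L, 2L, 2L, 2L, 2L), 2), 2, 5, byrow = TRUE)
    design <- CohortDesign(n_animals = 10, weekends = c(0, 5), deaths = 0,
                           stage_counts = sc,
                           repeat_counts = rbind(rep(0L, 5), rep(2L, 5)))
    coh <- simulateCohort(design, seed = 1, measurement = "analytic")
    later <- coh[coh$weekend > 0, ]
    expect_true(all(later$is_repeat_stage))
    expect_equal(nrow(later), 10)
})

test_that("cohort simulation is deterministic under a fixed seed", {
    a <- simulateCohort(seed = 9, measurement = "analytic")
    b <- simulateCohort(seed = 9, measurement = "analytic")
    expect_identical(a, b)
})

test_that("infeasible transition tables are rejected", {
    # stage regression: 2 animals at S2 at baseline cannot all be S0 later
    sc <- rbind(c(0L, 0L, 2L, 0L, 0L), c(2L, 0L, 0L, 0L, 0L))
    design <- CohortDesign(n_animals = 2, weekends = c(0, 5), deaths = 0,
                           stage_counts = sc)
    expect_error(simulateCohort(design, seed = 1, measurement = "analytic"),
                 "infeasible")
})
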