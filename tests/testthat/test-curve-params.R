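test_that("smoothing is identity at window 1, preserves constants, averages steps", {
    crv <- model_curve()
    expect_identical(preprocessCurve(crv, 1), crv)
    const <- SignalTimeCurve(frameTimes(std_protocol()), rep(7, 40))
    expect_equal(curveIntensities(preprocessCurve(const, 5)), rep(7, 40))
    step <- SignalTimeCurve(0:9, c(rep(0, 5), rep(10, 5)))
    sm <- preprocessCurve(step, 3)
    expect_equal(curveIntensities(sm)[5], mean(c(0, 0, 10)))
    expect_equal(curveIntensities(sm)[6], mean(c(0, 10, 10)))
    expect_error(preprocessCurve(step, 4), "odd")
    expect_error(preprocessCurve(step, 11), "larger")
})

test_that("onset detection follows the sustained-threshold rule", {
    # onset exactly on frame 4 (10.8 s): that frame is still baseline, so
    # detection lands on the first strictly enhanced frame
    m <- EnhancementModel(t_onset = 10.8)
    crv <- model_curve(m)
    expect_equal(detectOnset(crv), 13.5)
    # noiseless default model: onset between frames 8.1 and 10.8
    expect_equal(detectOnset(model_curve()), 10.8)
    # flat curve: nothing to detect
    flat <- SignalTimeCurve(frameTimes(std_protocol()), rep(100, 40))
    expect_error(detectOnset(flat), "no enhancement")
    # a single-frame spike shorter than m_consecutive is ignored
    y <- rep(100, 40); y[10] <- 150
    spike <- SignalTimeCurve(frameTimes(std_protocol()), y)
    expect_error(detectOnset(spike), "no enhancement")
})

test_that("TTP lands within one frame of the generator truth", {
    crv <- model_curve()           # true TTP 54 s
    onset <- detectOnset(crv)
    expect_lt(abs(computeTTP(crv, onset) - 54), 2.7)
    # monotone increasing curve: peak at the final frame
    tt <- frameTimes(std_protocol())
    inc <- SignalTimeCurve(tt, seq(100, 200, length.out = 40))
    expect_equal(computeTTP(inc, 10.8), max(tt) - 10.8)
    # earliest frame wins on ties
    y <- c(rep(100, 3), rep(100, 2), rep(180, 2), rep(150, 33))
    tie <- SignalTimeCurve(tt, y)
    expect_equal(computeTTP(tie, tt[6]), 0)
})

test_that("PEI matches closed-form areas and the analytic oracle", {
    tt <- seq(0, 105.3, by = 2.7)
    # triangle rising 0 -> 100 over 27 s then back: area exactly 2700
    tri <- approx(c(0, 27, 54, 105.3), c(0, 100, 0, 0), xout = tt)$y
    crv <- SignalTimeCurve(tt, tri)
    expect_equal(computePEI(crv, 0, pei_scale = 1), 2700)
    expect_equal(computePEI(crv, 0, pei_scale = 0.001), 2.7)
    # flat curve integrates to zero
    flat <- SignalTimeCurve(tt, rep(50, length(tt)))
    expect_equal(computePEI(flat, 0, pei_scale = 1), 0)
    # noiseless model curve against the dense-grid analytic truth
    m <- std_model()
    est <- computePEI(model_curve(m), detectOnset(model_curve(m)))
    truth <- analyticParams(m)@pei
    expect_lt(abs(est - truth) / truth, 0.02)
})

test_that("maximum slopes recover linear segments and the analytic oracle", {
    tt <- seq(0, 105.3, by = 2.7)
    # rise to a peak of 100 over [10.8, 54], then linear fall of slope -1/s
    y <- approx(c(0, 10.8, 54, 105.3), c(0, 0, 100, 100 - 51.3),
                xout = tt)$y
    crv <- SignalTimeCurve(tt, y)
    sl <- computeMaxSlopes(crv, 10.8, slope_scale = 1)
    # peak-normalized: peak enhancement is 100, so slope 1/s -> 0.01
    expect_equal(unname(sl["msd"]), 1 / 100, tolerance = 1e-9)
    # flat post-peak: no washout
    y2 <- approx(c(0, 10.8, 54, 105.3), c(0, 0, 100, 100), xout = tt)$y
    sl2 <- computeMaxSlopes(SignalTimeCurve(tt, y2), 10.8, slope_scale = 1)
    expect_equal(unname(sl2["msd"]), 0)
    # peak on the final frame: MSD 0 with a warning
    inc <- SignalTimeCurve(tt, seq(0, 100, length.out = length(tt)))
    expect_warning(sl3 <- computeMaxSlopes(inc, 0, slope_scale = 1),
                   "final frame")
    expect_equal(unname(sl3["msd"]), 0)
    # noiseless model vs analytic truth (discretization bound)
    m <- std_model()
    crv_m <- model_curve(m)
    slm <- computeMaxSlopes(crv_m, detectOnset(crv_m))
    truth <- analyticParams(m)
    expect_lt(abs(slm["msi"] - truth@msi) / truth@msi, 0.05)
    expect_lt(abs(slm["msd"] - truth@msd) / truth@msd, 0.05)
})

test_that("TTP and PEI obey the noiseless oracle bounds across all stages", {
    withr::with_seed(21, {
        for (stage in 0:4) {
            m <- calibrateModel(stage)
            truth <- analyticParams(m)
            est <- suppressWarnings(curveParams(model_curve(m)))
            expect_lt(abs(est@ttp - truth@ttp), 2.7)
            expect_lt(abs(est@pei - truth@pei) / truth@pei, 0.02)
        }
    })
})

test_that("slopes obey the 5% oracle bound when the washout is fully sampled", {
    # the wash-out slope extremum sits ~1/3 TTP after the peak; with the
    # default 108 s window it is observed for true TTP up to ~70 s
    for (ttp_true in c(40, 54, 68)) {
        m <- std_model(t_peak_offset = ttp_true, amplitude = 85)
        truth <- analyticParams(m)
        est <- curveParams(model_curve(m))
        expect_lt(abs(est@msi - truth@msi) / truth@msi, 0.05)
        expect_lt(abs(est@msd - truth@msd) / truth@msd, 0.05)
    }
})

test_that("parameters are invariant to intensity shift and scale as stated", {
    withr::with_seed(33, {
        for (i in 1:5) {
            m <- calibrateModel(sample(0:4, 1))
            crv <- model_curve(m)
            base <- curveParams(crv)
            shift <- curveParams(SignalTimeCurve(curveTimes(crv),
                                                 curveIntensities(crv) + 37.5))
            expect_equal(shift@ttp, base@ttp)
            expect_equal(shift@pei, base@pei, tolerance = 1e-9)
            expect_equal(shift@msi, base@msi, tolerance = 1e-9)
            expect_equal(shift@msd, base@msd, tolerance = 1e-9)
            sc <- curveParams(SignalTimeCurve(curveTimes(crv),
                                              curveIntensities(crv) * 3.2))
            expect_equal(sc@ttp, base@ttp)
            expect_equal(sc@pei, base@pei * 3.2, tolerance = 1e-9)
            expect_equal(sc@msi, base@msi, tolerance = 1e-9)
            expect_equal(sc@msd, base@msd, tolerance = 1e-9)
        }
    })
})

test_that("delaying a curve shifts its landmarks but not TTP", {
    m <- std_model()
    m_late <- std_model(t_onset = 10 + 8.1)
    a <- curveParams(model_curve(m))
    b <- curveParams(model_curve(m_late))
    expect_equal(b@onset_time - a@onset_time, 8.1)
    expect_equal(b@peak_time - a@peak_time, 8.1, tolerance = 2.7)
    expect_equal(b@ttp, a@ttp, tolerance = 2.7)
})

test_that("TTP stays within one frame under mild noise (median over curves)", {
    m <- std_model()
    errs <- withr::with_seed(17, vapply(seq_len(500), function(i) {
        crv <- SignalTimeCurve(
            frameTimes(std_protocol()),
            enhancementSignal(m, frameTimes(std_protocol())) +
                rnorm(40, 0, 0.02 * m@amplitude))
        est <- curveParams(crv, smooth_window = 7)
        abs(est@ttp - 54)
    }, numeric(1)))
    expect_lte(median(errs), 2.7 + 1e-9)   # <= one frame (float guard)
})
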