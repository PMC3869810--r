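#' Smooth a signal-time curve
#'
#' Centered moving-average smoothing with symmetric window shrinking at the
#' endpoints; times and length are unchanged and constants are preserved.
#' `smooth_window = 1` is the identity.
#'
#' @param curve a [SignalTimeCurve-class]
#' @param smooth_window odd window length in frames (default 1)
#' @return the smoothed [SignalTimeCurve-class]
#' @export
preprocessCurve <- function(curve, smooth_window = 1L) {
    validObject(curve)
    w <- as.integer(smooth_window)
    .stopIfNot(w >= 1L && w %% 2L == 1L, "smooth_window must be odd and >= 1")
    n <- length(curve@times)
    .stopIfNot(w <= n, "smooth_window larger than the curve")
    if (w == 1L) return(curve)
    hw <- (w - 1L) %/% 2L
    y <- curve@intensities
    sm <- vapply(seq_len(n), function(i) {
        h <- min(hw, i - 1L, n - i)
        mean(y[(i - h):(i + h)])
    }, numeric(1))
    SignalTimeCurve(curve@times, sm)
}

#' Detect the enhancement onset of a curve
#'
#' Arrival is declared at the first frame whose intensity exceeds
#' `baseline_mean + k_sd * max(baseline_sd, eps)` for `m_consecutive`
#' consecutive frames, where the baseline statistics come from the first
#' `baseline_frames` frames and `eps` (a small fraction of the curve's
#' intensity range) guards noise-free curves whose baseline SD is zero.
#'
#' @param curve a [SignalTimeCurve-class] (smoothed, if desired)
#' @param baseline_frames number of pre-contrast frames (default 3)
#' @param k_sd threshold in baseline SDs (default 3)
#' @param m_consecutive frames the threshold must be sustained (default 2)
#' @return onset time in seconds
#' @export
detectOnset <- function(curve, baseline_frames = 3L, k_sd = 3,
                        m_consecutive = 2L) {
    validObject(curve)
    .stopIfNot(baseline_frames >= 2L, "need at least 2 baseline frames")
    .stopIfNot(k_sd > 0, "k_sd must be positive")
    y <- curve@intensities
    b <- y[seq_len(baseline_frames)]
    eps <- 1e-6 * diff(range(y))
    thr <- mean(b) + k_sd * max(stats::sd(b), eps)
    above <- y > thr
    run <- rle(above)
    ends <- cumsum(run$lengths)
    hit <- which(run$values & run$lengths >= m_consecutive)
    if (length(hit) == 0L)
        stop("no enhancement detected")
    first <- ends[hit[1]] - run$lengths[hit[1]] + 1L
    curve@times[first]
}

#' Time to peak of a curve
#'
#' Seconds from the detected onset to the global maximum of the curve
#' (earliest frame on ties).
#'
#' @param curve a [SignalTimeCurve-class] (smoothed, if desired)
#' @param onset_time onset from [detectOnset()]
#' @return TTP in seconds
#' @export
computeTTP <- function(curve, onset_time) {
    validObject(curve)
    peak <- which.max(curve@intensities)   # earliest index on ties
    peak_time <- curve@times[peak]
    if (peak_time < onset_time)
        stop("curve peak precedes the detected onset")
    peak_time - onset_time
}

# baseline level for enhancement-area and slope normalization: mean of the
# (up to) first `baseline_frames` frames strictly before onset, or the
# first frame when the onset is at the start
.curveBaseline <- function(curve, onset_time, baseline_frames = 3L) {
    pre <- which(curve@times < onset_time - 1e-9)
    if (length(pre) == 0L) return(curve@intensities[1])
    mean(curve@intensities[pre[seq_len(min(baseline_frames, length(pre)))]])
}

#' Positive enhancement integral of a curve
#'
#' Trapezoidal integral of the positive part of the baseline-subtracted
#' signal from the onset to the end of the acquisition, scaled by
#' `pei_scale`.  Baseline subtraction makes the area invariant to constant
#' scanner offsets.
#'
#' @param curve a [SignalTimeCurve-class] (smoothed, if desired)
#' @param onset_time onset from [detectOnset()]
#' @param pei_scale display scaling (default 0.001)
#' @param baseline_frames frames used for the baseline mean (default 3)
#' @return PEI in scaled a.u., non-negative
#' @export
computePEI <- function(curve, onset_time, pei_scale = 0.001,
                       baseline_frames = 3L) {
    validObject(curve)
    base <- .curveBaseline(curve, onset_time, baseline_frames)
    idx <- which(curve@times >= onset_time - 1e-9)
    .stopIfNot(length(idx) >= 2L, "onset too close to the end of acquisition")
    pracma::trapz(curve@times[idx],
                  pmax(curve@intensities[idx] - base, 0)) * pei_scale
}

#' Maximum wash-in and wash-out slopes of a curve
#'
#' Both slopes are measured on the peak-normalized enhancement curve
#' `(SI - baseline) / (SImax - baseline)` — the normalization under which
#' they are invariant to both intensity offsets and intensity rescaling —
#' as the largest finite-difference slope over frame pairs `window` frames
#' apart: MSI over `[onset, peak]`, MSD (magnitude) over `[peak, end]`,
#' both clipped at zero and multiplied by `slope_scale`.
#'
#' @param curve a [SignalTimeCurve-class] (smoothed, if desired)
#' @param onset_time onset from [detectOnset()]
#' @param slope_scale display scaling (default 250)
#' @param window frame separation of the finite difference (default 1)
#' @param baseline_frames frames used for the baseline mean (default 3)
#' @return named numeric `c(msi, msd)` in scaled 1/s; a peak on the final
#'   frame yields `msd = 0` with a warning
#' @export
computeMaxSlopes <- function(curve, onset_time, slope_scale = 250,
                             window = 1L, baseline_frames = 3L) {
    validObject(curve)
    base <- .curveBaseline(curve, onset_time, baseline_frames)
    y <- curve@intensities
    peak <- which.max(y)
    si_max <- y[peak]
    if (si_max <= base) return(c(msi = 0, msd = 0))
    e <- (y - base) / (si_max - base)
    t <- curve@times
    w <- as.integer(window)
    onset_idx <- min(which(t >= onset_time - 1e-9))
    pair_slopes <- function(idx) {
        if (length(idx) <= w) return(numeric(0))
        i1 <- idx[seq_len(length(idx) - w)]
        i2 <- i1 + w
        (e[i2] - e[i1]) / (t[i2] - t[i1])
    }
    msi <- max(c(pair_slopes(onset_idx:peak), 0))
    if (peak == length(y)) {
        warning("peak at the final frame; MSD set to 0")
        msd <- 0
    } else {
        msd <- max(c(-pair_slopes(peak:length(y)), 0))
    }
    c(msi = msi * slope_scale, msd = msd * slope_scale)
}

#' All four perfusion parameters of one curve
#'
#' Convenience wrapper running smoothing, onset detection, and the TTP,
#' PEI and slope estimators on one curve.
#'
#' @param curve a [SignalTimeCurve-class]
#' @param smooth_window see [preprocessCurve()]
#' @param baseline_frames,k_sd,m_consecutive see [detectOnset()]
#' @param pei_scale,slope_scale,slope_window display scalings and slope
#'   window
#' @return a [PerfusionParams-class]
#' @export
#' @examples
#' p <- AcquisitionProtocol()
#' m <- EnhancementModel()
#' crv <- SignalTimeCurve(frameTimes(p), enhancementSignal(m, frameTimes(p)))
#' curveParams(crv)
curveParams <- function(curve, smooth_window = 1L, baseline_frames = 3L,
                        k_sd = 3, m_consecutive = 2L, pei_scale = 0.001,
                        slope_scale = 250, slope_window = 1L) {
    sm <- preprocessCurve(curve, smooth_window)
    onset <- detectOnset(sm, baseline_frames, k_sd, m_consecutive)
    ttp <- computeTTP(sm, onset)
    pei <- computePEI(sm, onset, pei_scale, baseline_frames)
    sl <- computeMaxSlopes(sm, onset, slope_scale, slope_window,
                           baseline_frames)
    new("PerfusionParams", ttp = ttp, pei = pei,
        msi = unname(sl["msi"]), msd = unname(sl["msd"]),
        onset_time = onset, peak_time = onset + ttp,
        si_max = max(sm@intensities))
}
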