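#' @import methods
NULL

#' Acquisition protocol for a dynamic contrast-enhanced series
#'
#' Describes the geometry and timing of one multi-section dynamic
#' acquisition: a stack of `n_sections` axial sections imaged repeatedly at
#' `frame_interval` seconds over `duration` seconds.  The default values are
#' a 12-section, 108 s acquisition at approximately 2.7 s per frame (40
#' frames, 480 images in total).
#'
#' @slot n_sections number of axial sections per frame
#' @slot frame_interval seconds between consecutive dynamic frames
#' @slot duration total acquisition time in seconds
#' @slot section_thickness section thickness in mm
#' @slot gap inter-section gap in mm
#'
#' @seealso [AcquisitionProtocol()], [nFrames()], [frameTimes()]
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
    representation(
        n_sections        = "numeric",
        frame_interval    = "numeric",
        duration          = "numeric",
        section_thickness = "numeric",
        gap               = "numeric"
    )
)

setValidity("AcquisitionProtocol", function(object) {
    msg <- character()
    if (length(object@n_sections) != 1L || object@n_sections < 1)
        msg <- c(msg, "n_sections must be a single value >= 1")
    if (length(object@frame_interval) != 1L || object@frame_interval <= 0)
        msg <- c(msg, "frame_interval must be a single positive value")
    if (length(object@duration) != 1L || object@duration <= 0)
        msg <- c(msg, "duration must be a single positive value")
    if (length(msg) == 0L &&
        floor(object@duration / object@frame_interval + 1e-9) < 4)
        msg <- c(msg, "protocol must yield at least 4 frames")
    if (length(msg)) msg else TRUE
})

#' Parametric ground-truth enhancement model for one spleen curve
#'
#' A gamma-variate first-pass bolus model with a recirculation plateau.  The
#' signal is `s_base` up to `t_onset`; afterwards, with
#' `tau = (t - t_onset)/t_peak_offset` and `g(tau) = tau^alpha *
#' exp(alpha*(1 - tau))`, the enhancement is `amplitude * g(tau)` up to the
#' peak (`tau = 1`, where `g` attains its unique maximum of 1) and
#' `amplitude * (w*g(tau) + 1 - w)` beyond it, so the curve decays towards a
#' plateau of `(1 - w) * amplitude` above baseline, `w` being
#' `washout_fraction` (the fraction of peak enhancement washed out;
#' `washout_fraction = 1` gives a pure gamma-variate that returns to
#' baseline).  Time to peak, enhancement integral and the extreme slopes of
#' this model are available in closed/dense-grid form, which makes it a
#' ground-truth oracle for the curve-parameter estimators.
#'
#' @slot s_base baseline signal (a.u., > 0)
#' @slot t_onset contrast arrival time in seconds
#' @slot t_peak_offset seconds from onset to peak: the true time to peak
#' @slot amplitude peak enhancement above baseline (a.u., >= 0)
#' @slot shape_alpha gamma-variate shape parameter (> 0)
#' @slot washout_fraction fraction of peak enhancement lost after first pass,
#'   in `[0, 1]`
#'
#' @seealso [EnhancementModel()], [enhancementSignal()], [analyticParams()]
#' @exportClass EnhancementModel
setClass("EnhancementModel",
    representation(
        s_base           = "numeric",
        t_onset          = "numeric",
        t_peak_offset    = "numeric",
        amplitude        = "numeric",
        shape_alpha      = "numeric",
        washout_fraction = "numeric"
    )
)

setValidity("EnhancementModel", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && is.finite(x)
    if (!one(object@s_base) || object@s_base <= 0)
        msg <- c(msg, "s_base must be a single positive value")
    if (!one(object@t_onset) || object@t_onset < 0)
        msg <- c(msg, "t_onset must be >= 0")
    if (!one(object@t_peak_offset) || object@t_peak_offset <= 0)
        msg <- c(msg, "t_peak_offset must be > 0")
    if (!one(object@amplitude) || object@amplitude < 0)
        msg <- c(msg, "amplitude must be >= 0")
    if (!one(object@shape_alpha) || object@shape_alpha <= 0)
        msg <- c(msg, "shape_alpha must be > 0")
    if (!one(object@washout_fraction) ||
        object@washout_fraction < 0 || object@washout_fraction > 1)
        msg <- c(msg, "washout_fraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Stage-wise calibration table for synthetic cohorts
#'
#' Mean, standard deviation and default group size of each perfusion
#' parameter per METAVIR fibrosis stage (0-4).  The default table holds the
#' published group statistics for the piglet fibrosis cohort (TTP in
#' seconds, PEI in display a.u., MSI/MSD in scaled 1/s) with group sizes
#' 16/11/13/13/10.
#'
#' @slot table data.frame with columns `stage`, `n`, and
#'   `<param>_mean` / `<param>_sd` for `ttp`, `pei`, `msi`, `msd`
#'
#' @seealso [defaultStageCalibration()], [calibrateModel()]
#' @exportClass StageCalibration
setClass("StageCalibration", representation(table = "data.frame"))

setValidity("StageCalibration", function(object) {
    tb <- object@table
    need <- c("stage", "n",
              paste0(rep(c("ttp", "pei", "msi", "msd"), each = 2),
                     c("_mean", "_sd")))
    if (!all(need %in% names(tb)))
        return(paste("calibration table must have columns:",
                     paste(need, collapse = ", ")))
    if (!setequal(tb$stage, 0:4) || nrow(tb) != 5L)
        return("calibration table must have exactly one row per stage 0..4")
    means <- unlist(tb[grep("_mean$", names(tb))])
    sds   <- unlist(tb[grep("_sd$", names(tb))])
    if (any(means <= 0)) return("all calibration means must be > 0")
    if (any(sds < 0)) return("all calibration SDs must be >= 0")
    if (any(tb$n < 1)) return("group sizes must be >= 1")
    TRUE
})

#' Longitudinal cohort design
#'
#' Per-weekend stage composition of a longitudinal animal cohort, the
#' number of deaths in each inter-weekend interval, and the per-weekend
#' count of repeat-stage ("starred") observations: animals whose stage at a
#' weekend equals their stage at the immediately previous weekend.  The
#' default design reproduces the published 16-piglet cohort followed on
#' weekends 0/5/9/16/21 with 1, 2 and 4 deaths in the last three intervals.
#'
#' @slot n_animals number of animals at baseline
#' @slot weekends follow-up weeks
#' @slot deaths deaths per interval (length `length(weekends) - 1`)
#' @slot stage_counts weekends x stages (0..4) matrix of observed counts
#' @slot repeat_counts weekends x stages matrix of repeat-stage counts
#' @slot weight_mean,weight_sd per-weekend body-weight distribution (kg;
#'   decorative, no downstream use)
#'
#' @seealso [defaultCohortDesign()], [simulateCohort()]
#' @exportClass CohortDesign
setClass("CohortDesign",
    representation(
        n_animals     = "numeric",
        weekends      = "numeric",
        deaths        = "numeric",
        stage_counts  = "matrix",
        repeat_counts = "matrix",
        weight_mean   = "numeric",
        weight_sd     = "numeric"
    )
)

setValidity("CohortDesign", function(object) {
    msg <- character()
    nw <- length(object@weekends)
    if (nw < 1L || is.unsorted(object@weekends, strictly = TRUE))
        msg <- c(msg, "weekends must be strictly increasing")
    if (length(object@deaths) != nw - 1L || any(object@deaths < 0))
        msg <- c(msg, "deaths must be non-negative, one per interval")
    if (!all(dim(object@stage_counts) == c(nw, 5L)))
        msg <- c(msg, "stage_counts must be weekends x 5")
    if (!all(dim(object@repeat_counts) == c(nw, 5L)))
        msg <- c(msg, "repeat_counts must be weekends x 5")
    if (length(msg) == 0L) {
        alive <- object@n_animals - cumsum(c(0, object@deaths))
        if (!all(rowSums(object@stage_counts) == alive))
            msg <- c(msg, "stage counts per weekend must sum to the surviving n")
        if (any(object@repeat_counts > object@stage_counts))
            msg <- c(msg, "repeat counts cannot exceed stage counts")
        if (any(object@repeat_counts[1, ] != 0))
            msg <- c(msg, "baseline weekend cannot contain repeat observations")
    }
    if (length(msg)) msg else TRUE
})

#' Sampled signal-intensity-time curve
#'
#' @slot times frame times in seconds, strictly increasing and uniform to
#'   within 1 percent of the median frame interval
#' @slot intensities signal values (a.u.), finite, same length as `times`
#'
#' @seealso [SignalTimeCurve()], [curveParams()]
#' @exportClass SignalTimeCurve
setClass("SignalTimeCurve",
    representation(times = "numeric", intensities = "numeric"))

setValidity("SignalTimeCurve", function(object) {
    t <- object@times; y <- object@intensities
    if (length(t) < 4L) return("curve must have at least 4 frames")
    if (length(t) != length(y)) return("times and intensities differ in length")
    if (any(!is.finite(t)) || any(!is.finite(y)))
        return("times and intensities must be finite")
    dt <- diff(t)
    if (any(dt <= 0)) return("times must be strictly increasing")
    if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt))
        return("frame times must be uniform within 1% of the frame interval")
    TRUE
})

#' Semi-quantitative perfusion parameters of one measurement
#'
#' The four curve parameters plus the landmarks they derive from.  `ttp`
#' (time to peak, s) is the interval from detectable enhancement onset to
#' maximum signal intensity; `pei` (positive enhancement integral, a.u.) is
#' the baseline-subtracted area under the curve from onset to the end of the
#' acquisition; `msi`/`msd` (1/s, magnitude convention, both >= 0) are the
#' steepest wash-in and wash-out slopes of the peak-normalized enhancement
#' curve.
#'
#' @slot ttp,pei,msi,msd the four parameters
#' @slot onset_time,peak_time curve landmarks in seconds
#' @slot si_max maximum signal intensity (a.u.)
#'
#' @seealso [curveParams()], [analyticParams()], [measureSpleen()]
#' @exportClass PerfusionParams
setClass("PerfusionParams",
    representation(
        ttp        = "numeric",
        pei        = "numeric",
        msi        = "numeric",
        msd        = "numeric",
        onset_time = "numeric",
        peak_time  = "numeric",
        si_max     = "numeric"
    )
)

setValidity("PerfusionParams", function(object) {
    msg <- character()
    if (object@ttp < 0) msg <- c(msg, "ttp must be >= 0")
    if (abs(object@ttp - (object@peak_time - object@onset_time)) > 1e-6)
        msg <- c(msg, "ttp must equal peak_time - onset_time")
    if (object@msi < 0 || object@msd < 0)
        msg <- c(msg, "msi and msd are magnitudes and must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Rendered 4D dynamic series
#'
#' Container for a synthetic (or loaded) dynamic series: a 4D array
#' `x, y, section, frame` together with its acquisition protocol and, for
#' synthetic phantoms, the generating geometry.
#'
#' @slot data 4D numeric array
#' @slot protocol the [AcquisitionProtocol-class] of the series
#' @slot geometry phantom geometry list (possibly empty for loaded data)
#'
#' @seealso [renderSeries()], [roiCurve()], [parametricMaps()]
#' @exportClass DceSeries
setClass("DceSeries",
    representation(data = "array", protocol = "AcquisitionProtocol",
                   geometry = "list"))

setValidity("DceSeries", function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be a 4D array (x, y, section, frame)")
    if (d[3] != object@protocol@n_sections)
        return("third dimension must equal protocol n_sections")
    if (d[4] != nFrames(object@protocol))
        return("fourth dimension must equal the protocol frame count")
    TRUE
})

#' Region-of-interest specification on one section
#'
#' A binary in-plane mask with the two ROI hygiene rules used for spleen
#' measurements: the mask is eroded by `erosion_margin_px` pixels so the ROI
#' does not approach the organ margin (partial-volume control), and voxels
#' whose peak enhancement exceeds `vessel_exclusion_factor` times the ROI
#' median peak enhancement are excluded as hilar-vessel contamination.
#'
#' @slot section_index section the mask lives on
#' @slot mask logical matrix, non-empty, not touching the image border
#' @slot erosion_margin_px erosion radius in pixels (0 = none)
#' @slot vessel_exclusion_factor exclusion threshold (Inf = keep all)
#'
#' @seealso [roiCurve()], [spleenRois()]
#' @exportClass RoiSpec
setClass("RoiSpec",
    representation(section_index = "numeric", mask = "matrix",
                   erosion_margin_px = "numeric",
                   vessel_exclusion_factor = "numeric"))

setValidity("RoiSpec", function(object) {
    m <- object@mask
    if (!is.logical(m)) return("mask must be a logical matrix")
    if (!any(m)) return("mask is empty")
    if (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))
        return("mask must not touch the image border")
    if (object@erosion_margin_px < 0) return("erosion_margin_px must be >= 0")
    if (object@vessel_exclusion_factor <= 0)
        return("vessel_exclusion_factor must be > 0")
    TRUE
})
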