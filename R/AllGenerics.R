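#' Number of dynamic frames of a protocol
#'
#' @param x an [AcquisitionProtocol-class]
#' @return integer frame count, `floor(duration / frame_interval)`
#' @export
#' @examples
#' nFrames(AcquisitionProtocol())  # 40
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame sampling times of a protocol
#'
#' @param x an [AcquisitionProtocol-class]
#' @return numeric vector of frame times in seconds, starting at 0
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "AcquisitionProtocol", function(x)
    as.integer(floor(x@duration / x@frame_interval + 1e-9)))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "AcquisitionProtocol", function(x)
    (seq_len(nFrames(x)) - 1) * x@frame_interval)

#' @describeIn nFrames frame count of the protocol a series was rendered with
#' @export
setMethod("nFrames", "DceSeries", function(x) nFrames(x@protocol))

#' @describeIn frameTimes frame times of the protocol a series was rendered
#'   with
#' @export
setMethod("frameTimes", "DceSeries", function(x) frameTimes(x@protocol))

#' Accessors for curves, series and calibrations
#'
#' `curveTimes`/`curveIntensities` return the sampling grid and signal of a
#' [SignalTimeCurve-class]; `seriesData` and `seriesProtocol` return the 4D
#' array and protocol of a [DceSeries-class]; `calibrationTable` returns the
#' stage table of a [StageCalibration-class].
#'
#' @param x the object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setGeneric("curveIntensities", function(x) standardGeneric("curveIntensities"))
#' @rdname accessors
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("seriesProtocol", function(x) standardGeneric("seriesProtocol"))
#' @rdname accessors
#' @export
setGeneric("calibrationTable", function(x) standardGeneric("calibrationTable"))

#' @rdname accessors
#' @export
setMethod("curveTimes", "SignalTimeCurve", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("curveIntensities", "SignalTimeCurve", function(x) x@intensities)
#' @rdname accessors
#' @export
setMethod("seriesData", "DceSeries", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("seriesProtocol", "DceSeries", function(x) x@protocol)
#' @rdname accessors
#' @export
setMethod("calibrationTable", "StageCalibration", function(x) x@table)

setMethod("show", "AcquisitionProtocol", function(object) {
    cat(sprintf(
        "AcquisitionProtocol: %d sections x %d frames (%.3g s interval, %.4g s total)\n",
        as.integer(object@n_sections), nFrames(object),
        object@frame_interval, object@duration))
    cat(sprintf("  section thickness %.3g mm, gap %.3g mm, %d images in total\n",
        object@section_thickness, object@gap,
        as.integer(object@n_sections) * nFrames(object)))
})

setMethod("show", "EnhancementModel", function(object) {
    cat("EnhancementModel (gamma-variate with washout plateau)\n")
    cat(sprintf("  s_base %.4g, onset %.4g s, true TTP %.4g s, amplitude %.4g\n",
        object@s_base, object@t_onset, object@t_peak_offset, object@amplitude))
    cat(sprintf("  shape alpha %.3g, washout fraction %.3g (plateau %.4g above baseline)\n",
        object@shape_alpha, object@washout_fraction,
        (1 - object@washout_fraction) * object@amplitude))
})

setMethod("show", "StageCalibration", function(object) {
    cat("StageCalibration (per-stage parameter means and SDs)\n")
    print(object@table, row.names = FALSE)
})

setMethod("show", "CohortDesign", function(object) {
    cat(sprintf("CohortDesign: %d animals, weekends %s, deaths per interval %s\n",
        as.integer(object@n_animals),
        paste(object@weekends, collapse = "/"),
        paste(object@deaths, collapse = "/")))
    tb <- cbind(weekend = object@weekends, object@stage_counts)
    colnames(tb) <- c("weekend", paste0("S", 0:4))
    print(tb)
})

setMethod("show", "SignalTimeCurve", function(object) {
    cat(sprintf("SignalTimeCurve: %d frames, t = %.4g..%.4g s, SI %.4g..%.4g\n",
        length(object@times), min(object@times), max(object@times),
        min(object@intensities), max(object@intensities)))
})

setMethod("show", "PerfusionParams", function(object) {
    cat("PerfusionParams\n")
    cat(sprintf("  TTP %.4g s   PEI %.4g   MSI %.4g /s   MSD %.4g /s\n",
        object@ttp, object@pei, object@msi, object@msd))
    cat(sprintf("  onset %.4g s, peak %.4g s, SImax %.4g\n",
        object@onset_time, object@peak_time, object@si_max))
})

setMethod("show", "DceSeries", function(object) {
    d <- dim(object@data)
    cat(sprintf("DceSeries: %d x %d in-plane, %d sections x %d frames (%d images)\n",
        d[1], d[2], d[3], d[4], d[3] * d[4]))
})

#' Coerce perfusion parameters to a one-row data frame
#'
#' @param x a [PerfusionParams-class]
#' @param row.names,optional,... passed for S3 compatibility, unused
#' @return a one-row `data.frame` with columns `ttp`, `pei`, `msi`, `msd`,
#'   `onset_time`, `peak_time`, `si_max`
#' @export
as.data.frame.PerfusionParams <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    data.frame(ttp = x@ttp, pei = x@pei, msi = x@msi, msd = x@msd,
               onset_time = x@onset_time, peak_time = x@peak_time,
               si_max = x@si_max)
}
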