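#' Mean signal-time curve of an ROI
#'
#' Applies the two ROI hygiene rules before averaging: the mask is eroded
#' by `erosion_margin_px` pixels (so the ROI stays clear of the organ
#' margin), and voxels whose peak enhancement exceeds
#' `vessel_exclusion_factor` times the ROI median peak enhancement are
#' excluded as hilar-vessel contamination.  The remaining voxels are
#' averaged per frame.
#'
#' @param series a [DceSeries-class]
#' @param roi an [RoiSpec-class]
#' @param baseline_frames frames used for the per-voxel baseline when
#'   ranking peak enhancement (default 3)
#' @return a [SignalTimeCurve-class]
#' @export
roiCurve <- function(series, roi, baseline_frames = 3L) {
    validObject(roi)
    d <- dim(series@data)
    .stopIfNot(roi@section_index >= 1 && roi@section_index <= d[3],
               "ROI section outside the series")
    .stopIfNot(all(dim(roi@mask) == d[1:2]),
               "ROI mask does not match the in-plane dimensions")
    mask <- roi@mask
    if (roi@erosion_margin_px > 0) {
        brush <- EBImage::makeBrush(2L * as.integer(roi@erosion_margin_px)
                                    + 1L, shape = "disc")
        mask <- EBImage::erode(mask * 1, brush) > 0.5
    }
    if (!any(mask))
        stop("ROI mask is empty after margin erosion")
    sec <- series@data[, , roi@section_index, ]
    vox <- matrix(sec, d[1] * d[2], d[4])[which(mask), , drop = FALSE]
    base <- rowMeans(vox[, seq_len(baseline_frames), drop = FALSE])
    peak_enh <- apply(vox, 1, max) - base
    med <- stats::median(peak_enh)
    keep <- if (is.finite(roi@vessel_exclusion_factor) && med > 0)
        peak_enh <= roi@vessel_exclusion_factor * med
    else rep(TRUE, nrow(vox))
    if (!any(keep))
        stop("ROI mask is empty after vessel exclusion")
    SignalTimeCurve(frameTimes(series), colMeans(vox[keep, , drop = FALSE]))
}

#' Spleen measurement from three consecutive sections
#'
#' Mirrors the standard reading procedure: ROIs on the three consecutive
#' largest spleen sections, one parameter set estimated per section, and
#' the arithmetic mean of the three parameter sets (parameters averaged,
#' not curves pooled) reported as the measurement.
#'
#' @param series a [DceSeries-class]
#' @param rois list of exactly three [RoiSpec-class] on consecutive
#'   sections; defaults to [spleenRois()] of the phantom geometry
#' @param ... estimator settings passed to [curveParams()]
#' @return a [PerfusionParams-class] (the mean of the three sections)
#' @export
#' @examples
#' s <- renderSeries(calibrateModel(0, seed = 1))
#' measureSpleen(s)
measureSpleen <- function(series, rois = spleenRois(series), ...) {
    .stopIfNot(length(rois) == 3L, "exactly 3 ROIs are required")
    secs <- vapply(rois, function(r) r@section_index, numeric(1))
    .stopIfNot(all(diff(sort(secs)) == 1),
               "ROI sections must be consecutive")
    per <- lapply(rois, function(r) {
        tryCatch(curveParams(roiCurve(series, r), ...),
                 error = function(e) stop("section ", r@section_index, ": ",
                                          conditionMessage(e), call. = FALSE))
    })
    avg <- function(f) mean(vapply(per, f, numeric(1)))
    new("PerfusionParams",
        ttp = avg(function(p) p@ttp), pei = avg(function(p) p@pei),
        msi = avg(function(p) p@msi), msd = avg(function(p) p@msd),
        onset_time = avg(function(p) p@onset_time),
        peak_time = avg(function(p) p@peak_time),
        si_max = avg(function(p) p@si_max))
}
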