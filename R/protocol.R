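#' Construct an acquisition protocol
#'
#' @param n_sections number of axial sections (default 12)
#' @param frame_interval seconds per dynamic frame (default 2.7)
#' @param duration total acquisition time in seconds (default 108)
#' @param section_thickness section thickness in mm (default 8)
#' @param gap inter-section gap in mm (default 1)
#' @return an [AcquisitionProtocol-class]
#' @export
#' @examples
#' p <- AcquisitionProtocol()
#' nFrames(p) * p@n_sections  # 480 images
AcquisitionProtocol <- function(n_sections = 12, frame_interval = 2.7,
                                duration = 108, section_thickness = 8,
                                gap = 1) {
    new("AcquisitionProtocol",
        n_sections = n_sections, frame_interval = frame_interval,
        duration = duration, section_thickness = section_thickness,
        gap = gap)
}

#' Construct a ground-truth enhancement model
#'
#' @param s_base baseline signal in a.u. (default 100)
#' @param t_onset contrast arrival time in seconds (default 10)
#' @param t_peak_offset true time to peak in seconds (default 54)
#' @param amplitude peak enhancement above baseline in a.u. (default 100)
#' @param shape_alpha gamma-variate shape (default 3)
#' @param washout_fraction fraction of peak enhancement washed out after the
#'   first pass (default 0.6, i.e. a plateau at 40 percent of peak
#'   enhancement)
#' @param protocol protocol used to check that the peak is observable; pass
#'   `NULL` to skip the check
#' @return an [EnhancementModel-class]
#' @export
EnhancementModel <- function(s_base = 100, t_onset = 10, t_peak_offset = 54,
                             amplitude = 100, shape_alpha = 3,
                             washout_fraction = 0.6,
                             protocol = AcquisitionProtocol()) {
    m <- new("EnhancementModel",
             s_base = s_base, t_onset = t_onset,
             t_peak_offset = t_peak_offset, amplitude = amplitude,
             shape_alpha = shape_alpha, washout_fraction = washout_fraction)
    if (!is.null(protocol) &&
        t_onset + t_peak_offset >= protocol@duration)
        stop("model peak (t_onset + t_peak_offset) must occur before the ",
             "end of the acquisition")
    m
}

#' Construct a signal-intensity-time curve
#'
#' @param times frame times in seconds (strictly increasing, uniform)
#' @param intensities signal values, same length
#' @return a [SignalTimeCurve-class]
#' @export
SignalTimeCurve <- function(times, intensities) {
    new("SignalTimeCurve", times = as.numeric(times),
        intensities = as.numeric(intensities))
}

#' Construct a region-of-interest specification
#'
#' @param section_index section the mask applies to
#' @param mask logical matrix (in-plane)
#' @param erosion_margin_px pixels of margin erosion before measurement
#'   (default 1)
#' @param vessel_exclusion_factor voxels with peak enhancement above this
#'   multiple of the ROI median peak enhancement are dropped as vessel
#'   contamination (default 2; `Inf` disables)
#' @return an [RoiSpec-class]
#' @export
RoiSpec <- function(section_index, mask, erosion_margin_px = 1,
                    vessel_exclusion_factor = 2) {
    storage.mode(mask) <- "logical"
    new("RoiSpec", section_index = section_index, mask = mask,
        erosion_margin_px = erosion_margin_px,
        vessel_exclusion_factor = vessel_exclusion_factor)
}
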