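#' Phantom geometry for a synthetic spleen series
#'
#' Defines, per section, an elliptical spleen with a small circular
#' hilar-vessel tube inside it, on a flat background.  Section-to-section
#' the ellipse semi-axes follow an ellipsoid profile so the middle sections
#' are the largest, mimicking how the organ is covered by an axial stack.
#'
#' @param protocol an [AcquisitionProtocol-class]
#' @param width,height in-plane matrix size (default 48 x 48)
#' @param spleen_semiaxes semi-axes in pixels of the largest section
#'   (default `c(16, 10)`)
#' @param vessel_radius hilar vessel tube radius in pixels (default 2)
#' @param background background signal level in a.u. (default 20)
#' @return a geometry list with logical 3D masks `spleen` and `vessel`
#'   (`width x height x n_sections`), the `background` level, and
#'   `largest_sections`, the indices of the three consecutive largest
#'   spleen sections
#' @export
phantomGeometry <- function(protocol = AcquisitionProtocol(), width = 48,
                            height = 48, spleen_semiaxes = c(16, 10),
                            vessel_radius = 2, background = 20) {
    ns <- as.integer(protocol@n_sections)
    cx <- (width + 1) / 2
    cy <- (height + 1) / 2
    if (cx + spleen_semiaxes[1] >= width || cy + spleen_semiaxes[2] >= height)
        stop("spleen geometry extends outside the field of view")
    mid <- (ns + 1) / 2
    half <- max(mid - 1, 1)
    scale <- sqrt(pmax(1 - ((seq_len(ns) - mid) / (half + 0.5))^2, 0))
    spleen <- vessel <- array(FALSE, c(width, height, ns))
    xs <- matrix(seq_len(width), width, height)
    ys <- matrix(seq_len(height), width, height, byrow = TRUE)
    for (k in seq_len(ns)) {
        a <- spleen_semiaxes[1] * scale[k]
        b <- spleen_semiaxes[2] * scale[k]
        if (a < 2 || b < 2) next
        sp <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
        # hilar vessel sits at the medial margin of the ellipse
        vx <- cx - 0.6 * a
        ve <- (xs - vx)^2 + (ys - cy)^2 <= vessel_radius^2
        spleen[, , k] <- sp
        vessel[, , k] <- sp & ve
    }
    areas <- apply(spleen, 3, sum)
    run <- stats::filter(areas, rep(1, 3), sides = 2)
    best <- which.max(run[2:(ns - 1)]) + 1L
    list(width = width, height = height, spleen = spleen, vessel = vessel,
         background = background,
         largest_sections = (best - 1L):(best + 1L))
}

# default fast arterial-like curve for the hilar vessel
.defaultVesselModel <- function(spleen_model, protocol) {
    EnhancementModel(
        s_base = spleen_model@s_base,
        t_onset = max(2 * protocol@frame_interval, 5),
        t_peak_offset = 8,
        amplitude = 3.5 * max(spleen_model@amplitude, 1),
        shape_alpha = 3, washout_fraction = 0.8,
        protocol = protocol)
}

#' Render a synthetic 4D dynamic series
#'
#' Fills the phantom geometry with the spleen model's curve, a fast
#' arterial-like curve in the hilar vessel tube, and a non-enhancing
#' background, then optionally adds Gaussian noise and an integer-pixel
#' in-plane translation jitter per frame.  The rendered series always
#' contains `n_sections * n_frames` images.
#'
#' @param model the spleen [EnhancementModel-class]
#' @param geometry a [phantomGeometry()] list
#' @param protocol an [AcquisitionProtocol-class]
#' @param vessel_model optional [EnhancementModel-class] for the vessel tube
#'   (default: fast, high-amplitude arterial-like curve)
#' @param noise_sd additive Gaussian noise SD in a.u. (0 = noiseless)
#' @param motion_jitter_px maximum integer in-plane shift per frame
#'   (0 = still)
#' @param seed optional integer seed; same seed, same noise and jitter
#' @return a [DceSeries-class]
#' @export
#' @examples
#' s <- renderSeries(EnhancementModel())
#' prod(dim(seriesData(s))[3:4])  # 480 images
renderSeries <- function(model, geometry = phantomGeometry(protocol),
                         protocol = AcquisitionProtocol(),
                         vessel_model = NULL, noise_sd = 0,
                         motion_jitter_px = 0, seed = NULL) {
    validObject(model); validObject(protocol)
    .stopIfNot(noise_sd >= 0, "noise_sd must be >= 0")
    if (is.null(vessel_model))
        vessel_model <- .defaultVesselModel(model, protocol)
    tt <- frameTimes(protocol)
    nf <- length(tt)
    ns <- as.integer(protocol@n_sections)
    sp_curve <- enhancementSignal(model, tt)
    ve_curve <- enhancementSignal(vessel_model, tt)
    w <- geometry$width; h <- geometry$height
    arr <- array(geometry$background, c(w, h, ns, nf))
    .withSeed(seed, {
        jit <- matrix(0L, nf, 2)
        if (motion_jitter_px > 0) {
            j <- as.integer(motion_jitter_px)
            jit[] <- sample(seq(-j, j), 2L * nf, replace = TRUE)
        }
        for (k in seq_len(ns)) {
            sp <- geometry$spleen[, , k]
            ve <- geometry$vessel[, , k]
            base <- matrix(geometry$background, w, h)
            for (f in seq_len(nf)) {
                m <- base
                m[sp] <- sp_curve[f]
                m[ve] <- ve_curve[f]
                if (jit[f, 1] != 0 || jit[f, 2] != 0)
                    m <- .shiftMatrix(m, jit[f, 1], jit[f, 2],
                                      geometry$background)
                arr[, , k, f] <- m
            }
        }
        if (noise_sd > 0)
            arr <- arr + stats::rnorm(length(arr), 0, noise_sd)
    })
    new("DceSeries", data = arr, protocol = protocol, geometry = geometry)
}

#' Write a dynamic series as NIfTI-1
#'
#' Stores the series as a 4D NIfTI volume with the frame interval in the
#' time-step field (`pixdim[4]`, seconds).
#'
#' @param series a [DceSeries-class]
#' @param file output path; a `.gz` suffix selects gzip compression
#' @return the written path, invisibly
#' @export
writeSeriesNifti <- function(series, file) {
    p <- seriesProtocol(series)
    nim <- oro.nifti::nifti(seriesData(series), datatype = 16)
    nim@pixdim[4] <- p@section_thickness + p@gap
    nim@pixdim[5] <- p@frame_interval
    nim@xyzt_units <- 10L  # mm + s
    oro.nifti::descrip(nim) <- "spleen DCE series"
    gz <- grepl("\\.gz$", file)
    stem <- sub("\\.nii(\\.gz)?$", "", file)
    oro.nifti::writeNIfTI(nim, stem, gzipped = gz)
    invisible(paste0(stem, if (gz) ".nii.gz" else ".nii"))
}

#' Read a dynamic series from NIfTI-1
#'
#' @param file a 4D NIfTI path
#' @param protocol optional [AcquisitionProtocol-class]; if `NULL` the
#'   protocol is reconstructed from the image dimensions and the stored
#'   time step
#' @return a [DceSeries-class]
#' @export
readSeriesNifti <- function(file, protocol = NULL) {
    nim <- oro.nifti::readNIfTI(sub("\\.nii(\\.gz)?$", "", file))
    arr <- array(nim@.Data, dim(nim))
    .stopIfNot(length(dim(arr)) == 4L, "expected a 4D NIfTI volume")
    if (is.null(protocol)) {
        fi <- nim@pixdim[5]
        if (!is.finite(fi) || fi <= 0) fi <- 2.7
        protocol <- AcquisitionProtocol(
            n_sections = dim(arr)[3], frame_interval = fi,
            duration = fi * dim(arr)[4])
    }
    new("DceSeries", data = arr, protocol = protocol, geometry = list())
}

#' Standard spleen ROIs on the three largest sections
#'
#' Builds one [RoiSpec-class] per section for the three consecutive largest
#' spleen sections of a synthetic phantom, using the full spleen ellipse as
#' the drawn mask (hilar-vessel voxels are removed later by the exclusion
#' rule in [roiCurve()]).
#'
#' @param series a [DceSeries-class] rendered from a [phantomGeometry()]
#' @param erosion_margin_px,vessel_exclusion_factor see [RoiSpec()]
#' @return list of three [RoiSpec-class]
#' @export
spleenRois <- function(series, erosion_margin_px = 1,
                       vessel_exclusion_factor = 2) {
    g <- series@geometry
    .stopIfNot(length(g) > 0 && !is.null(g$largest_sections),
               "series carries no phantom geometry; build RoiSpec manually")
    lapply(g$largest_sections, function(k)
        RoiSpec(section_index = k, mask = g$spleen[, , k],
                erosion_margin_px = erosion_margin_px,
                vessel_exclusion_factor = vessel_exclusion_factor))
}
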