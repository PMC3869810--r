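#' Voxelwise parametric maps
#'
#' Applies the curve-parameter estimators to every voxel in the mask and
#' returns one 3D map per parameter.  Voxels where no enhancement onset is
#' detected (background, non-enhancing tissue) are set to the missing-value
#' sentinel `NA`.
#'
#' @param series a [DceSeries-class]
#' @param mask logical 3D array (`x, y, section`); defaults to every voxel
#'   of the phantom spleen when the series carries its geometry
#' @param ... estimator settings passed to [curveParams()]
#' @return named list of 3D arrays `ttp`, `pei`, `msi`, `msd`
#' @export
parametricMaps <- function(series, mask = NULL, ...) {
    d <- dim(series@data)
    if (is.null(mask)) {
        .stopIfNot(!is.null(series@geometry$spleen),
                   "no mask given and the series carries no geometry")
        mask <- series@geometry$spleen
    }
    .stopIfNot(all(dim(mask) == d[1:3]), "mask does not match the series")
    .stopIfNot(any(mask), "mask is empty")
    tt <- frameTimes(series)
    maps <- lapply(1:4, function(i) array(NA_real_, d[1:3]))
    names(maps) <- c("ttp", "pei", "msi", "msd")
    flat <- matrix(series@data, prod(d[1:3]), d[4])
    lin <- which(mask)
    for (v in seq_along(lin)) {
        p <- tryCatch(
            curveParams(SignalTimeCurve(tt, flat[lin[v], ]), ...),
            error = function(e) NULL)
        if (!is.null(p)) {
            maps$ttp[lin[v]] <- p@ttp
            maps$pei[lin[v]] <- p@pei
            maps$msi[lin[v]] <- p@msi
            maps$msd[lin[v]] <- p@msd
        }
    }
    maps
}

#' Write parametric maps as NIfTI-1
#'
#' One volume per parameter, with the parameter name and the sentinel
#' convention recorded in the NIfTI description field.
#'
#' @param maps list from [parametricMaps()]
#' @param dir output directory (created if missing)
#' @param prefix filename prefix (default `"map"`)
#' @return named character vector of written paths, invisibly
#' @export
writeParametricMaps <- function(maps, dir, prefix = "map") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- vapply(names(maps), function(nm) {
        nim <- oro.nifti::nifti(maps[[nm]], datatype = 16)
        oro.nifti::descrip(nim) <- paste0(nm, " map; NA = no enhancement")
        stem <- file.path(dir, paste0(prefix, "_", nm))
        oro.nifti::writeNIfTI(nim, stem, gzipped = FALSE)
        paste0(stem, ".nii")
    }, character(1))
    invisible(out)
}
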