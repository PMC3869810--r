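#' Ground-truth recovery experiment for one stage
#'
#' Draws `n` stage-calibrated models, renders each one (noiseless by
#' default) and measures it back through the chosen path, returning the
#' drawn truth next to the estimates — the parameter-recovery experiment
#' used to validate the estimator against the generator.
#'
#' @param stage METAVIR stage 0..4
#' @param n number of animals
#' @param calib a [StageCalibration-class]
#' @param protocol an [AcquisitionProtocol-class]
#' @param seed integer seed
#' @param measurement `"rendered"` (phantom + three-section ROI
#'   measurement, the default) or `"curve"` (model curve on the frame grid)
#' @param noise_sd,motion_jitter_px degradation settings
#' @param ... passed to [calibrateModel()]
#' @return data.frame with per-animal `ttp_true`, `pei_true`, and estimated
#'   `ttp`, `pei`, `msi`, `msd`
#' @export
#' @examples
#' r <- recoverStageParams(4, n = 3, seed = 1)
#' mean(abs(r$ttp - r$ttp_true)) < 2.7
recoverStageParams <- function(stage, n, calib = defaultStageCalibration(),
                               protocol = AcquisitionProtocol(), seed = NULL,
                               measurement = c("rendered", "curve"),
                               noise_sd = 0, motion_jitter_px = 0, ...) {
    measurement <- match.arg(measurement)
    .withSeed(seed, {
        geom <- phantomGeometry(protocol)
        rows <- lapply(seq_len(n), function(i) {
            model <- calibrateModel(stage, calib, protocol, ...)
            truth <- analyticParams(model, protocol)
            est <- if (measurement == "rendered") {
                s <- renderSeries(model, geom, protocol,
                                  noise_sd = noise_sd,
                                  motion_jitter_px = motion_jitter_px)
                measureSpleen(s)
            } else {
                y <- enhancementSignal(model, frameTimes(protocol))
                if (noise_sd > 0)
                    y <- y + stats::rnorm(length(y), 0, noise_sd)
                curveParams(SignalTimeCurve(frameTimes(protocol), y))
            }
            data.frame(stage = stage, ttp_true = truth@ttp,
                       pei_true = truth@pei, ttp = est@ttp, pei = est@pei,
                       msi = est@msi, msd = est@msd)
        })
        do.call(rbind, rows)
    })
}

#' Assemble a pipeline configuration
#'
#' A plain serializable list describing one end-to-end run: protocol,
#' calibration table, cohort design, measurement path and degradation,
#' estimator settings, statistics family and the master seed.  Every
#' stochastic step of [runPipeline()] derives from `seed`, so a config
#' fully reproduces its report.
#'
#' @param protocol,calib,design the S4 inputs (defaults: published study
#'   conditions)
#' @param measurement `"curve"`, `"analytic"` or `"rendered"`
#' @param noise_sd,motion_jitter_px degradation settings
#' @param family_size Bonferroni family for grouped tests
#' @param parameters parameter columns to analyse
#' @param seed master seed
#' @return a `PipelineConfig` list
#' @export
pipelineConfig <- function(protocol = AcquisitionProtocol(),
                           calib = defaultStageCalibration(),
                           design = defaultCohortDesign(),
                           measurement = "curve", noise_sd = 0,
                           motion_jitter_px = 0, family_size = 4L,
                           parameters = c("ttp", "pei", "msi", "msd"),
                           seed = 1L) {
    structure(list(
        protocol = list(n_sections = protocol@n_sections,
                        frame_interval = protocol@frame_interval,
                        duration = protocol@duration,
                        section_thickness = protocol@section_thickness,
                        gap = protocol@gap),
        calibration = as.list(calib@table),
        design = list(n_animals = design@n_animals,
                      weekends = design@weekends, deaths = design@deaths,
                      stage_counts = unname(apply(design@stage_counts, 1,
                                                  as.integer,
                                                  simplify = FALSE)),
                      repeat_counts = unname(apply(design@repeat_counts, 1,
                                                   as.integer,
                                                   simplify = FALSE)),
                      weight_mean = design@weight_mean,
                      weight_sd = design@weight_sd),
        measurement = measurement, noise_sd = noise_sd,
        motion_jitter_px = motion_jitter_px,
        family_size = as.integer(family_size), parameters = parameters,
        seed = as.integer(seed)), class = "PipelineConfig")
}

#' Write / read a pipeline configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`) by file extension; configs
#' round-trip through serialization unchanged.
#'
#' @param config a `PipelineConfig`
#' @param path file path
#' @return `writePipelineConfig`: the path, invisibly;
#'   `readPipelineConfig`: the `PipelineConfig`
#' @export
writePipelineConfig <- function(config, path) {
    if (grepl("\\.json$", path))
        jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    else
        yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    raw <- if (grepl("\\.json$", path))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    structure(raw, class = "PipelineConfig")
}

# S4 objects from a (possibly deserialized) config
.configProtocol <- function(config)
    do.call(AcquisitionProtocol, config$protocol)

.configCalibration <- function(config)
    StageCalibration(as.data.frame(config$calibration))

# count rows may come back from YAML/JSON as lists of vectors or a matrix
.normCounts <- function(x) {
    if (is.list(x)) do.call(rbind, lapply(x, unlist)) else as.matrix(x)
}

.configDesign <- function(config) {
    d <- config$design
    CohortDesign(n_animals = d$n_animals, weekends = d$weekends,
                 deaths = d$deaths,
                 stage_counts = .normCounts(d$stage_counts),
                 repeat_counts = .normCounts(d$repeat_counts),
                 weight_mean = d$weight_mean, weight_sd = d$weight_sd)
}

#' Run the full simulate-measure-report pipeline
#'
#' Simulates the cohort under the config, writes the cohort table, runs
#' the staging report and writes it with a manifest sufficient to
#' reproduce every number (config copy, config hash, package and R
#' versions, seed).  Identical configs give identical bundles.
#'
#' @param config a `PipelineConfig`
#' @param out_dir output directory (created)
#' @return the `stagingReport`, invisibly; side effect: `cohort.csv`,
#'   `report.json` + CSV tables, `config.yaml`, `manifest.json` in
#'   `out_dir`
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    protocol <- .configProtocol(config)
    calib <- .configCalibration(config)
    design <- .configDesign(config)
    cohort <- simulateCohort(design, calib, protocol, seed = config$seed,
                             measurement = config$measurement,
                             noise_sd = config$noise_sd,
                             motion_jitter_px = config$motion_jitter_px)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    report <- stagingReport(cohort, parameters = config$parameters,
                            family_size = config$family_size)
    writeStagingReport(report, out_dir)
    cfg_path <- file.path(out_dir, "config.yaml")
    writePipelineConfig(config, cfg_path)
    manifest <- list(
        package = "spleenDCE",
        package_version = as.character(utils::packageVersion("spleenDCE")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = config$seed,
        config_md5 = unname(tools::md5sum(cfg_path)),
        n_observations = nrow(cohort),
        group_sizes = as.list(report$group_sizes))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(report)
}

#' Generate a miniature seeded test dataset
#'
#' Writes a small phantom series (4 sections x 20 frames) with its spleen
#' mask as uncompressed NIfTI, plus a 20-observation cohort CSV covering
#' all five stages (10 animals, two weekends, no progression).  Everything
#' derives from `seed`; regenerating with the same seed is byte-identical.
#'
#' @param out_dir writable directory (created)
#' @param seed integer seed
#' @return named list of written paths, invisibly
#' @export
makeFixtures <- function(out_dir, seed = 1L) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    mini <- AcquisitionProtocol(n_sections = 4, duration = 54)
    geom <- phantomGeometry(mini, width = 32, height = 32,
                            spleen_semiaxes = c(10, 7))
    model <- EnhancementModel(t_onset = 5.4, t_peak_offset = 27,
                              amplitude = 80, protocol = mini)
    series <- renderSeries(model, geom, mini, noise_sd = 1, seed = seed)
    p_series <- writeSeriesNifti(series, file.path(out_dir, "phantom.nii"))
    mask <- oro.nifti::nifti(geom$spleen * 1L, datatype = 2)
    oro.nifti::descrip(mask) <- "spleen mask"
    oro.nifti::writeNIfTI(mask, file.path(out_dir, "spleen_mask"),
                          gzipped = FALSE)
    sc <- matrix(rep(2L, 10), 2, 5, byrow = TRUE)
    design <- CohortDesign(n_animals = 10, weekends = c(0, 5),
                           deaths = 0, stage_counts = sc,
                           repeat_counts = rbind(rep(0L, 5), rep(2L, 5)))
    cohort <- simulateCohort(design, seed = seed, measurement = "curve")
    p_cohort <- file.path(out_dir, "cohort.csv")
    utils::write.csv(cohort, p_cohort, row.names = FALSE)
    invisible(list(series = p_series,
                   mask = file.path(out_dir, "spleen_mask.nii"),
                   cohort = p_cohort))
}
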