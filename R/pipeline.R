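#' Default pipeline configuration
#'
#' Returns the configuration list understood by [run_pipeline()]:
#' `simulate` (phantom preset, grid, object counts, seed), `preprocess`
#' (NLM sigma, binning factors), `segment` (range bounds, size and variance
#' cutoffs, connectivity), `analyze` and `evaluate` (truth class, IoU
#' threshold) stages. Unset segmentation bounds default to the phantom's
#' separating range; an unset variance cutoff defaults to
#' `(4 * label_sd)^2`. Any entry can be overridden via a YAML config file
#' or the `override` argument of [run_pipeline()].
#'
#' @param seed integer seed used by every stochastic stage.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(preset = "mito-sbem", grid_shape = c(96L, 96L, 96L),
                    n_objects = 8L, n_speckle = 30L,
                    n_membrane_fragments = 4L,
                    semi_axis_range = c(60, 120)),
    preprocess = list(nlm_sigma = 0, bin = c(1L, 1L, 1L)),
    segment = list(lo = NULL, hi = NULL, min_voxels = 10L,
                   min_volume_um3 = NULL, max_variance = NULL,
                   connectivity = 26L),
    analyze = TRUE,
    evaluate = list(class = "mitochondria", iou = 0.5))
}

#' Run the full simulate / preprocess / segment / analyze / evaluate
#' pipeline
#'
#' Executes the bulk-segmentation pipeline end-to-end from one
#' configuration, writing every stage product to `out_dir`:
#' `volume.tif(.json)`, ground-truth masks `truth_*.tif` and catalogue,
#' `pre.tif` (preprocessed working volume), `labels.tif`, `filters.json`
#' (the filter log), `features.csv` and `report.json`. Given a fixed seed
#' the outputs are byte-identical across runs.
#'
#' @param config configuration list as from [default_pipeline_config()], or
#'   a path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param override optional named list merged over the config.
#' @return invisibly, a list with the output paths and the in-memory stage
#'   results (`volume`, `truth`, `pre`, `labels`, `log`, `features`,
#'   `report`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, override = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(override)) cfg <- utils::modifyList(cfg, override)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)

  sim <- cfg$simulate
  spec <- phantom_preset(sim$preset, grid_shape = sim$grid_shape,
                         rng_seed = cfg$seed)
  ph <- make_mitochondria_phantom(
    spec, n_objects = sim$n_objects, semi_axis_range = sim$semi_axis_range,
    n_speckle = sim$n_speckle,
    n_membrane_fragments = sim$n_membrane_fragments)
  write_stack(ph$volume, pth("volume.tif"))
  write_truth(ph$truth, pth("truth"))

  pre <- ph$volume
  if (cfg$preprocess$nlm_sigma > 0)
    pre <- denoise_nlm(pre, cfg$preprocess$nlm_sigma)
  if (any(cfg$preprocess$bin != 1L))
    pre <- bin_volume(pre, cfg$preprocess$bin)
  write_stack(pre, pth("pre.tif"))

  sg <- cfg$segment
  sep <- separating_range(spec)
  rng <- intensity_range(if (is.null(sg$lo)) sep$lo else sg$lo,
                         if (is.null(sg$hi)) sep$hi else sg$hi)
  maxv <- if (is.null(sg$max_variance)) (4 * spec$label_sd)^2
          else sg$max_variance
  seg <- bulk_segment(pre, rng, min_voxels = sg$min_voxels,
                      min_volume_um3 = sg$min_volume_um3,
                      max_variance = maxv, connectivity = sg$connectivity)
  write_labels(seg$labels, pth("labels.tif"))
  jsonlite::write_json(
    list(header = seg$log$header, records = seg$log$records),
    pth("filters.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  feats <- NULL
  if (isTRUE(cfg$analyze)) {
    feats <- rank_by_volume(compute_features(seg$labels, pre))
    utils::write.csv(feats, pth("features.csv"), row.names = FALSE)
  }

  report <- NULL
  if (!is.null(cfg$evaluate) &&
      identical(dim(seg$labels$labels), dim(ph$volume$values))) {
    report <- evaluate_against_truth(seg$labels, ph$truth,
                                     cfg$evaluate$class, cfg$evaluate$iou)
    jsonlite::write_json(unclass(report), pth("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(
    paths = list(volume = pth("volume.tif"), pre = pth("pre.tif"),
                 labels = pth("labels.tif"), filters = pth("filters.json"),
                 features = pth("features.csv"),
                 report = pth("report.json")),
    volume = ph$volume, truth = ph$truth, pre = pre, labels = seg$labels,
    log = seg$log, features = feats, report = report))
}
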