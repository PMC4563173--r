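#' Pipeline configuration
#'
#' Collects every tunable of the quantification pipeline with its default:
#' bone-mask HU threshold (100) and closing radius (3 mm), islanding
#' minimum component size P (10 voxels) and connectivity (26), the
#' red-marrow threshold multiplier k (2.5), the shared class prior (0.5),
#' the training-set size (1000 voxels) and LOOCV repetition count (50), the
#' master seed, and whether the injected dose is decay-corrected when
#' converting PET activity to SUV.
#'
#' @param hu_threshold Bone threshold, HU in \[-1024, 3071\].
#' @param closing_radius_mm Morphological closing radius, mm (>= 0).
#' @param min_island Minimum trabecular component size P, voxels (>= 1).
#' @param connectivity 6, 18 or 26.
#' @param k Red-threshold multiplier (> 0).
#' @param prior Class prior in (0, 1).
#' @param training_size Training voxels sampled when labels come as masks.
#' @param loocv_repetitions Repetitions of the LOOCV protocol.
#' @param seed Master integer seed; stage streams are derived from it.
#' @param decay_correct Logical, see [compute_suv()].
#' @param exclude_skull Logical; drop the skull ROI from the analyzed
#'   region (default `TRUE`: skull interior shows no meaningful marrow
#'   uptake signal for quantification).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(hu_threshold = 100, closing_radius_mm = 3,
                            min_island = 10, connectivity = 26,
                            k = 2.5, prior = 0.5, training_size = 1000,
                            loocv_repetitions = 50, seed = 17L,
                            decay_correct = TRUE, exclude_skull = TRUE) {
  cfg <- list(hu_threshold = hu_threshold,
              closing_radius_mm = closing_radius_mm,
              min_island = min_island, connectivity = connectivity,
              k = k, prior = prior, training_size = training_size,
              loocv_repetitions = loocv_repetitions, seed = as.integer(seed),
              decay_correct = isTRUE(decay_correct),
              exclude_skull = isTRUE(exclude_skull))
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks every field's range and rejects with the offending key named.
#'
#' @param cfg A list of configuration values (as from [pipeline_config()]
#'   or parsed from YAML).
#' @return The config, classed `pipeline_config`, with defaults filled in
#'   for absent keys.
#' @export
validate_config <- function(cfg) {
  defaults <- list(hu_threshold = 100, closing_radius_mm = 3, min_island = 10,
                   connectivity = 26, k = 2.5, prior = 0.5,
                   training_size = 1000, loocv_repetitions = 50, seed = 17L,
                   decay_correct = TRUE, exclude_skull = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop(sprintf("config: unknown key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, cfg)
  chk <- function(ok, key, msg)
    if (!isTRUE(ok)) stop(sprintf("config: invalid '%s': %s", key, msg))
  chk(is.numeric(cfg$hu_threshold) && cfg$hu_threshold >= -1024 &&
        cfg$hu_threshold <= 3071, "hu_threshold", "must lie in [-1024, 3071] HU")
  chk(is.numeric(cfg$closing_radius_mm) && cfg$closing_radius_mm >= 0,
      "closing_radius_mm", "must be >= 0 mm")
  chk(is.numeric(cfg$min_island) && cfg$min_island >= 1,
      "min_island", "must be a voxel count >= 1")
  chk(cfg$connectivity %in% c(6, 18, 26), "connectivity", "must be 6, 18 or 26")
  chk(is.numeric(cfg$k) && cfg$k > 0, "k", "must be > 0")
  chk(is.numeric(cfg$prior) && cfg$prior > 0 && cfg$prior < 1,
      "prior", "must lie strictly inside (0, 1)")
  chk(is.numeric(cfg$training_size) && cfg$training_size >= 4,
      "training_size", "must be >= 4")
  chk(is.numeric(cfg$loocv_repetitions) && cfg$loocv_repetitions >= 1,
      "loocv_repetitions", "must be >= 1")
  chk(is.numeric(cfg$seed), "seed", "must be an integer")
  chk(is.logical(cfg$decay_correct), "decay_correct", "must be logical")
  chk(is.logical(cfg$exclude_skull), "exclude_skull", "must be logical")
  structure(cfg, class = "pipeline_config")
}

#' Run the full marrow quantification pipeline
#'
#' Wires the stages end to end: bone-mask extraction from CT, discriminant
#' training and voxel-wise posterior classification into cortical and
#' trabecular compartments, islanding cleanup, SUV conversion (when the PET
#' grid carries raw activity and a calibration is given), vertebral
#' statistics, red-marrow thresholding, red/yellow segmentation, volumetry
#' and regional SUV summary. PET grids on a different geometry are
#' resampled to the CT grid first. Fully deterministic given the config
#' seed. Errors are re-raised with the failing stage named.
#'
#' @param ct CT-role `voxel_grid`.
#' @param pet PET-role `voxel_grid` (SUV, or Bq/ml with `calibration`).
#' @param training A [training_set()], or `NULL` to sample one from
#'   `rois$cortical` / `rois$trabecular` label masks.
#' @param rois Named list of logical ROI masks on the CT geometry:
#'   `vertebrae` (required: thoracic+lumbar vertebral ROI), optional
#'   `spine` (defaults to `vertebrae`), `skull`, and (for training)
#'   `cortical`/`trabecular`.
#' @param calibration Optional [suv_calibration()]; when supplied the PET
#'   grid is interpreted as Bq/ml and converted.
#' @param config A [pipeline_config()].
#' @return An object of class `marrow_report`: list with `report` (named
#'   scalars: volumes, fractions, threshold, SUV summary), `masks`
#'   (`compartment_masks`), `segmentation` (`marrow_segmentation`),
#'   `model`, `vertebral_stats`, `config`.
#' @export
run_pipeline <- function(ct, pet, training = NULL, rois = list(),
                         calibration = NULL, config = pipeline_config()) {
  config <- validate_config(unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  stopifnot(inherits(ct, "voxel_grid"), inherits(pet, "voxel_grid"))

  suv <- stage("suv", {
    p <- if (!same_geometry(pet, ct))
      resample_to_grid(pet, ct, "trilinear") else pet
    if (!is.null(calibration)) compute_suv(p, calibration, config$decay_correct)
    else voxel_grid(p$data, ct$spacing, ct$origin, role = "PET")
  })

  bone <- stage("bone_mask",
                extract_bone_mask(ct, config$hu_threshold,
                                  config$closing_radius_mm))

  if (is.null(training)) {
    training <- stage("training", {
      if (is.null(rois$cortical) || is.null(rois$trabecular))
        stop("no training set given and no cortical/trabecular label masks in 'rois'")
      sample_training_voxels(ct, rois$cortical, rois$trabecular,
                             n = config$training_size,
                             seed = derive_seed(config$seed, "training"))
    })
  }

  model <- stage("train_lda", train_lda(training, prior = config$prior))
  post <- stage("posterior", posterior_map(model, ct, bone))
  masks <- stage("classify", classify_compartments(post))
  masks <- stage("islanding",
                 filter_compartments(masks, config$min_island,
                                     config$connectivity))

  if (is.null(rois$vertebrae))
    stop("[vertebral_stats] missing vertebral ROI ('rois$vertebrae'); cannot derive the red-marrow threshold",
         call. = FALSE)
  vstats <- stage("vertebral_stats",
                  vertebral_statistics(suv, masks$trabecular, rois$vertebrae,
                                       multiplier = config$k))
  thr <- stage("red_threshold", red_threshold(vstats))
  exclude <- if (config$exclude_skull && !is.null(rois$skull)) rois$skull else NULL
  seg <- stage("segment_marrow", segment_marrow(suv, masks$trabecular, thr, exclude))
  vols <- stage("volumes", compute_volumes(seg, masks$trabecular, ct$spacing))
  spine <- if (is.null(rois$spine)) rois$vertebrae else rois$spine
  suvsum <- stage("suv_summary",
                  suv_summary(suv, masks$trabecular, spine, exclude))

  report <- c(vols[c("ibv_ml", "rbv_ml", "ybv_ml", "analyzed_ml", "red_fraction")],
              list(threshold_suv = thr,
                   vertebral_mean_suv = vstats$mean_suv,
                   vertebral_sd_suv = vstats$sd_suv,
                   vertebral_voxels = vstats$voxel_count),
              suvsum[c("spinal_mean_suv", "rob_mean_suv", "spine_to_rob_ratio")],
              list(skull_excluded = !is.null(exclude),
                   n_bone = sum(masks$bone),
                   n_cortical = sum(masks$cortical),
                   n_trabecular = sum(masks$trabecular)))

  structure(list(report = report, masks = masks, segmentation = seg,
                 suv = suv, model = model, vertebral_stats = vstats,
                 config = config),
            class = "marrow_report")
}

#' @export
print.marrow_report <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<marrow_report>\n",
                     "  IBV %.1f ml | RBV %.1f ml | YBV %.1f ml | red fraction %.3f\n",
                     "  SUV threshold %.3f (vertebral %.3f +/- %.3f, k = %.2f)\n",
                     "  spine/ROB SUV %.3f / %.3f (ratio %.2f); skull excluded: %s\n"),
              r$ibv_ml, r$rbv_ml, r$ybv_ml, r$red_fraction,
              r$threshold_suv, r$vertebral_mean_suv, r$vertebral_sd_suv,
              x$config$k, r$spinal_mean_suv, r$rob_mean_suv,
              r$spine_to_rob_ratio, r$skull_excluded))
  invisible(x)
}

#' Write a pipeline report to JSON (and optionally a CSV row)
#'
#' The JSON carries the scalar report fields plus the fully resolved
#' configuration for provenance; the optional CSV row holds the volume and
#' SUV fields for cohort accumulation.
#'
#' @param result A `marrow_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @param csv_path Optional CSV path (one row).
#' @param id Subject identifier recorded in the CSV row.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, csv_path = NULL, id = "subject") {
  stopifnot(inherits(result, "marrow_report"))
  payload <- list(schema = "marrowmap-report-v1",
                  report = result$report,
                  config = unclass(result$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csv_path)) {
    row <- c(list(id = id), result$report)
    utils::write.csv(as.data.frame(row), csv_path, row.names = FALSE)
  }
  invisible(path)
}
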