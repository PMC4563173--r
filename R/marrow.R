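#' Vertebral SUV statistics for the red-marrow threshold
#'
#' Mean and sample standard deviation (denominator n - 1) of SUV over the
#' trabecular voxels inside the vertebral region of interest (thoracic and
#' lumbar vertebrae). These patient-specific statistics drive the
#' red-marrow threshold instead of a fixed SUV cut.
#'
#' @param suv PET-role `voxel_grid` of SUV values.
#' @param trabecular Logical trabecular mask on the SUV geometry.
#' @param vertebral_roi Logical vertebral ROI mask.
#' @param multiplier Threshold multiplier k (> 0), default 2.5.
#' @return An object of class `vertebral_statistics`: list with `mean_suv`,
#'   `sd_suv`, `voxel_count`, `multiplier`.
#' @export
vertebral_statistics <- function(suv, trabecular, vertebral_roi, multiplier = 2.5) {
  stopifnot(inherits(suv, "voxel_grid"))
  if (!is.finite(multiplier) || multiplier <= 0)
    stop("vertebral_statistics: multiplier must be > 0")
  trabecular <- as_mask_array(trabecular, dim(suv$data), "trabecular mask")
  vertebral_roi <- as_mask_array(vertebral_roi, dim(suv$data), "vertebral ROI")
  sel <- trabecular & vertebral_roi
  n <- sum(sel)
  if (n < 2L)
    stop("vertebral_statistics: vertebral ROI intersects fewer than 2 trabecular voxels; the ROI misses trabecular bone")
  vals <- suv$data[sel]
  structure(list(mean_suv = mean(vals), sd_suv = stats::sd(vals),
                 voxel_count = n, multiplier = multiplier),
            class = "vertebral_statistics")
}

#' Red-marrow SUV threshold
#'
#' `threshold = mean_suv - k * sd_suv`, the statistically driven,
#' patient-specific cut separating active (red) from inactive (yellow)
#' marrow. The threshold may be negative when the vertebral spread is
#' large; since SUV is non-negative, every analyzed voxel is then red (a
#' warning is emitted).
#'
#' @param stats A [vertebral_statistics()] object.
#' @return Scalar SUV threshold.
#' @export
red_threshold <- function(stats) {
  stopifnot(inherits(stats, "vertebral_statistics"))
  thr <- stats$mean_suv - stats$multiplier * stats$sd_suv
  if (thr < 0)
    warning(sprintf("red_threshold: threshold %.4g is negative; all analyzed voxels will be classified red", thr))
  thr
}

#' Partition trabecular PET activity into red and yellow marrow
#'
#' The analyzed region is the trabecular mask minus any exclusion mask
#' (typically the skull, whose trabecular-like interior shows no meaningful
#' marrow uptake with FDG-driven thresholds). Voxels strictly above the
#' threshold are red (active) marrow; voxels at or below it are yellow.
#'
#' @param suv PET-role `voxel_grid` of SUV values.
#' @param trabecular Logical trabecular mask.
#' @param threshold SUV threshold (see [red_threshold()]).
#' @param exclude Optional logical mask of voxels to leave out of the
#'   analysis (e.g. the skull ROI).
#' @return An object of class `marrow_segmentation`: list with logical
#'   arrays `red`, `yellow`, `analyzed` and the scalar `threshold`.
#' @export
segment_marrow <- function(suv, trabecular, threshold, exclude = NULL) {
  stopifnot(inherits(suv, "voxel_grid"), is.finite(threshold))
  trabecular <- as_mask_array(trabecular, dim(suv$data), "trabecular mask")
  analyzed <- trabecular
  if (!is.null(exclude))
    analyzed <- analyzed & !as_mask_array(exclude, dim(suv$data), "exclusion mask")
  red <- analyzed & (suv$data > threshold)
  yellow <- analyzed & !red
  structure(list(red = red, yellow = yellow, analyzed = analyzed,
                 threshold = threshold),
            class = "marrow_segmentation")
}

#' Volumes of the marrow compartments in millilitres
#'
#' Converts voxel counts to ml using the voxel volume. IBV is the volume of
#' the full trabecular compartment; RBV and YBV partition the analyzed
#' region exactly, and the red fraction is RBV over the analyzed volume.
#'
#' @param seg A [segment_marrow()] result.
#' @param trabecular Logical full trabecular mask (for IBV).
#' @param spacing Voxel spacing in mm (length 3), or a `voxel_grid` to take
#'   it from.
#' @return List with `ibv_ml`, `rbv_ml`, `ybv_ml`, `analyzed_ml`,
#'   `red_fraction` and the voxel counts.
#' @export
compute_volumes <- function(seg, trabecular, spacing) {
  stopifnot(inherits(seg, "marrow_segmentation"))
  if (inherits(spacing, "voxel_grid")) spacing <- spacing$spacing
  vox_ml <- prod(spacing) / 1000
  trabecular <- as_mask_array(trabecular, dim(seg$red), "trabecular mask")
  n_red <- sum(seg$red); n_yellow <- sum(seg$yellow)
  n_analyzed <- sum(seg$analyzed); n_trab <- sum(trabecular)
  list(ibv_ml = n_trab * vox_ml,
       rbv_ml = n_red * vox_ml,
       ybv_ml = n_yellow * vox_ml,
       analyzed_ml = n_analyzed * vox_ml,
       red_fraction = if (n_analyzed > 0) n_red / n_analyzed else NA_real_,
       n_red = n_red, n_yellow = n_yellow,
       n_analyzed = n_analyzed, n_trabecular = n_trab)
}

#' Regional SUV summary: spine versus rest of body
#'
#' Mean SUV over the trabecular spine region and over the rest of the
#' trabecular skeleton (minus the spine and, optionally, the skull), and
#' their ratio — the spine-to-rest-of-body contrast of the tracer.
#'
#' @param suv PET-role `voxel_grid` of SUV values.
#' @param trabecular Logical trabecular mask.
#' @param spine_roi Logical spinal-column ROI.
#' @param skull_roi Optional logical skull ROI excluded from the rest of
#'   body.
#' @return List with `spinal_mean_suv`, `rob_mean_suv`,
#'   `spine_to_rob_ratio` and the region voxel counts.
#' @export
suv_summary <- function(suv, trabecular, spine_roi, skull_roi = NULL) {
  stopifnot(inherits(suv, "voxel_grid"))
  trabecular <- as_mask_array(trabecular, dim(suv$data), "trabecular mask")
  spine_roi <- as_mask_array(spine_roi, dim(suv$data), "spine ROI")
  spine <- trabecular & spine_roi
  rob <- trabecular & !spine_roi
  if (!is.null(skull_roi))
    rob <- rob & !as_mask_array(skull_roi, dim(suv$data), "skull ROI")
  if (!any(spine))
    stop("suv_summary: spine ROI intersects no trabecular voxels")
  if (!any(rob))
    stop("suv_summary: rest-of-body region is empty")
  spinal_mean <- mean(suv$data[spine])
  rob_mean <- mean(suv$data[rob])
  list(spinal_mean_suv = spinal_mean,
       rob_mean_suv = rob_mean,
       spine_to_rob_ratio = spinal_mean / rob_mean,
       n_spine = sum(spine), n_rob = sum(rob))
}
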