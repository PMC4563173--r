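# 3-D binary morphology by vectorized array shifts. The structuring element
# is an ellipsoidal ball whose mm radius is converted to per-axis voxel radii,
# so anisotropic spacings get isotropic physical behaviour.

shift_array <- function(x, off, fill = FALSE) {
  d <- dim(x)
  if (all(off == 0L)) return(x)
  if (any(abs(off) >= d)) return(array(fill, d))
  out <- array(fill, d)
  idx_dst <- idx_src <- vector("list", 3L)
  for (i in 1:3) {
    o <- off[i]
    if (o >= 0) {
      idx_dst[[i]] <- (1 + o):d[i]; idx_src[[i]] <- 1:(d[i] - o)
    } else {
      idx_dst[[i]] <- 1:(d[i] + o); idx_src[[i]] <- (1 - o):d[i]
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Offsets (rows) of an ellipsoidal ball with radius_mm, in voxel steps.
ball_offsets <- function(radius_mm, spacing) {
  r_vox <- radius_mm / spacing
  rng <- lapply(r_vox, function(r) -floor(r + 1e-9):floor(r + 1e-9))
  g <- as.matrix(expand.grid(dx = rng[[1]], dy = rng[[2]], dz = rng[[3]]))
  keep <- rowSums(sweep(g, 2, pmax(r_vox, 1e-12), "/")^2) <= 1 + 1e-9
  g[keep, , drop = FALSE]
}

binary_dilate <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  for (k in seq_len(nrow(offsets)))
    out <- out | shift_array(mask, offsets[k, ], fill = FALSE)
  out
}

binary_erode <- function(mask, offsets) {
  out <- array(TRUE, dim(mask))
  for (k in seq_len(nrow(offsets))) {
    out <- out & shift_array(mask, offsets[k, ], fill = FALSE)
    if (!any(out)) break
  }
  out
}

#' Extract the bone compartment from a CT volume
#'
#' Thresholds the CT at `hu_threshold` and applies a morphological closing
#' with an ellipsoidal element of physical radius `closing_radius_mm`, which
#' recaptures trabecular interior voxels whose noisy Hounsfield value dips
#' below the threshold. The result is clamped to contain the raw thresholded
#' mask (closing is extensive), including at the volume boundary.
#'
#' @param ct CT-role `voxel_grid` in Hounsfield units.
#' @param hu_threshold Threshold in HU; must lie in the plausible CT range
#'   \[-1024, 3071\]. Default 100, between soft tissue and trabecular bone.
#' @param closing_radius_mm Radius (mm) of the closing element; 0 disables
#'   closing. Default 3.
#' @return Logical 3-D array on the CT geometry: the bone mask.
#' @export
extract_bone_mask <- function(ct, hu_threshold = 100, closing_radius_mm = 3) {
  stopifnot(inherits(ct, "voxel_grid"))
  if (!is.finite(hu_threshold) || hu_threshold < -1024 || hu_threshold > 3071)
    stop("extract_bone_mask: hu_threshold outside the plausible HU range [-1024, 3071]")
  if (!is.finite(closing_radius_mm) || closing_radius_mm < 0)
    stop("extract_bone_mask: closing_radius_mm must be >= 0")
  raw <- ct$data >= hu_threshold
  if (closing_radius_mm == 0) return(raw)
  offs <- ball_offsets(closing_radius_mm, ct$spacing)
  if (nrow(offs) <= 1L) return(raw)
  closed <- binary_erode(binary_dilate(raw, offs), offs)
  closed | raw
}
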