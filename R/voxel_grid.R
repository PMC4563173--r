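#' Construct a voxel grid
#'
#' A `voxel_grid` is the package's container for a 3-D scalar volume with
#' physical geometry: the voxel data (Hounsfield units for CT, Bq/ml or SUV
#' for PET, 0/1 for masks), the per-axis voxel edge lengths in millimetres,
#' and the physical position of voxel (1,1,1) in millimetres. Axes are
#' assumed axis-aligned (no rotation), matching a diagonal NIfTI affine.
#'
#' @param data 3-D numeric or logical array.
#' @param spacing Numeric length-3, voxel edge lengths in mm; all > 0.
#' @param origin Numeric length-3, physical coordinate (mm) of the centre of
#'   voxel (1,1,1).
#' @param role One of `"CT"`, `"PET"`, `"mask"`. PET-role grids must be
#'   non-negative (SUV or activity concentration); mask grids are stored as
#'   logical.
#' @return An object of class `voxel_grid`: a list with elements `data`,
#'   `spacing`, `origin`, `role`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume_ml(g) * prod(dim(g$data))  # total volume in ml
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       role = c("CT", "PET", "mask")) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L || any(dim(data) == 0L))
    stop("voxel_grid: 'data' must be a non-empty 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_grid: 'spacing' must be three strictly positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("voxel_grid: 'origin' must be three finite numbers (mm)")
  if (role == "mask") {
    storage.mode(data) <- "logical"
  } else {
    storage.mode(data) <- "double"
  }
  if (role == "PET" && any(data < 0, na.rm = TRUE))
    stop("voxel_grid: PET-role grids must be non-negative")
  structure(list(data = data, spacing = spacing, origin = origin, role = role),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid [%s]> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$role, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm; range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              suppressWarnings(min(x$data, na.rm = TRUE)),
              suppressWarnings(max(x$data, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Volume of one voxel in millilitres
#'
#' @param grid A `voxel_grid` (or anything with a `spacing` element in mm).
#' @return Scalar, voxel volume in ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) prod(grid$spacing) / 1000

#' Check that two grids share shape and physical geometry
#'
#' @param a,b `voxel_grid` objects.
#' @param tol Tolerance (mm) on spacing and origin agreement.
#' @return `TRUE` or `FALSE`.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_differs <- function(a, b, what) {
  if (!same_geometry(a, b))
    stop(sprintf("%s: grids differ in shape, spacing or origin", what))
  invisible(TRUE)
}

# Coerce a logical mask argument (voxel_grid or plain array) to a logical array
# of the stated dimensions.
as_mask_array <- function(mask, dims, what = "mask") {
  if (inherits(mask, "voxel_grid")) mask <- mask$data
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop(sprintf("%s must be a 3-D array or voxel_grid", what))
  if (!identical(dim(mask), as.integer(dims)) && !identical(dim(mask), dims))
    stop(sprintf("%s has dimensions %s, expected %s", what,
                 paste(dim(mask), collapse = "x"), paste(dims, collapse = "x")))
  storage.mode(mask) <- "logical"
  mask
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible stream seed (< 2^31) from a master seed and a stage tag,
# so pipeline stages are individually reproducible.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
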