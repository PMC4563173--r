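#' Read a volume from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` file into a [voxel_grid()]. Spacing is taken from
#' the header `pixdim`, the origin from the translation column of the sform
#' (falling back to the qform) affine. Only 3-D volumes are accepted;
#' 4-D files with a singleton fourth dimension are squeezed.
#'
#' @param path Path to a NIfTI file.
#' @param role Grid role, `"CT"`, `"PET"` or `"mask"` (see [voxel_grid()]).
#' @return A `voxel_grid`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, role = c("CT", "PET", "mask")) {
  role <- match.arg(role)
  if (!file.exists(path))
    stop(sprintf("read_volume: file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "read_volume: cannot read '%s' as NIfTI: %s",
                    path, conditionMessage(e))))
  dat <- as.array(img)
  d <- dim(dat)
  if (length(d) == 4L && d[4] == 1L) {
    dat <- array(dat, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop(sprintf("read_volume: '%s' is %d-dimensional, expected a 3-D volume",
                 path, length(d)))
  spacing <- abs(RNifti::pixdim(img)[1:3])
  aff <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(aff, "try-error")) c(0, 0, 0) else unclass(aff)[1:3, 4]
  attributes(dat) <- list(dim = d)
  voxel_grid(dat, spacing = spacing, origin = origin, role = role)
}

#' Write a volume to a NIfTI file
#'
#' Writes a [voxel_grid()] to NIfTI with a diagonal affine reproducing its
#' spacing and origin. Continuous volumes (CT/PET) are stored as
#' double-precision floats so that a read/write round trip is bit-exact;
#' mask-role grids are stored as 0/1 16-bit integers.
#'
#' @param grid A `voxel_grid`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("write_volume: directory does not exist: %s", dirname(path)))
  dat <- grid$data
  is_mask <- grid$role == "mask" || is.logical(dat)
  if (is_mask) {
    storage.mode(dat) <- "integer"
  } else {
    storage.mode(dat) <- "double"
  }
  attr(dat, "pixdim") <- grid$spacing
  attr(dat, "pixunits") <- c("mm", "s")
  dtype <- if (is_mask) "int16" else "double"
  img <- RNifti::asNifti(dat, datatype = dtype)
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}
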