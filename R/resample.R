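#' Resample a volume onto the geometry of a reference grid
#'
#' Interpolates `moving` in physical (mm) space at the voxel centres of
#' `reference`, returning a grid with the reference's shape, spacing and
#' origin. Both grids are taken as axis-aligned. Sample points falling
#' outside the physical extent of `moving` (beyond the centre of its first
#' or last voxel on any axis) are filled with 0.
#'
#' Use nearest-neighbour interpolation for label masks; trilinear for
#' continuous CT/PET data.
#'
#' @param moving `voxel_grid` to be resampled.
#' @param reference `voxel_grid` supplying the target geometry.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A `voxel_grid` on the reference geometry carrying the moving
#'   grid's role.
#' @export
resample_to_grid <- function(moving, reference,
                             interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(moving, "voxel_grid"), inherits(reference, "voxel_grid"))
  if (same_geometry(moving, reference))
    return(voxel_grid(moving$data, reference$spacing, reference$origin,
                      role = moving$role))

  dm <- dim(moving$data)
  dr <- dim(reference$data)
  # physical extent overlap check (voxel-centre bounding boxes)
  lo_m <- moving$origin
  hi_m <- moving$origin + (dm - 1) * moving$spacing
  lo_r <- reference$origin
  hi_r <- reference$origin + (dr - 1) * reference$spacing
  if (any(hi_m < lo_r - 1e-9) || any(lo_m > hi_r + 1e-9))
    stop("resample_to_grid: grids have no spatial overlap")

  # continuous (1-based) index of every reference voxel centre in moving space
  ci <- lapply(1:3, function(ax) {
    phys <- reference$origin[ax] + (seq_len(dr[ax]) - 1) * reference$spacing[ax]
    (phys - moving$origin[ax]) / moving$spacing[ax] + 1
  })
  inside1 <- ci[[1]] >= 1 - 1e-9 & ci[[1]] <= dm[1] + 1e-9
  inside2 <- ci[[2]] >= 1 - 1e-9 & ci[[2]] <= dm[2] + 1e-9
  inside3 <- ci[[3]] >= 1 - 1e-9 & ci[[3]] <= dm[3] + 1e-9

  src <- moving$data
  was_logical <- is.logical(src)
  storage.mode(src) <- "double"

  if (interpolation == "nearest") {
    ix <- pmin(pmax(round(ci[[1]]), 1), dm[1])
    iy <- pmin(pmax(round(ci[[2]]), 1), dm[2])
    iz <- pmin(pmax(round(ci[[3]]), 1), dm[3])
    out <- src[cbind(rep(ix, times = dr[2] * dr[3]),
                     rep(rep(iy, each = dr[1]), times = dr[3]),
                     rep(iz, each = dr[1] * dr[2]))]
  } else {
    x0 <- pmin(pmax(floor(ci[[1]]), 1), dm[1]); fx <- pmin(pmax(ci[[1]] - x0, 0), 1)
    y0 <- pmin(pmax(floor(ci[[2]]), 1), dm[2]); fy <- pmin(pmax(ci[[2]] - y0, 0), 1)
    z0 <- pmin(pmax(floor(ci[[3]]), 1), dm[3]); fz <- pmin(pmax(ci[[3]] - z0, 0), 1)
    x1 <- pmin(x0 + 1, dm[1]); y1 <- pmin(y0 + 1, dm[2]); z1 <- pmin(z0 + 1, dm[3])

    n <- prod(dr)
    X0 <- rep(x0, times = dr[2] * dr[3]); X1 <- rep(x1, times = dr[2] * dr[3])
    FX <- rep(fx, times = dr[2] * dr[3])
    Y0 <- rep(rep(y0, each = dr[1]), times = dr[3])
    Y1 <- rep(rep(y1, each = dr[1]), times = dr[3])
    FY <- rep(rep(fy, each = dr[1]), times = dr[3])
    Z0 <- rep(z0, each = dr[1] * dr[2]); Z1 <- rep(z1, each = dr[1] * dr[2])
    FZ <- rep(fz, each = dr[1] * dr[2])

    g <- function(ix, iy, iz) src[cbind(ix, iy, iz)]
    out <- (1 - FZ) * ((1 - FY) * ((1 - FX) * g(X0, Y0, Z0) + FX * g(X1, Y0, Z0)) +
                       FY * ((1 - FX) * g(X0, Y1, Z0) + FX * g(X1, Y1, Z0))) +
           FZ * ((1 - FY) * ((1 - FX) * g(X0, Y0, Z1) + FX * g(X1, Y0, Z1)) +
                 FY * ((1 - FX) * g(X0, Y1, Z1) + FX * g(X1, Y1, Z1)))
  }

  out <- array(out, dr)
  inside <- outer(outer(inside1, inside2, "&"), inside3, "&")
  out[!inside] <- 0
  if (was_logical || moving$role == "mask") out <- out > 0.5
  voxel_grid(out, reference$spacing, reference$origin, role = moving$role)
}
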