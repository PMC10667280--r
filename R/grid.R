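#' Voxel lattice
#'
#' A regular 1D or 3D voxel grid. Coordinates are voxel centres, lengths are in
#' centimetres, indices are 1-based along each axis.
#'
#' @param shape integer vector of voxel counts (length 1 or 3); every active
#'   axis needs at least 3 voxels so finite-difference stencils have interior
#'   points.
#' @param spacing voxel edge length per axis in cm (recycled to `length(shape)`).
#' @param origin physical coordinate of the first voxel centre per axis, cm.
#' @return an object of class `pde_grid`.
#' @export
pde_grid <- function(shape, spacing, origin = 0) {
  shape <- as.integer(shape)
  ndim <- length(shape)
  if (!ndim %in% c(1L, 3L)) stop("grid must be 1D or 3D")
  if (any(shape < 3L)) stop("each axis needs at least 3 voxels")
  spacing <- rep_len(as.numeric(spacing), ndim)
  origin <- rep_len(as.numeric(origin), ndim)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(ndim = ndim, shape = shape, spacing = spacing, origin = origin),
            class = "pde_grid")
}

#' @export
print.pde_grid <- function(x, ...) {
  cat(sprintf("<pde_grid> %dD, shape [%s], spacing [%s] cm\n",
              x$ndim, paste(x$shape, collapse = " x "),
              paste(signif(x$spacing, 4), collapse = ", ")))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

#' Voxel-centre coordinates
#'
#' @param grid a [pde_grid()].
#' @return an `n x ndim` matrix of physical coordinates (cm), voxels in
#'   column-major (R array) order.
#' @export
grid_coords <- function(grid) {
  axes <- lapply(seq_len(grid$ndim), function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
  if (grid$ndim == 1L) return(matrix(axes[[1]], ncol = 1))
  as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

# Interior faces of the lattice, grouped by axis. Each face joins the voxel
# pair (lo, hi) adjacent along that axis; `h` is the face-normal spacing.
# Within one axis every voxel occurs at most once as lo and once as hi, so
# vectorized accumulation by subscript is safe.
grid_faces <- function(grid) {
  arr <- array(seq_len(n_voxels(grid)), dim = grid$shape)
  lapply(seq_len(grid$ndim), function(a) {
    ind <- slice.index(arr, a)
    list(lo = arr[ind < grid$shape[a]], hi = arr[ind > 1L], h = grid$spacing[a])
  })
}

#' Tumour geometry on a grid
#'
#' Pairs a grid with a logical tumour mask; the mask selects the tumour value
#' of every stepped tissue parameter.
#'
#' @param grid a [pde_grid()].
#' @param mask logical vector/array with one entry per voxel, `TRUE` inside the
#'   tumour; at least one voxel must be tumour.
#' @return an object of class `tumour_geometry`.
#' @export
tumour_geometry <- function(grid, mask) {
  stopifnot(inherits(grid, "pde_grid"))
  mask <- as.logical(mask)
  if (length(mask) != n_voxels(grid)) stop("mask length must equal the voxel count")
  if (anyNA(mask)) stop("mask must not contain NA")
  if (!any(mask)) stop("mask must contain at least one tumour voxel")
  structure(list(grid = grid, mask = mask), class = "tumour_geometry")
}

#' @export
print.tumour_geometry <- function(x, ...) {
  cat(sprintf("<tumour_geometry> %d/%d tumour voxels on ", sum(x$mask),
              n_voxels(x$grid)))
  print(x$grid)
  invisible(x)
}

#' Centred 1D tumour geometry
#'
#' The synthetic-study domain: an interval of given length with a tumour of
#' given diameter centred in the middle.
#'
#' @param length_cm domain length, cm.
#' @param nx number of voxels.
#' @param diameter_cm tumour diameter, cm.
#' @return a [tumour_geometry()].
#' @export
centred_tumour_1d <- function(length_cm = 10, nx = 200, diameter_cm = 2) {
  grid <- pde_grid(nx, spacing = length_cm / nx, origin = length_cm / nx / 2)
  x <- grid_coords(grid)[, 1]
  tumour_geometry(grid, abs(x - length_cm / 2) < diameter_cm / 2)
}

#' Centred 3D tumour geometry
#'
#' A cubic domain with a centred spherical tumour; used to exercise the 3D
#' code paths on small synthetic fixtures.
#'
#' @param length_cm edge length of the cubic domain, cm.
#' @param nx voxels per axis.
#' @param diameter_cm tumour diameter, cm.
#' @return a [tumour_geometry()].
#' @export
centred_tumour_3d <- function(length_cm = 10, nx = 20, diameter_cm = 2) {
  grid <- pde_grid(rep(nx, 3), spacing = length_cm / nx, origin = length_cm / nx / 2)
  xyz <- grid_coords(grid)
  r2 <- rowSums(sweep(xyz, 2, rep(length_cm / 2, 3))^2)
  tumour_geometry(grid, r2 < (diameter_cm / 2)^2)
}

check_field <- function(values, grid, what = "field") {
  values <- as.numeric(values)
  if (length(values) != n_voxels(grid))
    stop(sprintf("%s length (%d) does not match the grid (%d voxels)",
                 what, length(values), n_voxels(grid)))
  if (any(!is.finite(values))) stop(sprintf("%s contains non-finite values", what))
  values
}

#' Pressure field on a grid
#'
#' @param grid a [pde_grid()].
#' @param values pressure per voxel, mmHg.
#' @return an object of class `pressure_field`.
#' @export
pressure_field <- function(grid, values) {
  structure(list(grid = grid, values = check_field(values, grid, "pressure")),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field> range [%.3g, %.3g] mmHg on ",
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Concentration time course on a grid
#'
#' @param grid a [pde_grid()].
#' @param times strictly increasing sample times, seconds.
#' @param values `n_voxels x n_times` matrix of concentrations, mgI/cm^3.
#' @return an object of class `concentration_field`.
#' @export
concentration_field <- function(grid, times, values) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  values <- as.matrix(values)
  if (nrow(values) != n_voxels(grid) || ncol(values) != length(times))
    stop("values must be n_voxels x n_times")
  if (any(!is.finite(values))) stop("concentration values must be finite")
  structure(list(grid = grid, times = times, values = values),
            class = "concentration_field")
}

#' Snapshot pair: the data the inverse problem consumes
#'
#' @param u1,u2 concentration maps (mgI/cm^3) on the geometry's grid at times
#'   `t1 < t2`.
#' @param t1,t2 acquisition times, seconds.
#' @param geom a [tumour_geometry()] carrying the grid and tumour mask.
#' @return an object of class `snapshot_pair` with `dt = t2 - t1`.
#' @export
snapshot_pair <- function(u1, u2, t1, t2, geom) {
  stopifnot(inherits(geom, "tumour_geometry"))
  if (!(t2 > t1)) stop("t2 must be greater than t1")
  u1 <- check_field(u1, geom$grid, "u1")
  u2 <- check_field(u2, geom$grid, "u2")
  structure(list(u1 = u1, u2 = u2, t1 = as.numeric(t1), t2 = as.numeric(t2),
                 dt = as.numeric(t2 - t1), geom = geom),
            class = "snapshot_pair")
}

#' @export
print.snapshot_pair <- function(x, ...) {
  cat(sprintf("<snapshot_pair> t1 = %.3g h, t2 = %.3g h, max u2 = %.3g mgI/cm^3 on ",
              x$t1 / 3600, x$t2 / 3600, max(x$u2)))
  print(x$geom$grid)
  invisible(x)
}
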