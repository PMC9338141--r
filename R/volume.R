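#' Scalar MR volume with grid geometry
#'
#' A `volume` couples a 3D scalar intensity array with its grid geometry:
#' per-axis voxel spacing (mm), the world position of the centre of voxel
#' (0,0,0), and a 3x3 orthonormal direction matrix. Voxel indices are
#' 0-based and world coordinates refer to voxel centres, so
#' `world = origin + direction %*% (index * spacing)`.
#'
#' @param data numeric 3D array of intensities (all finite).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param direction 3x3 orthonormal matrix with determinant +1 giving the
#'   world direction of each index axis.
#' @return An object of class `volume`.
#' @examples
#' v <- volume(array(rnorm(8^3), c(8, 8, 8)), spacing = c(0.4, 0.4, 0.4))
#' world_from_index(v, c(1, 0, 0))
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels per axis")
  storage.mode(data) <- "double"
  attributes(data) <- list(dim = dim(data))  # drop foreign attributes
  if (!all(is.finite(data)))
    stop("all intensities must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive values")
  if (length(origin) != 3L) stop("'origin' must have length 3")
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(det(direction) - 1) > 1e-6)
    stop("'direction' must be orthonormal with determinant +1")
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume")
}

#' @export
dim.volume <- function(x) dim(x$data)

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %s mm\n", d[1], d[2],
              d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, intensity range [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Test for volume objects
#' @param x object.
#' @return `TRUE` for objects created by [volume()].
#' @export
is_volume <- function(x) inherits(x, "volume")

#' Create a volume sharing another volume's geometry
#'
#' @param data 3D array congruent with `ref`.
#' @param ref a [volume()] supplying spacing/origin/direction.
#' @return A `volume`.
#' @export
volume_like <- function(data, ref) {
  stopifnot(is_volume(ref))
  if (!all(dim(data) == dim(ref)))
    stop("'data' shape does not match the reference volume")
  volume(data, spacing = ref$spacing, origin = ref$origin,
         direction = ref$direction)
}

check_congruent <- function(a, b, what = "volumes") {
  if (!all(dim(a) == dim(b)))
    stop(sprintf("%s have different grid shapes", what))
  invisible(TRUE)
}

#' Map voxel indices to world coordinates
#'
#' Applies `world = origin + direction %*% (ijk * spacing)` with 0-based
#' indices referring to voxel centres.
#'
#' @param vol a [volume()].
#' @param ijk integer triple, or an n x 3 matrix of index triples (0-based).
#' @param check if `TRUE` (default), error on out-of-bounds indices.
#' @return World coordinates (mm): length-3 vector or n x 3 matrix.
#' @export
world_from_index <- function(vol, ijk, check = TRUE) {
  stopifnot(is_volume(vol))
  m <- if (is.matrix(ijk)) ijk else matrix(ijk, nrow = 1)
  if (ncol(m) != 3L) stop("'ijk' must have 3 columns")
  if (check) {
    d <- dim(vol)
    if (any(m < 0) || any(m[, 1] > d[1] - 1) || any(m[, 2] > d[2] - 1) ||
        any(m[, 3] > d[3] - 1))
      stop("voxel index out of bounds")
  }
  w <- sweep(m, 2, vol$spacing, "*") %*% t(vol$direction)
  w <- sweep(w, 2, vol$origin, "+")
  if (is.matrix(ijk)) w else drop(w)
}

#' Map world coordinates to (continuous) voxel indices
#'
#' Exact inverse of [world_from_index()] on lattice points; general world
#' points map to continuous index coordinates.
#'
#' @param vol a [volume()].
#' @param xyz world point (mm), or an n x 3 matrix of points.
#' @return Continuous 0-based index coordinates, same shape as input.
#' @export
index_from_world <- function(vol, xyz) {
  stopifnot(is_volume(vol))
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  u <- sweep(m, 2, vol$origin, "-") %*% vol$direction  # = t(D) applied rowwise
  idx <- sweep(u, 2, vol$spacing, "/")
  if (is.matrix(xyz)) idx else drop(idx)
}

#' Trilinear sampling at world points
#'
#' Interpolates the 8 surrounding voxels in index space. Points outside
#' the grid return `outside` (default 0: background is dark in both
#' sequences handled by this package).
#'
#' @param vol a [volume()].
#' @param xyz world point (mm) or n x 3 matrix of points.
#' @param outside value returned for points outside the grid.
#' @return Numeric vector of sampled intensities.
#' @export
sample_trilinear <- function(vol, xyz, outside = 0) {
  stopifnot(is_volume(vol))
  idx <- index_from_world(vol, xyz)
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = 1)
  cpp_sample_trilinear(vol$data, dim(vol), idx, outside)
}

#' Nearest-neighbour sampling at world points
#'
#' For categorical grids (label maps) where interpolation is meaningless.
#'
#' @inheritParams sample_trilinear
#' @return Numeric vector of sampled values.
#' @export
sample_nearest <- function(vol, xyz, outside = 0) {
  stopifnot(is_volume(vol))
  idx <- index_from_world(vol, xyz)
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = 1)
  cpp_sample_nearest(vol$data, dim(vol), idx, outside)
}

#' All voxel-centre world coordinates of a grid
#'
#' @param vol a [volume()].
#' @param stride optional integer subsampling stride per axis.
#' @return n x 3 matrix of world coordinates in column-major voxel order.
#' @export
grid_points <- function(vol, stride = 1L) {
  d <- dim(vol)
  ii <- seq(0L, d[1] - 1L, by = stride)
  jj <- seq(0L, d[2] - 1L, by = stride)
  kk <- seq(0L, d[3] - 1L, by = stride)
  idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  world_from_index(vol, idx, check = FALSE)
}

#' Axis-aligned half-open voxel bounding box
#'
#' Per-axis index intervals `[lo, hi)`, 0-based.
#'
#' @param lo integer length-3 lower corner (inclusive).
#' @param hi integer length-3 upper corner (exclusive).
#' @return Object of class `bounding_box`.
#' @export
bounding_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(lo < 0) || any(lo >= hi))
    stop("invalid bounding box: need 0 <= lo < hi per axis")
  structure(list(lo = lo, hi = hi), class = "bounding_box")
}

#' Bounding box covering a whole grid
#' @param vol a [volume()].
#' @return A [bounding_box()] spanning all voxels.
#' @export
full_bbox <- function(vol) bounding_box(c(0, 0, 0), dim(vol))

check_bbox <- function(bbox, d) {
  if (!inherits(bbox, "bounding_box")) stop("invalid bounding box")
  if (any(bbox$hi > d)) stop("bounding box exceeds the grid")
  invisible(bbox)
}

#' Geometric centre of a volume (world mm)
#' @param vol a [volume()].
#' @return Length-3 world coordinate of the grid centre.
#' @export
volume_center <- function(vol) {
  world_from_index(vol, (dim(vol) - 1) / 2, check = FALSE)
}
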