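#' Rigid (6-DOF) spatial transform
#'
#' Maps fixed-image world points into moving-image world space:
#' `y = R %*% x + t`. Used for resampling the moving (TOF) volume on the
#' fixed (CISS) grid.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector, mm.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("'rotation' must be orthonormal with determinant +1")
  if (length(translation) != 3L) stop("'translation' must have length 3")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat(sprintf("  rotation angle %.3f deg, translation (%s) mm\n",
              rotation_angle(x),
              paste(sprintf("%.3f", x$translation), collapse = ", ")))
  invisible(x)
}

#' Rigid transform from Euler angles about a centre
#'
#' Rotations are applied about `center` in the order z, y, x (intrinsic
#' `R = Rx %*% Ry %*% Rz`), then translated:
#' `y = R %*% (x - center) + center + translation`.
#'
#' @param angles_deg length-3 Euler angles (x, y, z) in degrees.
#' @param translation length-3 vector, mm.
#' @param center rotation centre, world mm.
#' @return A [rigid_transform()].
#' @export
euler_transform <- function(angles_deg = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  center <- as.numeric(center)
  t_eff <- drop(center - R %*% center) + as.numeric(translation)
  rigid_transform(R, t_eff)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param xyz world point or n x 3 matrix of points (mm).
#' @return Transformed points, same shape as input.
#' @export
transform_points <- function(transform, xyz) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  y <- m %*% t(transform$rotation)
  y <- sweep(y, 2, transform$translation, "+")
  if (is.matrix(xyz)) y else drop(y)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, drop(-Rt %*% transform$translation))
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `b` first, then `a`:
#' `(a o b)(x) = a(b(x))`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Rotation angle of a rigid transform
#'
#' The single rotation angle of the axis-angle decomposition, in degrees.
#'
#' @param transform a [rigid_transform()].
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Discrepancy between two rigid transforms
#'
#' Reports the rotation angle of `a %*% inverse(b)` and the displacement
#' their mappings differ by at a reference point (default the origin).
#'
#' @param a,b [rigid_transform()] objects.
#' @param at world point at which the translation error is measured.
#' @return Named vector `c(rotation_deg, translation_mm)`.
#' @export
transform_error <- function(a, b, at = c(0, 0, 0)) {
  d <- compose_transforms(a, invert_transform(b))
  c(rotation_deg = rotation_angle(d),
    translation_mm = sqrt(sum((transform_points(a, at) -
                                 transform_points(b, at))^2)))
}

#' Serialize a rigid transform to JSON
#'
#' Stored as the row-major rotation matrix plus the translation in mm.
#'
#' @param transform a [rigid_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  jsonlite::write_json(
    list(rotation = as.vector(t(transform$rotation)),
         translation = transform$translation,
         convention = "y = R x + t, fixed world -> moving world, mm"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path path written by [write_transform()].
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
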