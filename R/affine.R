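#' 3D affine transform
#'
#' World-space affine map `y = L (x - c) + c + t` with linear part `L`
#' (3x3, unitless), translation `t` (mm) and rotation centre `c` (mm).
#' Transforms are used as the forward geometric map from the moving
#' (subject) space to the fixed (reference or atlas) space; resampling pulls
#' intensities through the inverse.
#'
#' @param linear 3x3 matrix with positive determinant.
#' @param translation numeric length-3, mm.
#' @param center numeric length-3, mm; the point the linear part pivots about.
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(linear = diag(3), translation = c(0, 0, 0),
                     center = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(translation) == 3, length(center) == 3,
            all(is.finite(linear)), all(is.finite(translation)),
            all(is.finite(center)))
  if (det(linear) <= 0)
    stop_param("affine3d requires det(linear) > 0, got ", det(linear))
  structure(list(linear = linear, translation = translation, center = center),
            class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d>  det =", format(det(x$linear), digits = 6), "\n")
  cat("linear:\n")
  print(round(x$linear, 6))
  cat("translation (mm):", round(x$translation, 6), "\n")
  cat("center (mm):     ", round(x$center, 6), "\n")
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param transform an [affine3d()].
#' @param points N x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @return N x 3 matrix of mapped coordinates.
#' @export
apply_affine <- function(transform, points) {
  stopifnot(inherits(transform, "affine3d"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  pts <- sweep(as.matrix(points), 2, transform$center)
  out <- pts %*% t(transform$linear)
  sweep(out, 2, transform$center + transform$translation, `+`)
}

#' Invert an affine transform
#'
#' @param transform an [affine3d()].
#' @return The inverse map as an [affine3d()] (same centre).
#' @export
invert_affine <- function(transform) {
  stopifnot(inherits(transform, "affine3d"))
  Li <- solve(transform$linear)
  affine3d(Li, -as.vector(Li %*% transform$translation), transform$center)
}

#' Compose two affine transforms
#'
#' `compose_transforms(A, B)` returns the map `x -> A(B(x))`. Typical use is
#' chaining the subject-to-reference registration with the pre-computed
#' reference-to-atlas alignment to carry atlas labels into subject space.
#'
#' @param ref_to_atlas,subject_to_ref [affine3d()] transforms (applied second
#'   and first, respectively).
#' @return The composed [affine3d()] (centre at the origin).
#' @export
compose_transforms <- function(ref_to_atlas, subject_to_ref) {
  A <- ref_to_atlas; B <- subject_to_ref
  stopifnot(inherits(A, "affine3d"), inherits(B, "affine3d"))
  M <- A$linear %*% B$linear
  # A(B(x)) = LA LB x + LA(-LB cB + cB + tB - cA) + cA + tA
  t_tot <- as.vector(A$linear %*% (-B$linear %*% B$center + B$center +
                                     B$translation - A$center)) +
    A$center + A$translation
  affine3d(M, t_tot, c(0, 0, 0))
}

#' Build an affine transform from 12 registration parameters
#'
#' Parameter order: 3 rotations (rad, applied as Rz Ry Rx), 3 log-scales,
#' 3 shears (xy, xz, yz) and 3 translations (mm). This is the search space of
#' [register_affine()].
#'
#' @param p numeric length-12 parameter vector.
#' @param center rotation centre, mm.
#' @return An [affine3d()].
#' @export
affine_from_params <- function(p, center = c(0, 0, 0)) {
  stopifnot(length(p) == 12)
  r <- p[1:3]; s <- exp(p[4:6]); sh <- p[7:9]; t <- p[10:12]
  Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3, 3)
  Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3, 3)
  Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3, 3)
  Sh <- diag(3); Sh[1, 2] <- sh[1]; Sh[1, 3] <- sh[2]; Sh[2, 3] <- sh[3]
  affine3d(Rz %*% Ry %*% Rx %*% Sh %*% diag(s), t, center)
}

#' Rotation angle of an affine transform
#'
#' Angle (degrees) of the rotation component from the polar decomposition of
#' the linear part; 0 for a pure scaling/translation.
#'
#' @param transform an [affine3d()].
#' @return Rotation magnitude in degrees.
#' @export
rotation_angle <- function(transform) {
  sv <- svd(transform$linear)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) { # reflection guard; det(linear) > 0 makes this unreachable
    u <- sv$u; u[, 3] <- -u[, 3]; R <- u %*% t(sv$v)
  }
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Write / read an affine transform as JSON
#'
#' Serialized fields: row-major 3x3 `linear`, `translation_mm`, `center_mm`.
#'
#' @param transform an [affine3d()].
#' @param path file path.
#' @return `read_affine` returns the [affine3d()]; `write_affine` returns
#'   `path` invisibly.
#' @export
write_affine <- function(transform, path) {
  stopifnot(inherits(transform, "affine3d"))
  obj <- list(linear = as.vector(t(transform$linear)),
              translation_mm = transform$translation,
              center_mm = transform$center)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$linear) || length(obj$linear) != 9)
    stop("malformed transform JSON at ", path, ": field 'linear' must have 9 entries")
  affine3d(matrix(obj$linear, 3, 3, byrow = TRUE), obj$translation_mm,
           obj$center_mm)
}
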