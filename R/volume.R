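#' 3D Power Doppler volume
#'
#' Non-negative intensity grid with voxel spacing (mm) and a Bregma-referenced
#' world origin. Global coordinate convention: x = lateral (left to right),
#' y = antero-posterior index axis (first slice most anterior), z = depth,
#' positive downward. Voxel indices are 0-based; the world coordinate of voxel
#' `i` is `origin + i * spacing` (voxel centres).
#'
#' @param intensity 3D numeric array, `intensity >= 0`.
#' @param spacing voxel spacing, mm triple, `> 0`.
#' @param origin_mm world coordinate of voxel (0,0,0), mm triple.
#' @param axes free-text orientation tag.
#' @return An object of class `doppler_volume`.
#' @export
doppler_volume <- function(intensity, spacing, origin_mm = c(0, 0, 0),
                           axes = "x=lateral,y=antero-posterior,z=depth") {
  intensity <- as.array(intensity)
  if (length(dim(intensity)) == 2) dim(intensity) <- c(dim(intensity), 1L)
  stopifnot(length(dim(intensity)) == 3)
  check_positive(spacing, "spacing")
  stopifnot(length(spacing) == 3, length(origin_mm) == 3)
  if (any(intensity < 0, na.rm = TRUE))
    stop_param("doppler_volume intensity must be non-negative")
  structure(list(intensity = intensity, spacing = as.numeric(spacing),
                 origin_mm = as.numeric(origin_mm), axes = axes),
            class = "doppler_volume")
}

#' @export
print.doppler_volume <- function(x, ...) {
  cat("<doppler_volume> ", paste(dim(x$intensity), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"), " mm, origin ",
      paste(round(x$origin_mm, 3), collapse = "/"), " mm\n", sep = "")
  cat("intensity range [", format(min(x$intensity), digits = 4), ", ",
      format(max(x$intensity), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Target grid specification
#'
#' @param dim integer triple of voxel counts.
#' @param spacing mm triple.
#' @param origin_mm mm triple (world position of voxel 0,0,0).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(dim, spacing, origin_mm = c(0, 0, 0)) {
  check_positive(spacing, "spacing")
  stopifnot(length(dim) == 3, all(dim >= 1))
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 origin_mm = as.numeric(origin_mm)), class = "grid_spec")
}

grid_of <- function(vol) grid_spec(dim(vol$intensity), vol$spacing, vol$origin_mm)

# All voxel centres of a grid as an N x 3 world-coordinate matrix (x fastest).
grid_points <- function(grid) {
  d <- grid$dim
  ix <- seq_len(d[1]) - 1; iy <- seq_len(d[2]) - 1; iz <- seq_len(d[3]) - 1
  cbind(rep(ix, times = d[2] * d[3]) * grid$spacing[1] + grid$origin_mm[1],
        rep(rep(iy, each = d[1]), times = d[3]) * grid$spacing[2] + grid$origin_mm[2],
        rep(iz, each = d[1] * d[2]) * grid$spacing[3] + grid$origin_mm[3])
}

world_to_index <- function(vol, pts) {
  sweep(sweep(as.matrix(pts), 2, vol$origin_mm), 2, vol$spacing, `/`)
}

#' Pre-condition a Doppler volume for registration
#'
#' Log-compresses intensities (`log1p`), clips to the given percentiles and
#' rescales to \[0, 1\]. Histogram-based similarity metrics work best on this
#' compressed dynamic range.
#'
#' @param vol a [doppler_volume()].
#' @param clip_percentiles length-2, `0 <= low < high <= 100`.
#' @return The normalized [doppler_volume()] (values in \[0, 1\]).
#' @export
normalize_for_registration <- function(vol, clip_percentiles = c(1, 99)) {
  stopifnot(inherits(vol, "doppler_volume"), length(clip_percentiles) == 2)
  lo <- clip_percentiles[1]; hi <- clip_percentiles[2]
  if (!(lo >= 0 && lo < hi && hi <= 100))
    stop_param("clip_percentiles must satisfy 0 <= low < high <= 100")
  x <- log1p(vol$intensity)
  q <- quantile(x, c(lo, hi) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant volume: normalization returns all zeros")
    x[] <- 0
  } else {
    x <- pmin(pmax(x, q[1]), q[2])
    x <- (x - q[1]) / (q[2] - q[1])
  }
  doppler_volume(x, vol$spacing, vol$origin_mm, vol$axes)
}

#' Resample a volume through an affine transform
#'
#' The output grid is sampled at its voxel centres mapped through the inverse
#' of `transform` (so `transform` is the forward map of the object from the
#' input volume's space into the target space). Out-of-support voxels are 0.
#'
#' @param vol a [doppler_volume()].
#' @param transform an [affine3d()] mapping `vol` space into target space.
#' @param target_grid a [grid_spec()]; default: the input grid.
#' @param interp `"trilinear"` or `"nearest"`.
#' @return A [doppler_volume()] on `target_grid`.
#' @export
resample_volume <- function(vol, transform, target_grid = grid_of(vol),
                            interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(vol, "doppler_volume"), inherits(transform, "affine3d"))
  if (abs(det(transform$linear)) < 1e-12)
    stop_param("singular transform cannot be inverted for resampling")
  inv <- invert_affine(transform)
  pts <- apply_affine(inv, grid_points(target_grid))
  idx <- world_to_index(vol, pts)
  vals <- cpp_sample3(as.vector(vol$intensity), dim(vol$intensity), idx,
                      if (interp == "nearest") 1L else 0L, 0)
  vals[vals < 0] <- 0 # numerical guard; trilinear of non-negative data
  doppler_volume(array(vals, target_grid$dim), target_grid$spacing,
                 target_grid$origin_mm, vol$axes)
}

#' Write / read a Doppler volume as NIfTI
#'
#' Spacing and origin are carried in the sform (code 2); intensities are
#' stored as float64 so round-trips are bit-exact.
#'
#' @param vol a [doppler_volume()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns the [doppler_volume()]; `write_volume`
#'   returns `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "doppler_volume"))
  img <- RNifti::asNifti(vol$intensity, datatype = "double")
  m <- diag(4)
  diag(m)[1:3] <- vol$spacing
  m[1:3, 4] <- vol$origin_mm
  RNifti::`sform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  m <- RNifti::xform(img, useQuaternionFirst = FALSE)
  spacing <- sqrt(colSums(m[1:3, 1:3]^2))
  doppler_volume(strip_nifti(img), spacing, m[1:3, 4])
}

strip_nifti <- function(img) {
  arr <- as.array(img)
  array(as.vector(arr), dim(arr))
}
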