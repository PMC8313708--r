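# Ultrafast Doppler processing: SVD clutter filtering of compounded frame
# ensembles, Power Doppler computation, acquisition-rate arithmetic and
# slice-to-volume assembly.

#' Compounded frame stack
#'
#' Beamformed, angle-compounded frame ensemble (`nx` x `nz` x `nt`) with its
#' acquisition parameters. When both `prf` and `angles` are given, the
#' compounded frame rate must equal `prf / length(angles)`.
#'
#' @param data numeric array nx x nz x nt (real amplitudes).
#' @param compound_rate compounded frame rate, Hz.
#' @param prf pulse repetition frequency, Hz (optional).
#' @param angles plane-wave tilt angles, degrees (optional).
#' @param pixel_size_mm pixel size (x, z), mm.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, compound_rate = NULL, prf = NULL, angles = NULL,
                        pixel_size_mm = c(0.1, 0.1)) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] < 2) stop_param("frame_stack requires nt >= 2")
  if (!is.null(prf) && !is.null(angles) && !is.null(compound_rate)) {
    expected <- prf / length(angles)
    if (abs(compound_rate - expected) > 1e-6 * expected)
      stop_param("compound_rate (", compound_rate, ") != prf/n_angles (",
                 expected, ")")
  }
  structure(list(data = data, compound_rate = compound_rate, prf = prf,
                 angles = angles, pixel_size_mm = as.numeric(pixel_size_mm)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<frame_stack> ", d[1], " x ", d[2], " px, ", d[3], " frames",
      if (!is.null(x$compound_rate))
        paste0(" @ ", x$compound_rate, " Hz (",
               round(1000 * d[3] / x$compound_rate), " ms)"), "\n", sep = "")
  invisible(x)
}

#' SVD clutter filter
#'
#' Casorati reshape (rows = flattened space, x fastest; columns = time),
#' singular value decomposition with singular values sorted descending, and
#' reconstruction from the components of index `> cutoff_rank`. The removed
#' low-order components carry slow, spatially coherent tissue motion; the
#' remainder is the blood signal.
#'
#' @param stack a [frame_stack()].
#' @param cutoff_rank number of leading singular components to remove
#'   (`0 <= cutoff_rank < nt`); 0 returns the input unchanged.
#' @return The filtered [frame_stack()].
#' @export
svd_clutter_filter <- function(stack, cutoff_rank) {
  stopifnot(inherits(stack, "frame_stack"))
  nt <- dim(stack$data)[3]
  if (cutoff_rank < 0 || cutoff_rank >= nt)
    stop_param("cutoff_rank must satisfy 0 <= cutoff_rank < nt = ", nt)
  if (cutoff_rank == 0) return(stack)
  d <- dim(stack$data)
  X <- matrix(stack$data, d[1] * d[2], nt)
  sv <- svd(X, nu = cutoff_rank, nv = cutoff_rank)
  Xf <- X - sv$u %*% (sv$d[seq_len(cutoff_rank)] * t(sv$v))
  out <- stack
  out$data <- array(Xf, d)
  out
}

#' Default clutter cutoff rank
#'
#' The source does not fix the number of removed components; 30% of the
#' ensemble length is a typical choice for rodent transcranial fUS (60 of a
#' 200-frame block).
#'
#' @param nt ensemble length in frames.
#' @param fraction fraction of components treated as clutter.
#' @return Integer cutoff rank.
#' @export
default_cutoff_rank <- function(nt, fraction = 0.3) {
  max(1L, min(nt - 1L, as.integer(round(fraction * nt))))
}

#' Power Doppler image
#'
#' Per-pixel mean squared magnitude over time of a (clutter-filtered) frame
#' stack; proportional to cerebral blood volume.
#'
#' @param stack a [frame_stack()].
#' @return nx x nz numeric matrix.
#' @export
power_doppler <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$data)
  if (d[3] == 0) stop_param("empty stack")
  matrix(rowMeans(matrix(abs(stack$data)^2, d[1] * d[2], d[3])), d[1], d[2])
}

#' Compounded frame rate from PRF and angle count
#'
#' One compounded frame sums `n_angles` tilted plane-wave transmissions, so
#' the frame rate is `prf / n_angles` (5500 Hz over 11 angles gives 500 Hz).
#'
#' @param prf pulse repetition frequency, Hz.
#' @param n_angles number of plane-wave angles (`>= 1`).
#' @return Compound frame rate, Hz.
#' @export
compound_frame_rate <- function(prf, n_angles) {
  check_positive(prf, "prf")
  if (n_angles < 1) stop_param("n_angles must be >= 1")
  prf / n_angles
}

#' Doppler frame rate from block size
#'
#' One Power Doppler image is produced per block of `block_frames` compounded
#' frames, so the Doppler rate is `compound_rate / block_frames` (200-frame
#' blocks at 500 Hz give 2.5 Hz and 400 ms blocks).
#'
#' @param block_frames compounded frames per Doppler block (`>= 1`).
#' @param compound_rate compounded frame rate, Hz.
#' @return list(doppler_rate_hz, block_duration_s).
#' @export
doppler_frame_rate <- function(block_frames, compound_rate) {
  if (block_frames < 1) stop_param("block_frames must be >= 1")
  check_positive(compound_rate, "compound_rate")
  list(doppler_rate_hz = compound_rate / block_frames,
       block_duration_s = block_frames / compound_rate)
}

#' Assemble 2D Power Doppler slices into a 3D volume
#'
#' Slices are stacked along the antero-posterior axis at `step` mm; the first
#' slice is the most anterior (slice index increases posteriorly, matching
#' decreasing Bregma labels).
#'
#' @param slices list of equal-shape nx x nz matrices, ordered
#'   anterior-to-posterior.
#' @param step elevation step between slices, mm (`> 0`).
#' @param in_plane_spacing (x, z) pixel size, mm.
#' @param origin_mm world coordinate of the first slice's (0,0) pixel.
#' @return A [doppler_volume()] (x, slice, z axes -> x, y, z).
#' @export
assemble_volume <- function(slices, step, in_plane_spacing = c(0.1, 0.1),
                            origin_mm = c(0, 0, 0)) {
  check_positive(step, "step")
  stopifnot(is.list(slices), length(slices) >= 1)
  d1 <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), d1), TRUE)))
    stop_param("all slices must have the same shape")
  vol <- array(0, c(d1[1], length(slices), d1[2]))
  for (i in seq_along(slices)) vol[, i, ] <- slices[[i]]
  doppler_volume(vol, c(in_plane_spacing[1], step, in_plane_spacing[2]),
                 origin_mm)
}

#' Write / read a frame stack (NIfTI + JSON sidecar)
#'
#' The frame array is stored as a 3D NIfTI (`nx` x `nz` x `nt`); acquisition
#' attributes (`frame_rate_hz`, `prf_hz`, `angles_deg`, `pixel_size_mm`) go
#' to a `.json` sidecar next to it.
#'
#' @param stack a [frame_stack()].
#' @param path NIfTI path (`.nii` / `.nii.gz`).
#' @return `read_frame_stack` returns the [frame_stack()];
#'   `write_frame_stack` returns `path` invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  img <- RNifti::asNifti(stack$data, datatype = "double")
  RNifti::writeNifti(img, path)
  meta <- list(frame_rate_hz = stack$compound_rate, prf_hz = stack$prf,
               angles_deg = stack$angles, pixel_size_mm = stack$pixel_size_mm)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       sidecar_path(path), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  data <- strip_nifti(RNifti::readNifti(path))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  frame_stack(data, compound_rate = meta$frame_rate_hz, prf = meta$prf_hz,
              angles = meta$angles_deg, pixel_size_mm = meta$pixel_size_mm)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
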