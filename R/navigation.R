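# Atlas label propagation through composed transforms, ROI extraction,
# virtual imaging-plane definition from two user markers and stage pose
# solving (the "GPS" layer on top of the registration).

#' Atlas label volume with ontology
#'
#' @param labels 3D integer array (0 = outside).
#' @param spacing,origin_mm as in [doppler_volume()].
#' @param ontology data frame with columns id, acronym, name, parent_id,
#'   group; every non-zero label must appear in it and parent links must be
#'   acyclic.
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, spacing, origin_mm = c(0, 0, 0), ontology) {
  labels <- as.array(labels)
  stopifnot(length(dim(labels)) == 3)
  check_positive(spacing, "spacing")
  need <- c("id", "acronym", "name", "parent_id", "group")
  if (!all(need %in% names(ontology)))
    stop_param("ontology needs columns ", paste(need, collapse = ","))
  present <- setdiff(unique(as.vector(labels)), 0)
  if (!all(present %in% ontology$id))
    stop_param("labels ", paste(setdiff(present, ontology$id), collapse = ","),
               " missing from ontology")
  # parent links acyclic: walking up must terminate at 0
  idx <- match(ontology$parent_id, ontology$id)
  for (i in seq_len(nrow(ontology))) {
    seen <- integer(); j <- i
    while (!is.na(j)) {
      if (j %in% seen) stop_param("ontology parent links contain a cycle")
      seen <- c(seen, j); j <- idx[j]
    }
  }
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin_mm = as.numeric(origin_mm), ontology = ontology),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat("<atlas_volume> ", paste(dim(x$labels), collapse = " x "), " voxels, ",
      nrow(x$ontology), " regions (",
      paste(unique(x$ontology$group), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Propagate atlas labels into a subject grid
#'
#' Samples the atlas label volume with nearest-neighbour interpolation at the
#' subject voxel centres mapped through `subject_to_atlas`; voxels falling
#' outside the atlas get 0. Labels are never averaged, so the output label
#' set is always a subset of the atlas labels plus 0.
#'
#' @param atlas an [atlas_volume()].
#' @param subject_to_atlas [affine3d()] mapping subject world coordinates to
#'   atlas world coordinates.
#' @param subject_grid a [grid_spec()].
#' @return Integer label array with `subject_grid$dim` dimensions.
#' @export
propagate_labels <- function(atlas, subject_to_atlas, subject_grid) {
  stopifnot(inherits(atlas, "atlas_volume"), inherits(subject_grid, "grid_spec"))
  pts <- apply_affine(subject_to_atlas, grid_points(subject_grid))
  idx <- sweep(sweep(pts, 2, atlas$origin_mm), 2, atlas$spacing, `/`)
  vals <- cpp_sample3(as.vector(atlas$labels), dim(atlas$labels), idx, 1L, 0)
  array(as.integer(vals), subject_grid$dim)
}

#' Extract per-ROI mean time series
#'
#' @param series voxel x time matrix whose rows follow the flattened label
#'   grid (x fastest), or an array with the label grid's dimensions plus
#'   time last.
#' @param labels integer label grid.
#' @param ontology data frame with at least id and acronym; determines ROI
#'   order.
#' @param min_voxels ROIs with fewer voxels are dropped (with a message).
#' @return list(signals = ROI x time matrix with acronym rownames,
#'   roi = metadata data frame with voxel counts).
#' @export
extract_roi_signals <- function(series, labels, ontology, min_voxels = 1) {
  lab <- as.vector(labels)
  if (!is.matrix(series)) {
    d <- dim(series)
    series <- matrix(series, prod(d[-length(d)]), d[length(d)])
  }
  if (nrow(series) != length(lab))
    stop_param("series rows (", nrow(series), ") do not match label grid (",
               length(lab), " voxels)")
  ids <- ontology$id[ontology$id %in% lab]
  counts <- vapply(ids, function(i) sum(lab == i), 1L)
  keep <- counts >= min_voxels
  if (!any(keep)) stop_param("no ROI has >= ", min_voxels, " voxels")
  if (any(!keep))
    message("dropping ", sum(!keep), " ROI(s) below ", min_voxels, " voxels: ",
            paste(ontology$acronym[match(ids[!keep], ontology$id)], collapse = ", "))
  ids <- ids[keep]
  sig <- t(vapply(ids, function(i) colMeans(series[lab == i, , drop = FALSE]),
                  numeric(ncol(series))))
  rownames(sig) <- ontology$acronym[match(ids, ontology$id)]
  list(signals = sig,
       roi = data.frame(id = ids,
                        acronym = ontology$acronym[match(ids, ontology$id)],
                        group = ontology$group[match(ids, ontology$id)],
                        n_voxels = counts[keep]))
}

#' Virtual imaging plane from two markers
#'
#' The plane contains both markers and the vertical (depth) direction:
#' `u` is the normalized horizontal component of `m2 - m1` (probe lateral
#' axis), `v` is +z (probe axial axis), the plane point is the midpoint.
#' Markers that are (nearly) vertically stacked leave the plane azimuth
#' undetermined and raise an error.
#'
#' @param m1,m2 marker world coordinates, mm.
#' @param min_horizontal_mm minimum horizontal separation.
#' @return A `plane_spec`: point, in_plane_u, in_plane_v, normal.
#' @export
plane_from_markers <- function(m1, m2, min_horizontal_mm = 0.1) {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2)
  stopifnot(length(m1) == 3, length(m2) == 3)
  h <- c(m2[1] - m1[1], m2[2] - m1[2], 0)
  if (sqrt(sum(h^2)) < min_horizontal_mm)
    stop(errorCondition(
      "markers are vertically stacked: imaging plane under-determined",
      class = c("fusbps_plane_error", "error")))
  u <- h / sqrt(sum(h^2))
  v <- c(0, 0, 1)
  normal <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
  structure(list(point = (m1 + m2) / 2, in_plane_u = u, in_plane_v = v,
                 normal = normal), class = "plane_spec")
}

#' Forward kinematics of the 4-DOF stage
#'
#' The stage model has x/y/z translations plus a yaw about the vertical
#' axis; it reaches exactly the family of vertical planes (coronal, sagittal
#' and vertical obliques).
#'
#' @param pose list or `stage_pose` with x_mm, y_mm, z_mm, yaw_deg.
#' @return The `plane_spec` the stage realizes.
#' @export
forward_kinematics <- function(pose) {
  yaw <- pose$yaw_deg * pi / 180
  u <- c(cos(yaw), sin(yaw), 0)
  v <- c(0, 0, 1)
  structure(list(point = c(pose$x_mm, pose$y_mm, pose$z_mm), in_plane_u = u,
                 in_plane_v = v,
                 normal = c(u[2], -u[1], 0)), class = "plane_spec")
}

#' Stage pose
#'
#' @param x_mm,y_mm,z_mm stage translations, mm.
#' @param yaw_deg rotation about the vertical axis, degrees in (-180, 180].
#' @return A `stage_pose`.
#' @export
stage_pose <- function(x_mm, y_mm, z_mm, yaw_deg) {
  yaw_deg <- ((yaw_deg + 180) %% 360) - 180
  if (yaw_deg == -180) yaw_deg <- 180
  structure(list(x_mm = x_mm, y_mm = y_mm, z_mm = z_mm, yaw_deg = yaw_deg),
            class = "stage_pose")
}

#' Inverse kinematics: stage pose realizing a plane
#'
#' Supported family: vertical planes (normal perpendicular to the depth
#' axis). The pose translation is the plane point; yaw is the azimuth of the
#' in-plane lateral axis. Non-vertical planes raise an
#' unsupported-orientation error rather than being silently approximated.
#'
#' @param plane a `plane_spec`.
#' @param tol_deg tolerance on the vertical-plane check.
#' @return A [stage_pose()] with `forward_kinematics(pose)` reproducing the
#'   plane.
#' @export
solve_stage_pose <- function(plane, tol_deg = 1e-6) {
  stopifnot(inherits(plane, "plane_spec"))
  tilt <- asin(min(1, abs(plane$normal[3]) /
                     sqrt(sum(plane$normal^2)))) * 180 / pi
  if (tilt > tol_deg)
    stop(errorCondition(
      sprintf("unsupported plane orientation: normal tilted %.3f deg off horizontal", tilt),
      class = c("fusbps_orientation_error", "error")))
  yaw <- atan2(plane$in_plane_u[2], plane$in_plane_u[1]) * 180 / pi
  stage_pose(plane$point[1], plane$point[2], plane$point[3], yaw)
}

#' Oblique slice through a volume
#'
#' Samples the volume on the plane's (u, v) grid with trilinear
#' interpolation (use `interp = "nearest"` for label volumes). The grid is
#' centred on the plane point.
#'
#' @param vol a [doppler_volume()] (or [atlas_volume()] with
#'   `interp = "nearest"`).
#' @param plane a `plane_spec`.
#' @param out_spacing (u, v) sample spacing, mm.
#' @param extent_mm (u, v) physical extent, mm.
#' @param interp `"trilinear"` or `"nearest"`.
#' @return list(image, u_mm, v_mm, points) where `points` holds the world
#'   coordinate of every sample.
#' @export
slice_volume <- function(vol, plane, out_spacing = c(0.1, 0.1),
                         extent_mm = c(12.8, 8), interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(inherits(plane, "plane_spec"))
  arr <- if (inherits(vol, "atlas_volume")) vol$labels else vol$intensity
  us <- seq(-extent_mm[1] / 2, extent_mm[1] / 2, by = out_spacing[1])
  vs <- seq(-extent_mm[2] / 2, extent_mm[2] / 2, by = out_spacing[2])
  nu <- length(us); nv <- length(vs)
  pts <- matrix(plane$point, nu * nv, 3, byrow = TRUE) +
    outer(rep(us, times = nv), plane$in_plane_u) +
    outer(rep(vs, each = nu), plane$in_plane_v)
  idx <- sweep(sweep(pts, 2, vol$origin_mm), 2, vol$spacing, `/`)
  vals <- cpp_sample3(as.vector(arr), dim(arr), idx,
                      if (interp == "nearest") 1L else 0L, 0)
  if (all(vals == 0))
    stop_param("plane does not intersect the volume support")
  list(image = matrix(vals, nu, nv), u_mm = us, v_mm = vs, points = pts)
}

#' Write / read an atlas (NIfTI labels + ontology CSV)
#'
#' @param atlas an [atlas_volume()].
#' @param path label volume path (`.nii` / `.nii.gz`); the ontology CSV goes
#'   next to it with suffix `_ontology.csv`.
#' @return `read_atlas` returns the [atlas_volume()].
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_volume"))
  vol <- doppler_volume(atlas$labels, atlas$spacing, atlas$origin_mm)
  write_volume(vol, path)
  write.csv(atlas$ontology, ontology_path(path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  vol <- read_volume(path)
  ont <- read.csv(ontology_path(path))
  atlas_volume(array(as.integer(round(vol$intensity)), dim(vol$intensity)),
               vol$spacing, vol$origin_mm, ont)
}

ontology_path <- function(path)
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_ontology.csv")
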