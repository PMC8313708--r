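# Transform composition, label propagation, ROI extraction, plane
# targeting and the stage kinematics.

random_affine <- function(seed) {
  set.seed(seed)
  repeat {
    L <- diag(3) + matrix(rnorm(9, 0, 0.15), 3, 3)
    if (det(L) > 0.1) break
  }
  affine3d(L, rnorm(3), rnorm(3))
}

test_that("transform composition equals sequential application", {
  T1 <- random_affine(1)
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_affine(compose_transforms(T1, affine3d()), pts),
               apply_affine(T1, pts), tolerance = 1e-12)
  roundtrip <- compose_transforms(invert_affine(T1), T1)
  expect_lt(max(abs(apply_affine(roundtrip, pts) - pts)), 1e-10)
  T2 <- random_affine(2)
  expect_equal(apply_affine(compose_transforms(T1, T2), pts),
               apply_affine(T1, apply_affine(T2, pts)), tolerance = 1e-12)
})

test_that("label propagation is exact for identity and integer shifts and never invents labels", {
  at <- synthetic_atlas(dim = c(20, 16, 12), spacing = c(0.1, 0.1, 0.2),
                        n_regions = 6, seed = 1)
  grid <- grid_spec(dim(at$labels), at$spacing, at$origin_mm)
  same <- propagate_labels(at, affine3d(), grid)
  expect_identical(same, at$labels + 0L)
  # subject shifted by +2 voxels in x relative to the atlas
  T2 <- affine3d(diag(3), c(2 * at$spacing[1], 0, 0))
  shifted <- propagate_labels(at, T2, grid)
  expect_identical(shifted[1:18, , ], at$labels[3:20, , ])
  expect_true(all(shifted[19:20, , ] == 0L))
  for (seed in 1:3) {
    Tr <- random_affine(seed + 10)
    out <- propagate_labels(at, Tr, grid)
    expect_true(all(out %in% c(0L, at$ontology$id)))
  }
})

test_that("ROI extraction returns per-region means in ontology order", {
  lab <- array(0L, c(5, 4, 1))
  lab[1:2, 1, 1] <- 1L; lab[3, 1, 1] <- 2L
  ont <- data.frame(id = 1:2, acronym = c("A", "B"), name = c("a", "b"),
                    parent_id = 0L, group = "isocortex")
  nt <- 6
  series <- matrix(0, 20, nt)
  series[1, ] <- 1; series[2, ] <- 3 # ROI 1: two constant voxels
  series[3, ] <- 7                   # ROI 2
  ext <- extract_roi_signals(series, lab, ont)
  expect_equal(rownames(ext$signals), c("A", "B"))
  expect_equal(unname(ext$signals["A", ]), rep(2, nt)) # mean of 1 and 3
  # uniform ROI reproduces its voxel signal
  v <- sin(seq_len(nt))
  series[1, ] <- v; series[2, ] <- v
  ext2 <- extract_roi_signals(series, lab, ont)
  expect_equal(unname(ext2$signals["A", ]), v)
  # 70-region map: one row per region, ontology order
  lab70 <- array(rep(1:70, each = 4), c(280, 1, 1))
  ont70 <- data.frame(id = 1:70, acronym = sprintf("R%02d", 1:70),
                      name = "r", parent_id = 0L, group = "isocortex")
  s70 <- matrix(rnorm(280 * 5), 280, 5)
  ext70 <- extract_roi_signals(s70, lab70, ont70)
  expect_equal(nrow(ext70$signals), 70)
  expect_equal(ext70$roi$id, 1:70)
  expect_error(extract_roi_signals(s70, lab70, ont70, min_voxels = 10),
               class = "fusbps_parameter_error")
})

test_that("planes from markers contain both markers and the vertical axis", {
  p1 <- plane_from_markers(c(-1, -2, 0), c(1, -2, 0)) # differ in x: coronal
  expect_equal(p1$in_plane_u, c(1, 0, 0))
  expect_equal(solve_stage_pose(p1)$yaw_deg, 0)
  p2 <- plane_from_markers(c(0.5, -3, 1), c(0.5, -1, 1)) # differ in y: sagittal
  expect_equal(solve_stage_pose(p2)$yaw_deg, 90)
  m1 <- c(-2, -1, 2); m2 <- c(2, -3, 4)
  p3 <- plane_from_markers(m1, m2)
  for (m in list(m1, m2))
    expect_lt(abs(sum(p3$normal * (m - p3$point))), 1e-10)
  expect_error(plane_from_markers(c(0, 0, 0), c(0.01, 0, 5)),
               class = "fusbps_plane_error")
})

test_that("pose solving inverts the forward kinematics on the vertical-plane family", {
  p <- plane_from_markers(c(-1, -2, 0), c(1, -2, 0))
  pose <- solve_stage_pose(p)
  expect_equal(unlist(pose[c("x_mm", "y_mm", "z_mm", "yaw_deg")]),
               c(x_mm = 0, y_mm = -2, z_mm = 0, yaw_deg = 0))
  set.seed(8)
  for (i in 1:100) {
    truth <- stage_pose(runif(1, -5, 5), runif(1, -5, 5), runif(1, 0, 6),
                        runif(1, -179, 180))
    solved <- solve_stage_pose(forward_kinematics(truth))
    expect_equal(unlist(solved), unlist(truth), tolerance = 1e-6)
  }
  tilted <- structure(list(point = c(0, 0, 0),
                           in_plane_u = c(cos(0.1), 0, sin(0.1)),
                           in_plane_v = c(0, 0, 1),
                           normal = c(-sin(10 * pi / 180) * 0 + 0.17, -0.98, 0.17)),
                      class = "plane_spec")
  expect_error(solve_stage_pose(tilted), class = "fusbps_orientation_error")
})

test_that("oblique slicing agrees with direct sampling", {
  vol <- blob_volume(dim = c(20, 16, 12), seed = 9)
  d <- dim(vol$intensity)
  # coronal plane exactly on a stored section
  j <- 6
  plane <- plane_from_markers(c(0, (j - 1) * vol$spacing[2], 0.2),
                              c(1, (j - 1) * vol$spacing[2], 0.2))
  plane$point <- c((d[1] - 1) / 2 * vol$spacing[1], (j - 1) * vol$spacing[2],
                   (d[3] - 1) / 2 * vol$spacing[3])
  sl <- slice_volume(vol, plane, out_spacing = c(vol$spacing[1], vol$spacing[3]),
                     extent_mm = c((d[1] - 1) * vol$spacing[1],
                                   (d[3] - 1) * vol$spacing[3]))
  expect_equal(sl$image, vol$intensity[, j, ], tolerance = 1e-12)
  # 45 degree oblique slice of a constant volume is constant (inside support)
  cv <- doppler_volume(array(2, c(20, 20, 10)), c(0.1, 0.1, 0.1))
  pl45 <- plane_from_markers(c(0.5, 0.5, 0), c(1.2, 1.2, 0))
  pl45$point <- c(0.95, 0.95, 0.45)
  sl45 <- slice_volume(cv, pl45, out_spacing = c(0.05, 0.05),
                       extent_mm = c(0.8, 0.6))
  expect_true(all(sl45$image == 2))
  # point-sampling oracle on an oblique plane through a smooth volume
  pl <- plane_from_markers(c(0.3, 0.2, 0), c(1.4, 1.1, 0))
  pl$point <- c(0.8, 0.7, 0.5)
  slo <- slice_volume(vol, pl, out_spacing = c(0.07, 0.07),
                      extent_mm = c(0.7, 0.6))
  for (k in c(5L, 23L, 47L)) {
    pt <- slo$points[k, ]
    idx <- (pt - vol$origin_mm) / vol$spacing
    expect_equal(slo$image[k], trilinear_oracle(vol$intensity, idx[1], idx[2],
                                                idx[3]), tolerance = 1e-10)
  }
  expect_error(slice_volume(vol, plane_from_markers(c(100, 0, 0), c(101, 0, 0)),
                            extent_mm = c(0.5, 0.5)),
               class = "fusbps_parameter_error")
})

test_that("atlases round-trip through NIfTI + ontology CSV and reject bad ontologies", {
  at <- synthetic_atlas(dim = c(12, 10, 8), n_regions = 5, seed = 3)
  p <- file.path(tempdir(), "atlas.nii.gz")
  write_atlas(at, p)
  back <- read_atlas(p)
  expect_identical(back$labels, at$labels)
  expect_equal(back$ontology$acronym, at$ontology$acronym)
  bad <- at$ontology; bad$parent_id <- c(2, 1, 0, 0, 0)[seq_len(nrow(bad))]
  expect_error(atlas_volume(at$labels, at$spacing, c(0, 0, 0), bad),
               class = "fusbps_parameter_error")
  expect_error(atlas_volume(at$labels + 100L, at$spacing, c(0, 0, 0),
                            at$ontology),
               class = "fusbps_parameter_error")
})
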