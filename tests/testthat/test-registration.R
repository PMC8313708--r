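# Mattes MI, the evolutionary optimizer, resampling, cross-correlation
# metrics and landmark discrepancies.

test_that("MI of constant volumes is zero and bin-centred MI matches the hard histogram", {
  const <- doppler_volume(array(0.5, c(6, 6, 4)), c(0.1, 0.1, 0.1))
  expect_equal(mattes_mi(const, const), 0)
  # integer-levelled toy volumes: the Parzen metric must reduce to the
  # brute-force joint-histogram MI
  a <- bin_centred_volume(c(4, 4, 1), seed = 11)
  b <- bin_centred_volume(c(4, 4, 1), seed = 12)
  expect_equal(mattes_mi(a, b),
               hard_mi_oracle(as.vector(a$intensity), as.vector(b$intensity), 50),
               tolerance = 1e-10)
})

test_that("MI of a 50-level uniform volume with itself is ln 50", {
  u <- array(rep(seq(0, 1, length.out = 50), length.out = 16 * 16 * 8),
             c(16, 16, 8))
  uv <- doppler_volume(u, c(0.1, 0.1, 0.1))
  expect_equal(mattes_mi(uv, uv), log(50), tolerance = 0.05)
})

test_that("the C++ Parzen accumulation agrees with a naive R implementation", {
  set.seed(21)
  for (kernel in c("linear", "cubic")) {
    a <- doppler_volume(array(runif(8 * 6 * 4), c(8, 6, 4)), c(0.1, 0.1, 0.1))
    b <- doppler_volume(array(runif(8 * 6 * 4), c(8, 6, 4)), c(0.1, 0.1, 0.1))
    got <- mattes_mi(a, b, config = mi_config(kernel = kernel),
                     return_joint = TRUE)
    want <- parzen_joint_oracle(as.vector(a$intensity), as.vector(b$intensity),
                                50, kernel)
    expect_equal(got$joint, want, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(got$mi, mi_of_joint(want), tolerance = 1e-10)
  }
})

test_that("MI is symmetric under swapping and bounded by the marginal entropies", {
  a <- bin_centred_volume(c(8, 8, 4), seed = 31)
  b <- bin_centred_volume(c(8, 8, 4), seed = 32)
  expect_equal(mattes_mi(a, b), mattes_mi(b, a), tolerance = 0.05)
  ent <- function(v) {
    p <- table(as.vector(v$intensity)) / length(v$intensity)
    -sum(p * log(p))
  }
  expect_lte(mattes_mi(a, b), min(ent(a), ent(b)) + 0.05)
})

test_that("vanishing overlap raises a degenerate-overlap error", {
  a <- blob_volume()
  far <- affine3d(diag(3), c(1000, 0, 0))
  expect_error(mattes_mi(a, a, far), class = "fusbps_overlap_error")
})

test_that("the (1+1)-ES solves a convex quadratic and is reproducible", {
  target <- c(1, 2, 3)
  obj <- function(x) sum((x - target)^2)
  par <- list(initial_radius = 0.5, growth_factor = 1.05, epsilon = 1e-9,
              max_iterations = 500)
  res <- one_plus_one_es(obj, c(0, 0, 0), par, seed = 1)
  expect_lt(sqrt(sum((res$par - target)^2)), 1e-3)
  res2 <- one_plus_one_es(obj, c(0, 0, 0), par, seed = 1)
  expect_identical(res$trace, res2$trace)
  none <- one_plus_one_es(obj, c(4, 4, 4),
                          list(initial_radius = 0.5, growth_factor = 1.05,
                               epsilon = 1e-9, max_iterations = 0), seed = 1)
  expect_equal(none$par, c(4, 4, 4))
  expect_error(one_plus_one_es(function(x) NaN, 0, par),
               class = "fusbps_parameter_error")
})

test_that("self-registration returns (numerically) the identity", {
  tree <- generate_vessel_tree(3, vessel_tree_params(extent_mm = c(5, 4, 4)))
  vol <- normalize_for_registration(
    rasterize_doppler_volume(tree, c(0.1, 0.1, 0.2), snr = 30, seed = 1))
  reg <- register_affine(vol, vol, mi_config(seed = 0))
  expect_lt(max(abs(reg$transform$translation)), 0.01)
  expect_lt(max(abs(reg$transform$linear - diag(3))), 1e-3)
  expect_gte(reg$mi, mattes_mi(vol, vol) - 1e-6)
})

test_that("a pure shift and a rotation+shift are recovered on phantom copies", {
  tree <- generate_vessel_tree(4, vessel_tree_params(extent_mm = c(6.3, 4.7, 6.2)))
  fixed <- normalize_for_registration(
    rasterize_doppler_volume(tree, c(0.1, 0.1, 0.2), snr = 20, seed = 2))
  center <- fixed$origin_mm + (dim(fixed$intensity) - 1) / 2 * fixed$spacing
  # pure translation
  T1 <- affine3d(diag(3), c(0.5, 0.3, 0.2))
  reg1 <- register_affine(resample_volume(fixed, T1), fixed, mi_config(seed = 1))
  err1 <- abs(reg1$transform$translation + c(0.5, 0.3, 0.2))
  expect_true(all(err1 <= 0.05)) # half an in-plane voxel per axis
  # 5 degree rotation about z plus shift
  a <- 5 * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  T2 <- affine3d(Rz, c(0.4, 0, 0), center)
  reg2 <- register_affine(resample_volume(fixed, T2), fixed, mi_config(seed = 2))
  comp <- compose_transforms(reg2$transform, T2)
  pts <- matrix(runif(60, 1, 4), 20, 3)
  expect_lt(mean(sqrt(rowSums((apply_affine(comp, pts) - pts)^2))), 0.1)
})

test_that("resampling matches closed-form interpolation", {
  vol <- blob_volume(seed = 5)
  # identity on the same grid is exact for both interpolators
  for (interp in c("trilinear", "nearest")) {
    out <- resample_volume(vol, affine3d(), interp = interp)
    expect_equal(out$intensity, vol$intensity, tolerance = 1e-14)
  }
  # integer-voxel translation with nearest is an index shift
  T2 <- affine3d(diag(3), c(2, 0, 0) * vol$spacing[1]) # +2 voxels in x
  out2 <- resample_volume(vol, T2, interp = "nearest")
  expect_equal(out2$intensity[3:12, , ], vol$intensity[1:10, , ])
  expect_true(all(out2$intensity[1:2, , ] == 0))
  # sub-voxel shift against the hand-rolled trilinear oracle
  T3 <- affine3d(diag(3), c(0.05, 0, 0))
  out3 <- resample_volume(vol, T3)
  d <- dim(vol$intensity)
  for (probe in list(c(3, 4, 2), c(7, 2, 5), c(11, 9, 7))) {
    want <- trilinear_oracle(vol$intensity, probe[1] - 1 - 0.5, probe[2] - 1,
                             probe[3] - 1)
    expect_equal(out3$intensity[probe[1], probe[2], probe[3]], want,
                 tolerance = 1e-10)
  }
  expect_error(resample_volume(vol, affine3d(diag(c(1, 1, 1e-20)) + 0)),
               class = "fusbps_parameter_error")
})

test_that("resample roundtrip preserves the interior up to interpolation blur", {
  vol <- blob_volume(dim = c(16, 14, 12), seed = 6)
  a <- 4 * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  T1 <- affine3d(Rz, c(0.13, -0.07, 0.05),
                 center = (dim(vol$intensity) - 1) / 2 * vol$spacing)
  back <- resample_volume(resample_volume(vol, T1), invert_affine(T1))
  inner <- vol$intensity[4:13, 4:11, 4:9]
  inner_back <- back$intensity[4:13, 4:11, 4:9]
  expect_gte(cor(as.vector(inner), as.vector(inner_back)), 0.99)
})

test_that("cross-correlation peaks at the applied shift with unit autocorrelation", {
  vol <- blob_volume(dim = c(20, 16, 12), seed = 7)
  auto <- normalized_xcorr3(vol, vol)
  m <- xcorr_metrics(auto)
  expect_equal(m$peak_value, 1, tolerance = 1e-10)
  expect_equal(m$peak_lag_mm, c(0, 0, 0))
  # b = a shifted +0.4 mm in x (4 voxels at 0.1 mm)
  shifted <- vol
  arr <- array(0, dim(vol$intensity))
  arr[5:20, , ] <- vol$intensity[1:16, , ]
  shifted$intensity <- arr
  m2 <- xcorr_metrics(normalized_xcorr3(vol, shifted))
  expect_equal(m2$peak_lag_mm, c(0.4, 0, 0))
  expect_gt(m2$peak_value, 0.8)
  # constant volume has no defined normalization
  expect_error(normalized_xcorr3(doppler_volume(array(1, c(4, 4, 4)), c(1, 1, 1)),
                                 vol),
               class = "fusbps_parameter_error")
})

test_that("uncorrelated volumes correlate weakly everywhere", {
  set.seed(41)
  a <- doppler_volume(array(runif(64^3), c(64, 64, 64)), c(0.1, 0.1, 0.1))
  b <- doppler_volume(array(runif(64^3), c(64, 64, 64)), c(0.1, 0.1, 0.1))
  xc <- normalized_xcorr3(a, b)
  expect_lt(max(abs(xc$corr)), 0.2)
})

test_that("FWHM of a Gaussian autocorrelation follows the closed form", {
  # the domain must dwarf the blob: the zero-mean normalization shifts the
  # correlation baseline by the blob/volume mass ratio
  sp <- c(0.05, 0.05, 0.05)
  ax <- lapply(1:3, function(i) ((0:95) - 47.5) * sp[i])
  s0 <- 0.3
  g <- exp(-(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)) /
             (2 * s0^2))
  vol <- doppler_volume(g, sp)
  m <- xcorr_metrics(normalized_xcorr3(vol, vol))
  want <- 2 * sqrt(2 * log(2)) * s0 * sqrt(2) # autocorr sigma = s0 * sqrt(2)
  expect_equal(m$fwhm_mm, rep(want, 3), tolerance = 0.03 * want)
  # a delta-like volume cannot be sharper than the lag sampling
  d <- array(0, c(9, 9, 9)); d[5, 5, 5] <- 1
  dv <- doppler_volume(d, c(0.1, 0.1, 0.1))
  md <- xcorr_metrics(normalized_xcorr3(dv, dv))
  expect_true(all(md$fwhm_mm <= 2 * 0.1 + 1e-9))
})

test_that("landmark discrepancies are Euclidean shifts in micrometres", {
  a <- landmark_set(rbind(VL1 = c(1, 2, 3)))
  expect_equal(landmark_discrepancy(a, a)$per_landmark_um,
               c(VL1 = 0))
  b <- landmark_set(rbind(VL1 = c(1, 2, 3) + c(0.03, 0.04, 0)))
  expect_equal(landmark_discrepancy(a, b)$mean_um, 50, tolerance = 1e-9)
  offs <- rbind(c(100, 0, 0), c(0, 100, 0), c(0, 0, 100), c(100, 100, 100)) / 1000
  a4 <- landmark_set(matrix(1, 4, 3,
                            dimnames = list(paste0("VL", 1:4), NULL)))
  b4 <- landmark_set(a4$entries + offs)
  expect_equal(landmark_discrepancy(a4, b4)$mean_um, (300 + 100 * sqrt(3)) / 4,
               tolerance = 1e-9)
  expect_error(landmark_discrepancy(a, landmark_set(rbind(ZZ = c(0, 0, 0)))),
               class = "fusbps_parameter_error")
  # CSV round-trip
  p <- file.path(tempdir(), "lm.csv")
  write_landmarks(b4, p)
  expect_equal(read_landmarks(p)$entries, b4$entries)
})
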