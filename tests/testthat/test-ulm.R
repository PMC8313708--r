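# ULM: detection, Hungarian linking, track refinement, map rendering,
# demons misalignment.

gauss_spot <- function(nx, nz, cx, cz, sigma = 1.5, amp = 1) {
  outer(exp(-((seq_len(nx) - 1) - cx)^2 / (2 * sigma^2)),
        exp(-((seq_len(nz) - 1) - cz)^2 / (2 * sigma^2))) * amp
}

test_that("bubble detection localizes isolated spots to sub-pixel accuracy", {
  expect_equal(nrow(detect_bubbles(matrix(0, 32, 32), 0.1)), 0)
  f <- gauss_spot(40, 32, 20.3, 15.7)
  det <- detect_bubbles(f, 0.1, psf_radius = 3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 20.3), 0.05)
  expect_lt(abs(det$z_px - 15.7), 0.05)
  # two spots 10 psf apart stay separate
  f2 <- gauss_spot(64, 32, 15, 16) + gauss_spot(64, 32, 45, 16)
  expect_equal(nrow(detect_bubbles(f2, 0.1, psf_radius = 3)), 2)
  # two spots closer than the merge radius collapse into the brighter
  f3 <- gauss_spot(64, 32, 30, 16, amp = 1) + gauss_spot(64, 32, 32, 16, amp = 0.4)
  expect_equal(nrow(detect_bubbles(f3, 0.1, psf_radius = 4)), 1)
})

test_that("Hungarian assignment matches exhaustive permutation search", {
  res <- solve_assignment(matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE))
  expect_equal(res$assignment, c(1, 2))
  expect_equal(res$total_cost, 2)
  set.seed(13)
  for (n in 2:6) {
    for (rep in 1:5) {
      cost <- matrix(runif(n * n), n, n)
      got <- solve_assignment(cost)
      want <- brute_force_assignment(cost)
      expect_equal(got$total_cost, want$min_cost, tolerance = 1e-12)
    }
  }
  # rectangular: every row must still get the optimal column
  cost <- matrix(runif(12), 3, 4)
  got <- solve_assignment(cost)
  best <- min(apply(perms(4)[, 1:3, drop = FALSE], 1, function(p)
    sum(cost[cbind(1:3, p)])))
  expect_equal(got$total_cost, best, tolerance = 1e-12)
})

test_that("gated linking keeps parallel tracks apart without identity swaps", {
  gate <- 0.2
  frames <- lapply(0:9, function(f) {
    data.frame(x_px = 0, z_px = 0,
               x_mm = c(0.05 + f * 0.5 * gate, 0.05 + f * 0.5 * gate),
               z_mm = c(0.1, 0.1 + 3 * gate), intensity = 1)
  })
  ts <- link_tracks(frames, max_link_dist = gate, min_track_length = 4,
                    frame_rate = 100)
  tl <- split(ts$tracks, ts$tracks$track_id)
  expect_length(tl, 2)
  for (tr in tl) {
    expect_equal(nrow(tr), 10)
    expect_equal(diff(range(tr$z_mm)), 0) # no swap across the two lanes
    expect_equal(tr$vx_mm_s, rep(0.5 * gate * 100, 10), tolerance = 1e-10)
  }
  # detections beyond the gate never link
  far <- lapply(0:5, function(f)
    data.frame(x_px = 0, z_px = 0, x_mm = f * 5 * gate, z_mm = 0, intensity = 1))
  ts2 <- link_tracks(far, max_link_dist = gate, min_track_length = 1,
                     frame_rate = 100)
  expect_equal(length(unique(ts2$tracks$track_id)), 6)
})

test_that("track refinement averages with shrinking edges and preserves lines", {
  tr <- data.frame(frame = 1:3, x_mm = c(0, 1, 5), z_mm = 0)
  out <- refine_track(tr, smooth_window = 3, upsample = 1)
  expect_equal(out$x_mm[2], 2) # mean(0, 1, 5)
  expect_equal(out$x_mm[c(1, 3)], c(0, 5)) # edge windows shrink to length 1
  same <- refine_track(tr, smooth_window = 1, upsample = 1)
  expect_equal(same$x_mm, tr$x_mm)
  line <- data.frame(frame = 1:9, x_mm = seq(0, 2, length.out = 9),
                     z_mm = seq(1, 2.6, length.out = 9))
  ref <- refine_track(line, smooth_window = 5, upsample = 4)
  # collinearity: residual from the straight line through the endpoints
  dir <- c(2 - 0, 2.6 - 1); dir <- dir / sqrt(sum(dir^2))
  rel <- cbind(ref$x_mm - 0, ref$z_mm - 1)
  resid <- rel[, 1] * dir[2] - rel[, 2] * dir[1]
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("ULM maps count interpolated points and carry the track speed", {
  fr <- 100
  tr <- data.frame(track_id = 1, frame = 1:20,
                   x_mm = seq(0, by = 10 / fr, length.out = 20), z_mm = 0.05)
  ts <- track_set(tr, frame_rate = fr)
  maps <- render_ulm_maps(ts, pixel_size_mm = 0.005, extent_mm = c(2.2, 0.2),
                          smooth_window = 1, upsample = 10)
  visited <- which(maps$density > 0)
  expect_equal(sum(maps$density), (20 - 1) * 10 + 1) # interpolated points
  expect_equal(unname(maps$velocity[visited]), rep(10, length(visited)),
               tolerance = 1e-6)
  # revisiting a pixel doubles its density
  tr2 <- data.frame(track_id = 1, frame = 1:2, x_mm = c(0.05, 0.05),
                    z_mm = c(0.05, 0.05))
  m2 <- render_ulm_maps(track_set(tr2, fr), pixel_size_mm = 0.005,
                        extent_mm = c(0.1, 0.1), smooth_window = 1,
                        upsample = 1)
  expect_equal(max(m2$density), 2)
  # permutation invariance in track order
  trs <- rbind(tr, transform(tr, track_id = 2, z_mm = 0.1))
  m_a <- render_ulm_maps(track_set(trs, fr), 0.005, c(2.2, 0.2))
  m_b <- render_ulm_maps(track_set(trs[order(-trs$track_id, trs$frame), ], fr),
                         0.005, c(2.2, 0.2))
  expect_equal(m_a$density, m_b$density)
})

test_that("demons recovers known shifts and flags hopeless inputs", {
  set.seed(17)
  base <- blur2d_for_test(matrix(runif(80 * 60), 80, 60), 3)
  f0 <- demons_displacement(base, base, n_iter = 20)
  expect_lt(mean(abs(f0)), 0.05)
  # build B(x) = A(x - 3) along rows: B[i, ] = A[i - 3, ]
  B <- base; B[4:80, ] <- base[1:77, ]; B[1:3, ] <- base[rep(1, 3), ]
  fld <- demons_displacement(base, B, n_iter = 60, reg_sigma = 2)
  interior <- fld[15:65, 10:50, 1]
  expect_equal(mean(interior), 3, tolerance = 0.3) # within 10%
  expect_warning(
    demons_displacement(gauss_spot(60, 60, 15, 30, 2),
                        gauss_spot(60, 60, 45, 30, 2), n_iter = 5,
                        pyramid = 1),
    "converge")
})

test_that("misalignment averaging converts pixels to micrometres over the mask", {
  f <- array(0, c(20, 20, 2))
  mask <- matrix(FALSE, 20, 20); mask[8:12, 8:12] <- TRUE
  expect_equal(mean_misalignment(f, mask, mask, 0.005)$mean_shift_um,
               c(lateral = 0, axial = 0))
  f[, , 1] <- 3
  expect_equal(mean_misalignment(f, mask, mask, 0.005)$mean_shift_um,
               c(lateral = 15, axial = 0))
  other <- matrix(FALSE, 20, 20); other[18:20, 18:20] <- TRUE
  expect_error(mean_misalignment(f, mask, other, 0.005, dilate_px = 0),
               class = "fusbps_parameter_error")
})

test_that("a constructed 40 um offset between ULM maps is recovered", {
  # two straight vessels rendered at 5 um pixels; second acquisition offset
  # by 8 px = 40 um laterally
  fr <- 1000
  mk_tracks <- function(x_off_mm) {
    do.call(rbind, lapply(1:6, function(k) {
      data.frame(track_id = k, frame = 1:30,
                 x_mm = 0.1 + x_off_mm + 0.004 * k +
                   seq(0, by = 12 / fr, length.out = 30) * 0,
                 z_mm = seq(0.05, by = 15 / fr, length.out = 30))
    }))
  }
  mA <- render_ulm_maps(track_set(mk_tracks(0), fr), 0.005, c(0.4, 0.6))
  mB <- render_ulm_maps(track_set(mk_tracks(0.040), fr), 0.005, c(0.4, 0.6))
  fld <- demons_displacement(mA$density, mB$density, n_iter = 60,
                             reg_sigma = 2, pre_blur_sigma = 2)
  mis <- mean_misalignment(fld, mA$density > 0, mB$density > 0, 0.005)
  expect_equal(unname(mis$mean_shift_um["lateral"]), 40, tolerance = 10 / 40)
  expect_lt(abs(mis$mean_shift_um["axial"]), 10)
})

test_that("noise-free movies are recovered end to end", {
  tree <- generate_vessel_tree(5, vessel_tree_params(extent_mm = c(6, 4, 5)))
  mv <- simulate_bubble_movie(tree, n_bubbles = 12, n_frames = 60,
                              frame_rate = 1000, psf_sigma = 1.2, seed = 6,
                              speed_range_mm_s = c(8, 25))
  det <- lapply(seq_len(dim(mv$stack$data)[3]), function(f)
    detect_bubbles(mv$stack$data[, , f], threshold = 0.3, psf_radius = 2,
                   pixel_size_mm = mv$stack$pixel_size_mm))
  est <- link_tracks(det, max_link_dist = 50 / 1000, min_track_length = 4,
                     frame_rate = 1000)
  gt <- split(mv$tracks$tracks, mv$tracks$tracks$track_id)
  est_l <- split(est$tracks, est$tracks$track_id)
  px <- mv$stack$pixel_size_mm[1]
  recovered <- 0; loc_err <- c()
  for (g in gt) {
    best_cov <- 0; best_err <- NA
    for (e in est_l) {
      m <- merge(g, e, by = "frame")
      if (!nrow(m)) next
      d <- sqrt((m$x_mm.x - m$x_mm.y)^2 + (m$z_mm.x - m$z_mm.y)^2) / px
      cov <- mean(d < 0.5) * nrow(m) / nrow(g)
      if (cov > best_cov) { best_cov <- cov; best_err <- mean(d) }
    }
    if (best_cov >= 0.8) { recovered <- recovered + 1; loc_err <- c(loc_err, best_err) }
  }
  expect_gte(recovered / length(gt), 0.95)
  expect_lte(mean(loc_err), 0.2)
})

test_that("tracks round-trip through CSV", {
  tr <- data.frame(track_id = c(1, 1, 2), frame = c(1, 2, 1),
                   x_mm = c(0.1, 0.2, 0.5), z_mm = c(1, 1.1, 2),
                   vx_mm_s = 1, vz_mm_s = 0)
  ts <- track_set(tr, 1000)
  p <- file.path(tempdir(), "tracks.csv")
  write_tracks(ts, p)
  back <- read_tracks(p, 1000)
  expect_equal(back$tracks$x_mm, tr$x_mm)
  expect_equal(back$tracks$track_id, tr$track_id)
  expect_error(track_set(data.frame(track_id = 1, frame = c(2, 1),
                                    x_mm = 0, z_mm = 0)),
               class = "fusbps_parameter_error")
})
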