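# Ultrasound Localization Microscopy: sub-pixel microbubble detection,
# Hungarian frame-to-frame linking, track refinement, super-resolved map
# rendering, and displacement-map misalignment quantification between
# repositioned acquisitions.

#' Bubble track set
#'
#' @param tracks data frame with columns track_id, frame, x_mm, z_mm
#'   (optional vx_mm_s, vz_mm_s); frames must be strictly increasing within
#'   a track.
#' @param frame_rate acquisition frame rate, Hz.
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, frame_rate = NULL) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "frame", "x_mm", "z_mm") %in% names(tracks)))
  ok <- tapply(tracks$frame, tracks$track_id,
               function(f) all(diff(f) > 0) || length(f) == 1)
  if (!all(unlist(ok)))
    stop_param("frames must be strictly increasing within each track")
  structure(list(tracks = tracks, frame_rate = frame_rate),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat("<track_set> ", length(unique(x$tracks$track_id)), " tracks, ",
      nrow(x$tracks), " points\n", sep = "")
  invisible(x)
}

track_list <- function(ts) split(ts$tracks, ts$tracks$track_id)

#' Detect microbubbles in a filtered frame
#'
#' Local maxima above `threshold` are refined to sub-pixel position by the
#' intensity-weighted centroid of a `(2r+1)^2` window; maxima closer than
#' `psf_radius` are merged into the brighter one.
#'
#' @param frame 2D image (clutter-filtered magnitude or envelope).
#' @param threshold detection threshold, a.u. (`> 0`).
#' @param psf_radius merge radius / centroid window half-width, pixels.
#' @param pixel_size_mm (x, z) pixel size used for the mm coordinates.
#' @return data frame (x_px, z_px, x_mm, z_mm, intensity); 0-based pixel
#'   coordinates, mm coordinates at `pixel * pixel_size`.
#' @export
detect_bubbles <- function(frame, threshold, psf_radius = 2,
                           pixel_size_mm = c(0.1, 0.1)) {
  check_positive(threshold, "threshold")
  f <- as.matrix(frame)
  nx <- nrow(f); nz <- ncol(f)
  if (nx < 3 || nz < 3) return(empty_detections())
  core <- f[2:(nx - 1), 2:(nz - 1)]
  is_max <- core > threshold
  for (dx in -1:1) for (dz in -1:1) {
    if (dx == 0 && dz == 0) next
    is_max <- is_max & core >= f[2:(nx - 1) + dx, 2:(nz - 1) + dz]
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (!nrow(hits)) return(empty_detections())
  hits <- hits + 1 # undo border crop
  inten <- f[hits]
  ord <- order(inten, decreasing = TRUE)
  hits <- hits[ord, , drop = FALSE]; inten <- inten[ord]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) { # merge into the brighter (earlier) peak
    if (!keep[i]) next
    if (i < nrow(hits)) {
      j <- (i + 1):nrow(hits)
      d2 <- (hits[j, 1] - hits[i, 1])^2 + (hits[j, 2] - hits[i, 2])^2
      keep[j[d2 < psf_radius^2]] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]; inten <- inten[keep]
  r <- max(1L, as.integer(ceiling(psf_radius)))
  pos <- t(vapply(seq_len(nrow(hits)), function(i) {
    ix <- max(1, hits[i, 1] - r):min(nx, hits[i, 1] + r)
    iz <- max(1, hits[i, 2] - r):min(nz, hits[i, 2] + r)
    w <- f[ix, iz]
    w <- w - min(w) # local background (incl. neighbour tails) removed
    s <- sum(w)
    p <- c(sum(outer(ix, rep(1, length(iz))) * w) / s,
           sum(outer(rep(1, length(ix)), iz) * w) / s)
    # 3-point log-parabolic refinement along each axis: exact for Gaussian
    # spots and free of the pixel-phase bias of the windowed centroid
    cx <- hits[i, 1]; cz <- hits[i, 2]
    if (cx > 1 && cx < nx) {
      v <- f[(cx - 1):(cx + 1), cz]
      if (all(v > 0)) {
        lv <- log(v); den <- lv[1] - 2 * lv[2] + lv[3]
        if (den < -1e-12) {
          d <- 0.5 * (lv[1] - lv[3]) / den
          if (abs(d) <= 1) p[1] <- cx + d
        }
      }
    }
    if (cz > 1 && cz < nz) {
      v <- f[cx, (cz - 1):(cz + 1)]
      if (all(v > 0)) {
        lv <- log(v); den <- lv[1] - 2 * lv[2] + lv[3]
        if (den < -1e-12) {
          d <- 0.5 * (lv[1] - lv[3]) / den
          if (abs(d) <= 1) p[2] <- cz + d
        }
      }
    }
    p
  }, numeric(2)))
  data.frame(x_px = pos[, 1] - 1, z_px = pos[, 2] - 1,
             x_mm = (pos[, 1] - 1) * pixel_size_mm[1],
             z_mm = (pos[, 2] - 1) * pixel_size_mm[2],
             intensity = inten)
}

empty_detections <- function() {
  data.frame(x_px = numeric(), z_px = numeric(), x_mm = numeric(),
             z_mm = numeric(), intensity = numeric())
}

#' Minimum-cost bipartite assignment (Hungarian method)
#'
#' Optimal assignment of rows to columns minimizing total cost, via shortest
#' augmenting paths with potentials. Rectangular matrices are allowed; with
#' more rows than columns the unassignable rows get `NA`.
#'
#' @param cost numeric cost matrix.
#' @return list(assignment = column per row (NA if unassigned),
#'   total_cost).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop_param("cost matrix must be finite")
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0)
    return(list(assignment = rep(NA_integer_, n), total_cost = 0))
  if (n <= m) {
    a <- cpp_hungarian(cost)
    list(assignment = a,
         total_cost = sum(cost[cbind(seq_len(n), a)]))
  } else {
    a <- cpp_hungarian(t(cost)) # assign columns to rows
    out <- rep(NA_integer_, n)
    out[a] <- seq_len(m)
    list(assignment = out,
         total_cost = sum(cost[cbind(a, seq_len(m))]))
  }
}

#' Link detections into tracks (Hungarian method)
#'
#' For each frame, active track heads are matched to the new detections by
#' minimum-cost assignment on Euclidean distance, gated at `max_link_dist`
#' per elapsed frame (candidate pairs beyond the gate are infeasible;
#' unmatched heads terminate after `max_gap` missed frames, unmatched
#' detections start new tracks). Tracks shorter than `min_track_length` are
#' discarded. Per-point velocities come from central differences.
#'
#' @param detections list of per-frame detection data frames (as returned by
#'   [detect_bubbles()]), in frame order; `NULL`/empty entries are allowed.
#' @param max_link_dist gating distance per frame, mm. Default matches a
#'   50 mm/s maximum speed at the given frame rate.
#' @param max_gap frames a track may go undetected before termination.
#' @param min_track_length minimum points per returned track.
#' @param frame_rate Hz (for velocities).
#' @return A [track_set()].
#' @export
link_tracks <- function(detections, max_link_dist = 50 / frame_rate,
                        max_gap = 0, min_track_length = 4,
                        frame_rate = 1000) {
  BIG <- 1e12
  active <- list() # each: list(pts = data.frame, last_frame)
  done <- list()
  for (fi in seq_along(detections)) {
    det <- detections[[fi]]
    ndet <- if (is.null(det)) 0L else nrow(det)
    # retire stale heads
    if (length(active)) {
      stale <- vapply(active, function(a) fi - a$last_frame > max_gap + 1, TRUE)
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    na_ <- length(active)
    if (ndet == 0) next
    if (na_ == 0) {
      for (j in seq_len(ndet))
        active[[length(active) + 1]] <-
          list(pts = cbind(det[j, , drop = FALSE], frame = fi), last_frame = fi)
      next
    }
    heads <- t(vapply(active, function(a) {
      p <- a$pts[nrow(a$pts), ]
      c(p$x_mm, p$z_mm, a$last_frame)
    }, numeric(3)))
    D <- sqrt(outer(heads[, 1], det$x_mm, `-`)^2 +
                outer(heads[, 2], det$z_mm, `-`)^2)
    gate_i <- max_link_dist * (fi - heads[, 3]) # per elapsed frame
    Dm <- D
    Dm[D > gate_i] <- BIG
    n_all <- na_ + ndet
    C <- matrix(BIG, n_all, n_all)
    C[seq_len(na_), seq_len(ndet)] <- Dm
    C[cbind(seq_len(na_), ndet + seq_len(na_))] <- max_link_dist # termination
    C[cbind(na_ + seq_len(ndet), seq_len(ndet))] <- max_link_dist # birth
    C[na_ + seq_len(ndet), ndet + seq_len(na_)] <- 0
    asg <- cpp_hungarian(C)
    new_active <- list()
    for (i in seq_len(na_)) {
      j <- asg[i]
      if (j <= ndet && Dm[i, j] < BIG) {
        a <- active[[i]]
        a$pts <- rbind(a$pts, cbind(det[j, , drop = FALSE], frame = fi))
        a$last_frame <- fi
        new_active[[length(new_active) + 1]] <- a
      } else {
        new_active[[length(new_active) + 1]] <- active[[i]] # may still link later (gap)
      }
    }
    linked <- vapply(seq_len(na_), function(i) {
      j <- asg[i]
      if (j <= ndet && Dm[i, j] < BIG) j else NA_integer_
    }, 1L)
    linked <- linked[!is.na(linked)]
    for (j in setdiff(seq_len(ndet), linked))
      new_active[[length(new_active) + 1]] <-
        list(pts = cbind(det[j, , drop = FALSE], frame = fi), last_frame = fi)
    active <- new_active
  }
  done <- c(done, active)
  done <- Filter(function(a) nrow(a$pts) >= min_track_length, done)
  if (!length(done)) {
    return(track_set(data.frame(track_id = integer(), frame = integer(),
                                x_mm = numeric(), z_mm = numeric(),
                                vx_mm_s = numeric(), vz_mm_s = numeric()),
                     frame_rate))
  }
  out <- do.call(rbind, lapply(seq_along(done), function(k) {
    p <- done[[k]]$pts
    v <- track_velocity(p$x_mm, p$z_mm, p$frame, frame_rate)
    data.frame(track_id = k, frame = p$frame, x_mm = p$x_mm, z_mm = p$z_mm,
               vx_mm_s = v[, 1], vz_mm_s = v[, 2])
  }))
  track_set(out, frame_rate)
}

# Central-difference velocity (one-sided at the ends), mm/s.
track_velocity <- function(x, z, frame, frame_rate) {
  n <- length(x)
  if (n == 1) return(cbind(0, 0))
  i0 <- pmax(seq_len(n) - 1, 1); i1 <- pmin(seq_len(n) + 1, n)
  dt <- (frame[i1] - frame[i0]) / frame_rate
  cbind((x[i1] - x[i0]) / dt, (z[i1] - z[i0]) / dt)
}

#' Smooth and upsample a track
#'
#' Sliding-average smoothing (window shrinks symmetrically at the track
#' ends) followed by linear interpolation to `upsample` times the temporal
#' density. Straight tracks are mapped onto themselves (collinearity is
#' preserved).
#'
#' @param track data frame with frame, x_mm, z_mm (one track).
#' @param smooth_window odd window length in points (`1` = no smoothing).
#' @param upsample integer temporal upsampling factor (`1` = none).
#' @return Data frame with fractional `frame` and refined positions.
#' @export
refine_track <- function(track, smooth_window = 5, upsample = 10) {
  stopifnot(smooth_window >= 1, smooth_window %% 2 == 1, upsample >= 1)
  n <- nrow(track)
  h <- (smooth_window - 1) / 2
  sm <- function(x) {
    vapply(seq_len(n), function(i) {
      k <- min(h, i - 1, n - i) # shrink symmetrically at the edges
      mean(x[(i - k):(i + k)])
    }, 0)
  }
  x <- sm(track$x_mm); z <- sm(track$z_mm)
  if (upsample == 1 || n == 1) {
    return(data.frame(frame = track$frame, x_mm = x, z_mm = z))
  }
  fout <- seq(track$frame[1], track$frame[n], length.out = (n - 1) * upsample + 1)
  data.frame(frame = fout,
             x_mm = approx(track$frame, x, xout = fout)$y,
             z_mm = approx(track$frame, z, xout = fout)$y)
}

#' Render super-resolved ULM density and velocity maps
#'
#' Every (refined, interpolated) track point is accumulated on a fine pixel
#' grid: density is the point count per pixel, velocity the density-weighted
#' mean speed (finite differences on the refined track times the frame
#' rate). 5 um pixels resolve vessels an order of magnitude below the
#' Doppler resolution.
#'
#' @param tracks a [track_set()].
#' @param pixel_size_mm output pixel size (default 0.005 mm = 5 um).
#' @param extent_mm (x, z) extents of the map, mm.
#' @param smooth_window,upsample passed to [refine_track()].
#' @return An `ulm_maps` object: density (counts), velocity (mm/s, NA where
#'   density is 0), pixel_size_mm.
#' @export
render_ulm_maps <- function(tracks, pixel_size_mm = 0.005,
                            extent_mm = NULL, smooth_window = 5,
                            upsample = 10) {
  stopifnot(inherits(tracks, "track_set"))
  check_positive(pixel_size_mm, "pixel_size_mm")
  tl <- track_list(tracks)
  fr <- tracks$frame_rate %||% 1
  if (is.null(extent_mm))
    extent_mm <- c(max(tracks$tracks$x_mm, 0), max(tracks$tracks$z_mm, 0))
  nx <- floor(extent_mm[1] / pixel_size_mm) + 1
  nz <- floor(extent_mm[2] / pixel_size_mm) + 1
  dens <- matrix(0, nx, nz)
  vsum <- matrix(0, nx, nz)
  for (tr in tl) {
    r <- refine_track(tr, smooth_window, upsample)
    np <- nrow(r)
    if (np >= 2) {
      i0 <- pmax(seq_len(np) - 1, 1); i1 <- pmin(seq_len(np) + 1, np)
      dt <- (r$frame[i1] - r$frame[i0]) / fr
      speed <- sqrt((r$x_mm[i1] - r$x_mm[i0])^2 +
                      (r$z_mm[i1] - r$z_mm[i0])^2) / dt
    } else speed <- 0
    px <- floor(r$x_mm / pixel_size_mm + 0.5) + 1
    pz <- floor(r$z_mm / pixel_size_mm + 0.5) + 1
    ok <- px >= 1 & px <= nx & pz >= 1 & pz <= nz
    for (k in which(ok)) {
      dens[px[k], pz[k]] <- dens[px[k], pz[k]] + 1
      vsum[px[k], pz[k]] <- vsum[px[k], pz[k]] + speed[k]
    }
  }
  vel <- vsum / dens
  vel[dens == 0] <- NA_real_
  structure(list(density = dens, velocity = vel,
                 pixel_size_mm = pixel_size_mm), class = "ulm_maps")
}

#' Demons non-rigid displacement between two images
#'
#' Thirion-style demons with Gaussian regularization of the displacement
#' field, run coarse-to-fine over an internal pyramid so that shifts of
#' several pixels stay inside the capture range. The returned field `d`
#' warps `imgB` toward `imgA`: `B(x + d(x)) ~ A(x)`.
#'
#' @param imgA,imgB 2D images of identical shape (finite).
#' @param n_iter iterations per pyramid level.
#' @param reg_sigma Gaussian regularization of the field, pixels.
#' @param pre_blur_sigma optional Gaussian blur of both inputs (pixels);
#'   near-binary super-resolution maps need gradients, so blur them first.
#' @param pyramid shrink factors, coarse to fine.
#' @return nx x nz x 2 array (dx, dz in pixels); attribute `converged` is
#'   FALSE (with a warning) when the residual did not shrink.
#' @export
demons_displacement <- function(imgA, imgB, n_iter = 50, reg_sigma = 2,
                                pre_blur_sigma = 0, pyramid = c(4, 2, 1)) {
  A <- as.matrix(imgA); B <- as.matrix(imgB)
  if (!all(dim(A) == dim(B))) stop_param("images must have the same shape")
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop_param("non-finite input image")
  if (pre_blur_sigma > 0) {
    A <- blur2(A, pre_blur_sigma)
    B <- blur2(B, pre_blur_sigma)
  }
  init_res <- mean(abs(A - B))
  d <- dim(A)
  field <- array(0, c(d, 2))
  for (s in pyramid) {
    if (s > min(d)) next
    As <- shrink2(A, s); Bs <- shrink2(B, s)
    fs <- array(0, c(dim(As), 2))
    fs[, , 1] <- shrink2(field[, , 1], s) / s
    fs[, , 2] <- shrink2(field[, , 2], s) / s
    gx <- grad_x(As); gz <- grad_z(As)
    for (it in seq_len(n_iter)) {
      Bw <- warp2(Bs, fs)
      diff <- Bw - As
      den <- gx^2 + gz^2 + diff^2
      upd_x <- ifelse(den > 1e-12, -diff * gx / den, 0)
      upd_z <- ifelse(den > 1e-12, -diff * gz / den, 0)
      fs[, , 1] <- blur2(fs[, , 1] + upd_x, reg_sigma)
      fs[, , 2] <- blur2(fs[, , 2] + upd_z, reg_sigma)
    }
    field[, , 1] <- expand2(fs[, , 1], d) * s
    field[, , 2] <- expand2(fs[, , 2], d) * s
  }
  final_res <- mean(abs(warp2(B, field) - A))
  converged <- final_res <= 0.8 * init_res || init_res < 1e-12
  if (!converged)
    warning("demons did not converge: residual ", format(final_res, digits = 3),
            " vs initial ", format(init_res, digits = 3),
            " (displacement may exceed the capture range)")
  attr(field, "converged") <- converged
  field
}

blur2 <- function(img, sigma) {
  if (sigma <= 0) return(img)
  d <- dim(img)
  matrix(cpp_blur3(as.vector(img), c(d, 1L), c(sigma, sigma, 0)), d[1], d[2])
}

shrink2 <- function(img, s) {
  if (s == 1) return(img)
  b <- blur2(img, s / 2)
  b[seq(1, nrow(b), by = s), seq(1, ncol(b), by = s), drop = FALSE]
}

expand2 <- function(img, target_dim) {
  if (all(dim(img) == target_dim)) return(img)
  # bilinear upsample back to the full grid
  sx <- (nrow(img) - 1) / max(target_dim[1] - 1, 1)
  sz <- (ncol(img) - 1) / max(target_dim[2] - 1, 1)
  idx <- cbind(rep((seq_len(target_dim[1]) - 1) * sx, times = target_dim[2]),
               rep((seq_len(target_dim[2]) - 1) * sz, each = target_dim[1]),
               0)
  matrix(cpp_sample3(as.vector(img), c(dim(img), 1L), idx, 0L, 0),
         target_dim[1], target_dim[2])
}

grad_x <- function(img) {
  n <- nrow(img)
  (img[pmin(seq_len(n) + 1, n), , drop = FALSE] -
     img[pmax(seq_len(n) - 1, 1), , drop = FALSE]) / 2
}

grad_z <- function(img) t(grad_x(t(img)))

# Warp img by field: out(x) = img(x + d(x)), bilinear, replicated border.
warp2 <- function(img, field) {
  d <- dim(img)
  ix <- rep(seq_len(d[1]) - 1, times = d[2]) + as.vector(field[, , 1])
  iz <- rep(seq_len(d[2]) - 1, each = d[1]) + as.vector(field[, , 2])
  ix <- pmin(pmax(ix, 0), d[1] - 1)
  iz <- pmin(pmax(iz, 0), d[2] - 1)
  matrix(cpp_sample3(as.vector(img), c(d, 1L), cbind(ix, iz, 0), 0L, 0),
         d[1], d[2])
}

#' Vasculature-averaged misalignment between two ULM acquisitions
#'
#' Averages the demons displacement field over the (dilated) intersection of
#' the two vascular masks and converts to micrometres; the single per-
#' direction value quantifies the repositioning error between acquisitions.
#'
#' @param field displacement field from [demons_displacement()], pixels.
#' @param maskA,maskB logical vasculature masks (e.g. `density > 0`).
#' @param pixel_size_mm map pixel size, mm.
#' @param dilate_px square dilation radius applied to each mask first.
#' @return list(mean_shift_um = c(lateral, axial), mask_voxel_count).
#' @export
mean_misalignment <- function(field, maskA, maskB, pixel_size_mm,
                              dilate_px = 2) {
  maskA <- dilate2(maskA, dilate_px)
  maskB <- dilate2(maskB, dilate_px)
  m <- maskA & maskB
  if (!any(m)) stop_param("vascular masks do not overlap")
  dx <- field[, , 1][m]; dz <- field[, , 2][m]
  list(mean_shift_um = c(lateral = mean(dx), axial = mean(dz)) *
         pixel_size_mm * 1000,
       mask_voxel_count = sum(m))
}

dilate2 <- function(mask, r) {
  mask <- as.matrix(mask) > 0
  if (r <= 0) return(mask)
  out <- mask
  d <- dim(mask)
  for (dx in -r:r) for (dz in -r:r) {
    if (dx == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    zs <- pmin(pmax(seq_len(d[2]) + dz, 1), d[2])
    out <- out | mask[xs, zs]
  }
  out
}

#' Write / read tracks as CSV
#'
#' Columns: `track_id,frame,x_mm,z_mm,vx_mm_s,vz_mm_s`.
#'
#' @param tracks a [track_set()].
#' @param path CSV path.
#' @return `read_tracks` returns the [track_set()].
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  df <- tracks$tracks
  for (col in c("vx_mm_s", "vz_mm_s")) if (!col %in% names(df)) df[[col]] <- NA
  write.csv(df[, c("track_id", "frame", "x_mm", "z_mm", "vx_mm_s", "vz_mm_s")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, frame_rate = NULL) {
  df <- read.csv(path)
  need <- c("track_id", "frame", "x_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("malformed track CSV at ", path, ": need columns ",
         paste(need, collapse = ","))
  track_set(df, frame_rate)
}
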