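# Seeded synthetic phantoms: vascular trees, Doppler volumes, tissue+blood
# frame stacks, microbubble movies with ground truth, and functional CBV
# series. Every generator is a pure function of (params, seed) and returns
# the latent truth needed by downstream validation.

#' Vessel tree parameters
#'
#' @param extent_mm domain box extents (x, y, z), mm.
#' @param depth branching depth; a binary tree of depth `d` has `2^(d+1) - 1`
#'   segments.
#' @param root_radius_mm radius of the trunk, mm.
#' @param radius_ratio child/parent radius ratio (`<= 1`).
#' @param length0_mm trunk length before the tree is fitted to the box.
#' @param length_ratio child/parent segment length ratio.
#' @param branch_angle_deg mean half-angle between siblings.
#' @param jitter_deg random perturbation of branch angles.
#' @param margin fraction of each extent kept clear at the box faces.
#' @return A parameter list for [generate_vessel_tree()].
#' @export
vessel_tree_params <- function(extent_mm = c(12.8, 6, 6), depth = 5,
                               root_radius_mm = 0.15, radius_ratio = 0.78,
                               length0_mm = 0.35 * extent_mm[1],
                               length_ratio = 0.72, branch_angle_deg = 35,
                               jitter_deg = 8, margin = 0.05) {
  list(extent_mm = extent_mm, depth = depth, root_radius_mm = root_radius_mm,
       radius_ratio = radius_ratio, length0_mm = length0_mm,
       length_ratio = length_ratio, branch_angle_deg = branch_angle_deg,
       jitter_deg = jitter_deg, margin = margin)
}

#' Generate a synthetic vascular tree
#'
#' Grows a binary branching tree (trunk plus two children per segment down to
#' `depth`), then anisotropically fits the node cloud into the domain box with
#' a `margin` clearance, so the tree spans 90% of every axis. Stands in for
#' the subject's cerebral vascular fingerprint in registration and ULM
#' phantoms.
#'
#' @param seed integer RNG seed; the tree is a pure function of
#'   (seed, params).
#' @param params see [vessel_tree_params()].
#' @return A `vessel_tree`: `segments` data frame (start/end points mm,
#'   radius mm, branch depth, parent index) and `extent_mm`.
#' @export
generate_vessel_tree <- function(seed = 1, params = vessel_tree_params()) {
  ext <- params$extent_mm
  if (!is.numeric(ext) || length(ext) != 3 || any(ext <= 0))
    stop_param("domain extents must be three positive numbers")
  if (params$depth < 0) stop_param("depth must be >= 0")
  with_seed(seed, {
    segs <- list()
    grow <- function(start, dir, depth_i, radius, len, parent) {
      end <- start + len * dir
      segs[[length(segs) + 1]] <<- c(start, end, radius, depth_i, parent)
      me <- length(segs)
      if (depth_i >= params$depth) return(invisible())
      # orthonormal frame around dir
      a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a - sum(a * dir) * dir; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
              dir[3] * e1[1] - dir[1] * e1[3],
              dir[1] * e1[2] - dir[2] * e1[1])
      phi <- runif(1, 0, 2 * pi)
      for (sgn in c(0, pi)) {
        ang <- (params$branch_angle_deg +
                  runif(1, -params$jitter_deg, params$jitter_deg)) * pi / 180
        p <- phi + sgn + runif(1, -0.3, 0.3)
        cd <- cos(ang) * dir + sin(ang) * (cos(p) * e1 + sin(p) * e2)
        cd <- cd / sqrt(sum(cd^2))
        grow(end, cd, depth_i + 1, radius * params$radius_ratio,
             len * params$length_ratio, me)
      }
    }
    d0 <- c(1, 0.35, 0.3); d0 <- d0 / sqrt(sum(d0^2))
    grow(c(0, 0, 0), d0, 0, params$root_radius_mm, params$length0_mm, 0L)
    m <- do.call(rbind, segs)
    colnames(m) <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "depth",
                     "parent")
    # fit the node cloud into [margin, 1 - margin] * extent per axis
    for (ax in 1:3) {
      pts <- c(m[, ax], m[, ax + 3])
      lo <- min(pts); hi <- max(pts)
      tlo <- params$margin * ext[ax]; thi <- (1 - params$margin) * ext[ax]
      if (hi - lo > 1e-9) {
        sc <- (thi - tlo) / (hi - lo)
        m[, ax] <- tlo + (m[, ax] - lo) * sc
        m[, ax + 3] <- tlo + (m[, ax + 3] - lo) * sc
      } else {
        m[, ax] <- m[, ax] - lo + ext[ax] / 2
        m[, ax + 3] <- m[, ax + 3] - lo + ext[ax] / 2
      }
    }
    structure(list(segments = as.data.frame(m), extent_mm = ext,
                   params = params, seed = seed), class = "vessel_tree")
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat("<vessel_tree> ", nrow(x$segments), " segments, depth ",
      max(x$segments$depth), ", box ", paste(x$extent_mm, collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

# Root-to-leaf polylines (list of point matrices), used as bubble paths.
tree_paths <- function(tree) {
  s <- tree$segments
  children <- split(seq_len(nrow(s)), s$parent)
  leaves <- setdiff(seq_len(nrow(s)), s$parent)
  lapply(leaves, function(leaf) {
    chain <- leaf
    while (s$parent[chain[1]] != 0) chain <- c(s$parent[chain[1]], chain)
    pts <- rbind(as.matrix(s[chain[1], c("x0", "y0", "z0")]),
                 as.matrix(s[chain, c("x1", "y1", "z1")]))
    dimnames(pts) <- NULL
    pts
  })
}

#' Vascular landmarks of a phantom tree
#'
#' Returns the first `n` branch points (segment endpoints in breadth order)
#' as a named landmark set (VL1, VL2, ...), mimicking the manually annotated
#' vascular landmarks used to audit registration accuracy.
#'
#' @param tree a [generate_vessel_tree()] result.
#' @param n number of landmarks.
#' @return A [landmark_set()].
#' @export
vessel_landmarks <- function(tree, n = 4) {
  s <- tree$segments[order(tree$segments$depth), ]
  n <- min(n, nrow(s))
  pts <- as.matrix(s[seq_len(n), c("x1", "y1", "z1")])
  rownames(pts) <- paste0("VL", seq_len(n))
  landmark_set(pts)
}

#' Rasterize a vessel tree into a Power Doppler volume
#'
#' Voxels near a segment carry intensity proportional to radius^2 (a blood
#' volume proxy) with a Gaussian radial profile (sigma = radius) so the
#' metric sees smooth gradients; additive Gaussian noise with standard
#' deviation `peak / snr` is clamped at zero.
#'
#' @param tree a [generate_vessel_tree()] result.
#' @param spacing voxel spacing mm triple; grid dimension per axis is
#'   `floor(extent / spacing) + 1` (voxel centres at `i * spacing`).
#' @param snr peak-signal to noise-sd ratio; `Inf` for noise-free.
#' @param seed RNG seed for the noise.
#' @return A [doppler_volume()].
#' @export
rasterize_doppler_volume <- function(tree, spacing = c(0.1, 0.1, 0.2),
                                     snr = 20, seed = 1) {
  check_positive(spacing, "spacing")
  stopifnot(inherits(tree, "vessel_tree"))
  ext <- tree$extent_mm
  dims <- floor(ext / spacing) + 1
  vol <- array(0, dims)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  s <- tree$segments
  for (i in seq_len(nrow(s))) {
    p0 <- c(s$x0[i], s$y0[i], s$z0[i]); p1 <- c(s$x1[i], s$y1[i], s$z1[i])
    r <- s$radius[i]
    reach <- 3 * r
    rng <- lapply(1:3, function(a) {
      which(ax[[a]] >= min(p0[a], p1[a]) - reach &
              ax[[a]] <= max(p0[a], p1[a]) + reach)
    })
    if (any(vapply(rng, length, 1L) == 0)) next
    gx <- ax[[1]][rng[[1]]]; gy <- ax[[2]][rng[[2]]]; gz <- ax[[3]][rng[[3]]]
    nxl <- length(gx); nyl <- length(gy); nzl <- length(gz)
    px <- rep(gx, times = nyl * nzl)
    py <- rep(rep(gy, each = nxl), times = nzl)
    pz <- rep(gz, each = nxl * nyl)
    d <- p1 - p0; len2 <- sum(d^2)
    t_ <- ((px - p0[1]) * d[1] + (py - p0[2]) * d[2] + (pz - p0[3]) * d[3]) / len2
    t_ <- pmin(pmax(t_, 0), 1)
    dist2 <- (px - (p0[1] + t_ * d[1]))^2 + (py - (p0[2] + t_ * d[2]))^2 +
      (pz - (p0[3] + t_ * d[3]))^2
    val <- r^2 * exp(-dist2 / (2 * r^2))
    sub <- array(vol[rng[[1]], rng[[2]], rng[[3]]], c(nxl, nyl, nzl))
    vol[rng[[1]], rng[[2]], rng[[3]]] <- pmax(sub, array(val, c(nxl, nyl, nzl)))
  }
  if (is.finite(snr)) {
    check_positive(snr, "snr")
    vol <- with_seed(seed, vol + rnorm(length(vol), 0, max(vol) / snr))
    vol[vol < 0] <- 0
  }
  doppler_volume(vol, spacing)
}

#' Simulate a beamformed compounded frame stack
#'
#' Tissue clutter is a sum of `tissue_rank` spatially coherent, slowly varying
#' temporal modes of large amplitude; blood signal is fast-decorrelating
#' (temporally white) and confined to `blood_mask`; white sensor noise is
#' added everywhere. The result feeds the SVD clutter filter.
#'
#' @param n_frames number of compounded frames.
#' @param grid pixel grid (nx, nz).
#' @param tissue_rank number of tissue modes (`< n_frames`).
#' @param blood_mask logical nx x nz matrix (NULL for no blood).
#' @param blood_power blood signal variance.
#' @param seed RNG seed.
#' @param tissue_power variance scale of the strongest tissue mode.
#' @param noise_power white noise variance (0 for noise-free).
#' @param compound_rate compounded frame rate, Hz.
#' @param prf pulse repetition frequency, Hz.
#' @param angles plane-wave tilt angles, degrees.
#' @param pixel_size_mm pixel size (x, z), mm.
#' @return A [frame_stack()].
#' @export
simulate_frame_stack <- function(n_frames = 200, grid = c(64, 64),
                                 tissue_rank = 5, blood_mask = NULL,
                                 blood_power = 1, seed = 1,
                                 tissue_power = 100, noise_power = 1e-3,
                                 compound_rate = 500, prf = 5500,
                                 angles = seq(-10, 10, by = 2),
                                 pixel_size_mm = c(0.1, 0.1)) {
  if (tissue_rank >= n_frames)
    stop_param("tissue_rank must be < n_frames")
  stopifnot(n_frames >= 2, length(grid) == 2)
  with_seed(seed, {
    nx <- grid[1]; nz <- grid[2]; np <- nx * nz
    t_s <- (seq_len(n_frames) - 1) / compound_rate
    data <- matrix(0, np, n_frames)
    for (k in seq_len(tissue_rank)) {
      sp <- array(rnorm(np), c(nx, nz, 1))
      sp <- cpp_blur3(as.vector(sp), c(nx, nz, 1L), c(6, 6, 0))
      sp <- sp / sqrt(mean(sp^2))
      f <- runif(1, 0.2, 2) # Hz, slow tissue motion
      tm <- cos(2 * pi * f * t_s + runif(1, 0, 2 * pi))
      amp <- sqrt(tissue_power) / k
      data <- data + amp * outer(as.vector(sp), tm)
    }
    if (!is.null(blood_mask) && any(blood_mask)) {
      stopifnot(all(dim(blood_mask) == grid))
      idx <- which(as.vector(blood_mask))
      data[idx, ] <- data[idx, ] +
        matrix(rnorm(length(idx) * n_frames, 0, sqrt(blood_power)),
               length(idx), n_frames)
    }
    if (noise_power > 0)
      data <- data + rnorm(np * n_frames, 0, sqrt(noise_power))
    frame_stack(array(data, c(nx, nz, n_frames)),
                compound_rate = compound_rate, prf = prf, angles = angles,
                pixel_size_mm = pixel_size_mm)
  })
}

#' Simulate a microbubble movie with ground-truth tracks
#'
#' Each bubble travels at constant speed along a root-to-leaf centreline of
#' the vessel tree (projected to the lateral/depth plane) and is rendered as
#' an isotropic Gaussian spot. The returned track set is exact ground truth.
#'
#' @param tree a [generate_vessel_tree()] result.
#' @param n_bubbles number of bubbles (`>= 1`).
#' @param n_frames movie length in frames.
#' @param frame_rate Hz.
#' @param psf_sigma point-spread sigma, pixels.
#' @param seed RNG seed.
#' @param pixel_size_mm pixel size (x, z), mm.
#' @param speed_range_mm_s per-bubble speed drawn uniformly from this range;
#'   give a single value for exact constant speed.
#' @param noise_sd additive image noise (0 = noise-free).
#' @param amplitude peak spot amplitude.
#' @param min_separation_mm minimum distance between co-visible bubbles
#'   (default 4 PSF sigmas, just beyond the localizer's centroid window);
#'   placements violating it are redrawn so that every simulated bubble is
#'   resolvable. Bubbles within a PSF of each other are indistinguishable
#'   by construction and would make the ground truth unrecoverable for any
#'   tracker; a warning is issued if a placement cannot be found.
#' @return list(stack = [frame_stack()], tracks = [track_set()]).
#' @export
simulate_bubble_movie <- function(tree, n_bubbles = 20, n_frames = 100,
                                  frame_rate = 1000, psf_sigma = 1.2,
                                  seed = 1, pixel_size_mm = c(0.1, 0.1),
                                  speed_range_mm_s = c(8, 30), noise_sd = 0,
                                  amplitude = 1,
                                  min_separation_mm = 4 * psf_sigma *
                                    max(pixel_size_mm)) {
  stopifnot(inherits(tree, "vessel_tree"), n_bubbles >= 1, n_frames >= 1)
  paths <- tree_paths(tree)
  nx <- floor(tree$extent_mm[1] / pixel_size_mm[1]) + 1
  nz <- floor(tree$extent_mm[3] / pixel_size_mm[2]) + 1
  gx <- (seq_len(nx) - 1) * pixel_size_mm[1]
  gz <- (seq_len(nz) - 1) * pixel_size_mm[2]
  if (length(speed_range_mm_s) == 1)
    speed_range_mm_s <- rep(speed_range_mm_s, 2)
  with_seed(seed, {
    frames <- array(0, c(nx, nz, n_frames))
    tracks <- vector("list", n_bubbles)
    # per-bubble n_frames x 2 matrix of positions (NA where not visible)
    occupied <- vector("list", n_bubbles)
    for (b in seq_len(n_bubbles)) {
      for (attempt in 1:1000) {
        path <- paths[[sample.int(length(paths), 1)]][, c(1, 3), drop = FALSE]
        seglen <- sqrt(rowSums(diff(path)^2))
        cum <- c(0, cumsum(seglen))
        total <- cum[length(cum)]
        speed <- runif(1, speed_range_mm_s[1], speed_range_mm_s[2])
        # early attempts keep the bubble visible for the whole movie; if the
        # tree cannot host that many co-visible bubbles at the required
        # separation, later attempts stagger the wash-in frame
        entry <- if (attempt <= 300 || n_frames < 8) 0L
        else sample.int(max(1L, n_frames - 8L), 1) - 1L
        vis <- entry:(n_frames - 1)
        s0 <- runif(1, 0, max(total - speed * (length(vis) - 1) / frame_rate, 0))
        s_at <- s0 + speed * (vis - entry) / frame_rate
        keep <- s_at <= total + 1e-12
        vis <- vis[keep]
        s_at <- pmin(s_at[keep], total)
        xs <- approx(cum, path[, 1], xout = s_at)$y
        zs <- approx(cum, path[, 2], xout = s_at)$y
        pos <- matrix(NA_real_, n_frames, 2)
        pos[vis + 1, ] <- cbind(xs, zs)
        ok <- TRUE
        for (prev in occupied[seq_len(b - 1)]) {
          d2 <- (pos[, 1] - prev[, 1])^2 + (pos[, 2] - prev[, 2])^2
          if (any(d2 < min_separation_mm^2, na.rm = TRUE)) { ok <- FALSE; break }
        }
        if (ok) break
      }
      if (!ok)
        warning("bubble ", b, ": could not honour min_separation_mm = ",
                signif(min_separation_mm, 3),
                " after 1000 placement attempts; reduce n_bubbles or the separation")
      occupied[[b]] <- pos
      tracks[[b]] <- data.frame(track_id = b, frame = vis + 1L,
                                x_mm = xs, z_mm = zs, speed_mm_s = speed)
      sx <- psf_sigma * pixel_size_mm[1]; sz <- psf_sigma * pixel_size_mm[2]
      for (j in seq_along(s_at)) {
        ix <- which(abs(gx - xs[j]) <= 4 * sx)
        iz <- which(abs(gz - zs[j]) <= 4 * sz)
        if (!length(ix) || !length(iz)) next
        spot <- amplitude *
          outer(exp(-(gx[ix] - xs[j])^2 / (2 * sx^2)),
                exp(-(gz[iz] - zs[j])^2 / (2 * sz^2)))
        frames[ix, iz, vis[j] + 1] <-
          frames[ix, iz, vis[j] + 1] + spot
      }
    }
    if (noise_sd > 0)
      frames <- frames + rnorm(length(frames), 0, noise_sd)
    list(stack = frame_stack(frames, compound_rate = frame_rate, prf = NULL,
                             angles = NULL, pixel_size_mm = pixel_size_mm),
         tracks = track_set(do.call(rbind, tracks), frame_rate = frame_rate))
  })
}

#' Simulate functional CBV time series on a labelled map
#'
#' Voxel signal is `baseline * (1 + effect * regressor(t))` plus noise. With
#' `corr` given, the noise is shared at the ROI level and drawn with that
#' correlation (Cholesky of `corr`), which makes the ROI-mean correlation
#' structure the generator's ground truth; otherwise noise is i.i.d. per
#' voxel.
#'
#' @param label_map 2D integer matrix of region labels (0 = background).
#' @param stimulus a [stimulus_pattern()].
#' @param effects named numeric: fractional CBV change per region id;
#'   names must be a subset of the labels present.
#' @param noise_sd noise standard deviation as a fraction of baseline.
#' @param rate sampling rate, Hz (the Doppler frame rate).
#' @param corr optional ROI x ROI correlation matrix (symmetric PSD, unit
#'   diagonal), ordered by sorted region id.
#' @param seed RNG seed.
#' @param baseline baseline CBV level, a.u.
#' @param voxel_noise_sd additional i.i.d. voxel noise fraction.
#' @return list(series = voxel x time matrix, label_map, rate, time_s,
#'   design, truth = list(effects, corr)).
#' @export
simulate_functional_timeseries <- function(label_map, stimulus, effects,
                                           noise_sd = 0.05, rate = 2.5,
                                           corr = NULL, seed = 1,
                                           baseline = 100,
                                           voxel_noise_sd = 0) {
  check_positive(rate, "rate")
  label_map <- as.matrix(label_map)
  ids <- sort(unique(as.vector(label_map)))
  ids <- ids[ids != 0]
  effects <- effects[order(as.numeric(names(effects)))] %||% numeric()
  if (length(effects) && !all(as.numeric(names(effects)) %in% ids))
    stop_param("effects keys must be a subset of the labels present")
  if (!is.null(corr)) {
    corr <- as.matrix(corr)
    if (nrow(corr) != length(ids) || ncol(corr) != length(ids))
      stop_param("corr must be ", length(ids), " x ", length(ids))
    if (max(abs(corr - t(corr))) > 1e-8 ||
        min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop_param("corr must be symmetric positive semi-definite")
  }
  design <- build_design(stimulus, rate)
  reg <- design[, 2]
  nt <- nrow(design)
  nvox <- length(label_map)
  eff_vec <- setNames(rep(0, length(ids)), ids)
  eff_vec[names(effects)] <- effects
  with_seed(seed, {
    series <- matrix(baseline, nvox, nt)
    if (!is.null(corr)) {
      ev <- eigen(corr, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ids))
      eta <- matrix(rnorm(nt * length(ids)), nt) %*% t(L) # nt x R
    }
    for (k in seq_along(ids)) {
      vox <- which(as.vector(label_map) == ids[k])
      sig <- baseline * (1 + eff_vec[k] * reg)
      noise <- if (!is.null(corr)) baseline * noise_sd * eta[, k]
      else NULL
      for (v in vox) {
        series[v, ] <- sig + (noise %||% rnorm(nt, 0, baseline * noise_sd))
        if (voxel_noise_sd > 0)
          series[v, ] <- series[v, ] + rnorm(nt, 0, baseline * voxel_noise_sd)
      }
    }
    bg <- which(as.vector(label_map) == 0)
    if (length(bg)) {
      series[bg, ] <- baseline +
        matrix(rnorm(length(bg) * nt, 0, baseline * max(noise_sd, 1e-6)),
               length(bg), nt)
    }
    list(series = series, label_map = label_map, rate = rate,
         time_s = (seq_len(nt) - 1) / rate, design = design,
         truth = list(effects = eff_vec, corr = corr))
  })
}

#' Generate a synthetic mini brain atlas
#'
#' An ellipsoidal "brain" partitioned into `n_regions` Voronoi regions of
#' seeded random sites, with a toy ontology (id, acronym, name, parent, and a
#' depth-based group: isocortex / thalamus / hypothalamus). A drop-in
#' stand-in for a real labelled reference atlas in tests and phantoms; it is
#' synthetic and carries no real anatomy.
#'
#' @param dim label grid dimensions.
#' @param spacing voxel spacing, mm.
#' @param n_regions number of regions.
#' @param seed RNG seed.
#' @return An [atlas_volume()].
#' @export
synthetic_atlas <- function(dim = c(64, 48, 32), spacing = c(0.1, 0.1, 0.2),
                            n_regions = 12, seed = 1) {
  stopifnot(n_regions >= 1)
  with_seed(seed, {
    ext <- (dim - 1) * spacing
    ax <- lapply(1:3, function(a) (seq_len(dim[a]) - 1) * spacing[a])
    cx <- ext / 2
    px <- rep(ax[[1]], times = dim[2] * dim[3])
    py <- rep(rep(ax[[2]], each = dim[1]), times = dim[3])
    pz <- rep(ax[[3]], each = dim[1] * dim[2])
    inside <- ((px - cx[1]) / (0.48 * ext[1]))^2 +
      ((py - cx[2]) / (0.48 * ext[2]))^2 +
      ((pz - cx[3]) / (0.48 * ext[3]))^2 <= 1
    sites <- cbind(runif(n_regions, 0.15, 0.85) * ext[1],
                   runif(n_regions, 0.15, 0.85) * ext[2],
                   runif(n_regions, 0.15, 0.85) * ext[3])
    lab <- integer(length(px))
    idx <- which(inside)
    best <- rep(Inf, length(idx)); bestk <- rep(1L, length(idx))
    for (k in seq_len(n_regions)) {
      d2 <- (px[idx] - sites[k, 1])^2 + (py[idx] - sites[k, 2])^2 +
        (pz[idx] - sites[k, 3])^2
      upd <- d2 < best
      best[upd] <- d2[upd]; bestk[upd] <- k
    }
    lab[idx] <- bestk
    depth_frac <- sites[, 3] / ext[3]
    group <- cut(depth_frac, c(-Inf, 1 / 3, 2 / 3, Inf),
                 labels = c("isocortex", "thalamus", "hypothalamus"))
    ontology <- data.frame(id = seq_len(n_regions),
                           acronym = paste0("R", seq_len(n_regions)),
                           name = paste("synthetic region", seq_len(n_regions)),
                           parent_id = 0L, group = as.character(group))
    atlas_volume(array(lab, dim), spacing, c(0, 0, 0), ontology)
  })
}
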