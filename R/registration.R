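# Monomodal 3D affine registration of Power Doppler volumes by Mattes
# mutual-information maximization with a (1+1) evolution strategy, plus the
# similarity / discrepancy metrics used to audit it.

#' Mutual-information registration configuration
#'
#' @param n_bins joint-histogram bins per axis (all spatial samples are used
#'   by default, density over 50 bins).
#' @param sampling fraction of fixed voxels used as metric samples.
#' @param pyramid_levels multiresolution levels (coarse to fine, shrink
#'   factors `2^(levels-1) ... 1`).
#' @param initial_radius,growth_factor,epsilon,max_iterations (1+1)-ES
#'   search-radius schedule and stopping rule (per level).
#' @param seed optimizer RNG seed (registration is deterministic given it).
#' @param kernel Parzen window on the moving-intensity axis: `"linear"`
#'   (first-order B-spline; exact hard-histogram equivalence for bin-centred
#'   data) or `"cubic"`. The fixed axis is always hard-binned.
#' @param min_overlap minimum fraction of metric samples that must land
#'   inside the moving volume.
#' @param polish_iterations Nelder-Mead refinement budget at the finest
#'   pyramid level after the stochastic search (0 disables); the polish is
#'   deterministic and only kept when it improves the metric.
#' @return An `mi_config` list.
#' @export
mi_config <- function(n_bins = 50, sampling = 1, pyramid_levels = 3,
                      initial_radius = 6.25e-3, growth_factor = 1.05,
                      epsilon = 1.5e-6, max_iterations = 300, seed = 0,
                      kernel = c("linear", "cubic"), min_overlap = 0.1,
                      polish_iterations = 300) {
  kernel <- match.arg(kernel)
  if (n_bins < 2) stop_param("n_bins must be >= 2")
  if (sampling <= 0 || sampling > 1) stop_param("sampling must be in (0, 1]")
  list(n_bins = n_bins, sampling = sampling, pyramid_levels = pyramid_levels,
       initial_radius = initial_radius, growth_factor = growth_factor,
       epsilon = epsilon, max_iterations = max_iterations, seed = seed,
       kernel = kernel, min_overlap = min_overlap,
       polish_iterations = polish_iterations)
}

# Intensity binning: bins span [min, max] with half-bin padding; bin centres
# sit at min + k * width, width = (max - min) / (nbins - 1).
intensity_bins <- function(x, nbins) {
  vmin <- min(x); vmax <- max(x)
  width <- if (vmax > vmin) (vmax - vmin) / (nbins - 1) else 1
  list(min = vmin, width = width)
}

mi_from_joint <- function(joint) {
  s <- sum(joint)
  if (s <= 0) return(0)
  P <- joint / s
  pf <- rowSums(P); pm <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log(P[nz] / (pf[row(P)[nz]] * pm[col(P)[nz]])))
}

# Compose (inverse affine then world-to-index) into a single linear map.
index_map <- function(transform, moving) {
  inv <- invert_affine(transform)
  A <- inv$linear / moving$spacing # row-scale
  b <- (as.vector(inv$linear %*% (-inv$center)) + inv$center +
          inv$translation - moving$origin_mm) / moving$spacing
  list(A = A, b = b)
}

#' Mattes mutual information between two volumes
#'
#' Joint intensity density between the fixed volume's samples and the
#' transformed moving volume, over `n_bins` x `n_bins` bins with a Parzen
#' window on the moving axis (fixed axis hard-binned), reported in nats.
#' Samples mapping outside the moving volume are dropped; if fewer than
#' `min_overlap` of them remain, a degenerate-overlap error is raised (this
#' is what keeps the optimizer from escaping the brain).
#'
#' @param fixed,moving [doppler_volume()]s, normalized to \[0, 1\]
#'   (see [normalize_for_registration()]).
#' @param transform an [affine3d()] mapping moving space into fixed space.
#' @param config an [mi_config()].
#' @param return_joint if `TRUE`, return the joint histogram with the value.
#' @return MI in nats (scalar), or a list(mi, joint, overlap) if
#'   `return_joint`.
#' @export
mattes_mi <- function(fixed, moving, transform = affine3d(),
                      config = mi_config(), return_joint = FALSE) {
  stopifnot(inherits(fixed, "doppler_volume"), inherits(moving, "doppler_volume"))
  pts <- grid_points(grid_of(fixed))
  fvals <- as.vector(fixed$intensity)
  if (config$sampling < 1) {
    keep <- with_seed(config$seed,
                      sample.int(nrow(pts), ceiling(config$sampling * nrow(pts))))
    pts <- pts[keep, , drop = FALSE]
    fvals <- fvals[keep]
  }
  fb <- intensity_bins(fvals, config$n_bins)
  fbin <- pmin(pmax(as.integer(round((fvals - fb$min) / fb$width)), 0L),
               config$n_bins - 1L)
  mp <- index_map(transform, moving)
  idx <- pts %*% t(mp$A)
  idx <- sweep(idx, 2, mp$b, `+`)
  mb <- intensity_bins(moving$intensity, config$n_bins)
  res <- cpp_mi_joint(as.vector(moving$intensity), dim(moving$intensity),
                      idx, fbin, as.integer(config$n_bins), mb$min, mb$width,
                      if (config$kernel == "cubic") 3L else 1L)
  overlap <- res$inside / nrow(pts)
  if (overlap < config$min_overlap)
    stop(errorCondition(
      sprintf("degenerate overlap: %.1f%% of samples inside the moving volume (min %.0f%%)",
              100 * overlap, 100 * config$min_overlap),
      class = c("fusbps_overlap_error", "error")))
  mi <- mi_from_joint(res$joint)
  if (return_joint) list(mi = mi, joint = res$joint, overlap = overlap) else mi
}

#' (1+1) evolution strategy
#'
#' Stochastic hill-climber: the current best is perturbed by an isotropic
#' Gaussian scaled per parameter; an improving offspring replaces it and
#' grows the search radius by `growth_factor`, a failure shrinks it by
#' `growth_factor^(-1/4)`. Stops when the radius falls below `epsilon` or
#' after `max_iterations`. Minimizes; deterministic for a fixed seed.
#'
#' @param objective function of a numeric vector returning a scalar (non-
#'   finite values are treated as rejected candidates).
#' @param x0 start vector (objective must be finite here).
#' @param params list with `initial_radius`, `growth_factor`, `epsilon`,
#'   `max_iterations`, and optional per-parameter `scales`.
#' @param seed RNG seed.
#' @return list(par, value, iterations, trace) where trace is a data frame
#'   (iteration, value, radius, accepted).
#' @export
one_plus_one_es <- function(objective, x0,
                            params = list(initial_radius = 6.25e-3,
                                          growth_factor = 1.05,
                                          epsilon = 1.5e-6,
                                          max_iterations = 300),
                            seed = 0) {
  scales <- params$scales %||% rep(1, length(x0))
  f <- objective(x0)
  if (!is.finite(f)) stop_param("objective is not finite at x0")
  x <- x0
  radius <- params$initial_radius
  grow <- params$growth_factor
  shrink <- grow^(-1 / 4)
  n_it <- params$max_iterations
  tr_val <- numeric(n_it); tr_rad <- numeric(n_it); tr_acc <- logical(n_it)
  it <- 0L
  with_seed(seed, {
    while (it < n_it && radius >= params$epsilon) {
      it <- it + 1L
      cand <- x + rnorm(length(x)) * radius * scales
      fc <- objective(cand)
      if (is.finite(fc) && fc < f) {
        x <- cand; f <- fc; radius <- radius * grow; tr_acc[it] <- TRUE
      } else {
        radius <- radius * shrink
      }
      tr_val[it] <- f; tr_rad[it] <- radius
    }
  })
  list(par = x, value = f, iterations = it,
       trace = data.frame(iteration = seq_len(it), value = tr_val[seq_len(it)],
                          radius = tr_rad[seq_len(it)],
                          accepted = tr_acc[seq_len(it)]))
}

# Smooth + subsample a volume for one pyramid level (shrink >= 1).
pyramid_level <- function(vol, shrink, sigma) {
  if (shrink == 1 && sigma <= 0) return(vol)
  d <- dim(vol$intensity)
  x <- cpp_blur3(as.vector(vol$intensity), d, rep(sigma, 3))
  x <- array(x, d)
  ix <- seq(1, d[1], by = shrink); iy <- seq(1, d[2], by = shrink)
  iz <- seq(1, d[3], by = shrink)
  doppler_volume(x[ix, iy, iz, drop = FALSE], vol$spacing * shrink,
                 vol$origin_mm, vol$axes)
}

# Per-parameter conditioning of the 12-dim affine search space: 0.1 rad of
# rotation, 0.1 log-scale and 0.1 shear are treated as comparable to 1 mm of
# translation (1 rad ~ 10 mm).
affine_param_scales <- function() c(rep(0.1, 3), rep(0.1, 3), rep(0.1, 3), rep(1, 3))

# Intensity centre of mass in world coordinates.
volume_centroid <- function(vol) {
  w <- as.vector(vol$intensity)
  s <- sum(w)
  if (s <= 0) return(vol$origin_mm + (dim(vol$intensity) - 1) / 2 * vol$spacing)
  as.vector(t(grid_points(grid_of(vol))) %*% w / s)
}

#' Affine registration of a Doppler volume to a reference
#'
#' Maximizes Mattes mutual information over 12 affine parameters (rotations,
#' log-scales, shears, translations; rotation centre at the fixed volume's
#' centre) with a (1+1) evolution strategy, coarse-to-fine over a Gaussian
#' pyramid. The returned transform maps moving-space world coordinates into
#' fixed space.
#'
#' @param moving,fixed [doppler_volume()]s normalized to \[0, 1\].
#' @param config an [mi_config()].
#' @param init `"centroid"` initializes the translation from the intensity
#'   centres of mass; `"identity"` starts from zero.
#' @return list(transform = [affine3d()], mi = final MI in nats,
#'   levels = per-level optimizer summaries).
#' @export
register_affine <- function(moving, fixed, config = mi_config(),
                            init = c("centroid", "identity")) {
  init <- match.arg(init)
  stopifnot(inherits(moving, "doppler_volume"), inherits(fixed, "doppler_volume"))
  center <- fixed$origin_mm + (dim(fixed$intensity) - 1) / 2 * fixed$spacing
  p <- rep(0, 12)
  if (init == "centroid")
    p[10:12] <- volume_centroid(fixed) - volume_centroid(moving)
  p_init <- p
  scales <- affine_param_scales()
  shrinks <- 2^((config$pyramid_levels - 1):0)
  sigmas <- shrinks / 2
  sigmas[shrinks == 1] <- 0
  max_shrink <- max(1, floor(min(dim(fixed$intensity)) / 8))
  levels <- list()
  started <- FALSE
  best_val <- Inf
  obj <- NULL
  for (li in seq_along(shrinks)) {
    s <- min(shrinks[li], max_shrink)
    f_l <- pyramid_level(fixed, s, sigmas[li])
    m_l <- pyramid_level(moving, s, sigmas[li])
    obj <- local({
      f_l <- f_l; m_l <- m_l
      function(u) {
        tr <- affine_from_params(u * scales, center)
        tryCatch(-mattes_mi(f_l, m_l, tr, config),
                 fusbps_overlap_error = function(e) Inf)
      }
    })
    u0 <- p / scales
    if (!is.finite(obj(u0))) {
      levels[[li]] <- list(shrink = s, skipped = TRUE)
      next
    }
    started <- TRUE
    res <- one_plus_one_es(obj, u0,
                           params = list(initial_radius = config$initial_radius,
                                         growth_factor = config$growth_factor,
                                         epsilon = config$epsilon,
                                         max_iterations = config$max_iterations),
                           seed = config$seed + li)
    p <- res$par * scales
    best_val <- res$value
    levels[[li]] <- list(shrink = s, mi = -res$value,
                         iterations = res$iterations)
  }
  if (started && (config$polish_iterations %||% 0) > 0) {
    nm <- stats::optim(p / scales, obj, method = "Nelder-Mead",
                       control = list(maxit = config$polish_iterations))
    if (is.finite(nm$value) && nm$value < best_val) p <- nm$par * scales
  }
  if (!started)
    stop(errorCondition("registration failure: degenerate overlap at every pyramid level",
                        class = c("fusbps_registration_failure", "error")))
  full_mi <- function(par) {
    tryCatch(mattes_mi(fixed, moving, affine_from_params(par, center), config),
             fusbps_overlap_error = function(e) -Inf)
  }
  final_mi <- full_mi(p)
  init_mi <- full_mi(p_init)
  if (init_mi > final_mi) { # never report worse than the starting point
    p <- p_init
    final_mi <- init_mi
  }
  list(transform = affine_from_params(p, center), mi = final_mi,
       levels = levels)
}

#' Normalized 3D cross-correlation of two volumes
#'
#' Zero-mean, globally unit-normalized cross-correlation over all integer
#' voxel lags (FFT accelerated). The autocorrelation of any volume equals 1
#' at zero lag.
#'
#' @param a,b [doppler_volume()]s with identical spacing.
#' @return An `xcorr3` object: `corr` lag array and `lag_mm` per-axis lag
#'   coordinates (lag is the shift of `b` relative to `a` in mm).
#' @export
normalized_xcorr3 <- function(a, b) {
  stopifnot(inherits(a, "doppler_volume"), inherits(b, "doppler_volume"))
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop_param("volumes must share voxel spacing")
  za <- a$intensity - mean(a$intensity)
  zb <- b$intensity - mean(b$intensity)
  na_ <- sqrt(sum(za^2)); nb_ <- sqrt(sum(zb^2))
  if (na_ == 0 || nb_ == 0)
    stop_param("constant input: cross-correlation normalization undefined")
  da <- dim(za); db <- dim(zb)
  nout <- da + db - 1
  nfft <- vapply(nout, stats::nextn, 1, factors = c(2, 3, 5))
  pa <- array(0, nfft); pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- za
  pb <- array(0, nfft); pb[seq_len(db[1]), seq_len(db[2]), seq_len(db[3])] <- zb
  # cc at circular index l (0-based) = sum_y b(y + l) a(y): peaks at the
  # displacement of b relative to a
  cc <- Re(fft(fft(pb) * Conj(fft(pa)), inverse = TRUE)) / prod(nfft)
  reorder <- function(n_neg, n_pos, nfft_ax) {
    c(nfft_ax - (n_neg:1) + 1, 1:(n_pos + 1)) # R 1-based indices
  }
  ix <- reorder(da[1] - 1, db[1] - 1, nfft[1])
  iy <- reorder(da[2] - 1, db[2] - 1, nfft[2])
  iz <- reorder(da[3] - 1, db[3] - 1, nfft[3])
  corr <- cc[ix, iy, iz, drop = FALSE] / (na_ * nb_)
  lag_mm <- lapply(1:3, function(ax) {
    (-(da[ax] - 1):(db[ax] - 1)) * a$spacing[ax]
  })
  structure(list(corr = corr, lag_mm = lag_mm, spacing = a$spacing),
            class = "xcorr3")
}

#' Peak metrics of a cross-correlation volume
#'
#' Peak value, peak lag and full width at half maximum of the axis profiles
#' through the peak (half crossings linearly interpolated). The peak is the
#' first global maximum in scan order; an axis whose profile never crosses
#' the half maximum inside the lag range gets `NA` width.
#'
#' @param xc an `xcorr3` from [normalized_xcorr3()].
#' @return list(peak_value, peak_lag_mm, fwhm_mm).
#' @export
xcorr_metrics <- function(xc) {
  stopifnot(inherits(xc, "xcorr3"))
  k <- which.max(xc$corr)
  d <- dim(xc$corr)
  kx <- (k - 1) %% d[1] + 1
  ky <- ((k - 1) %/% d[1]) %% d[2] + 1
  kz <- (k - 1) %/% (d[1] * d[2]) + 1
  peak <- xc$corr[kx, ky, kz]
  half <- peak / 2
  fwhm1 <- function(prof, lags, center) {
    cross <- function(idx_seq) { # walk outward, interpolate the crossing
      for (j in idx_seq) {
        if (prof[j] <= half) {
          prev <- j + sign(center - j)
          frac <- (prof[prev] - half) / (prof[prev] - prof[j])
          return(lags[prev] + frac * (lags[j] - lags[prev]))
        }
      }
      NA_real_
    }
    left <- if (center > 1) cross((center - 1):1) else NA_real_
    right <- if (center < length(prof)) cross((center + 1):length(prof)) else NA_real_
    right - left
  }
  fwhm <- c(fwhm1(xc$corr[, ky, kz], xc$lag_mm[[1]], kx),
            fwhm1(xc$corr[kx, , kz], xc$lag_mm[[2]], ky),
            fwhm1(xc$corr[kx, ky, ], xc$lag_mm[[3]], kz))
  list(peak_value = peak,
       peak_lag_mm = c(xc$lag_mm[[1]][kx], xc$lag_mm[[2]][ky],
                       xc$lag_mm[[3]][kz]),
       fwhm_mm = fwhm)
}

#' Named vascular landmark set
#'
#' @param entries N x 3 matrix of world coordinates (mm) with unique row
#'   names (e.g. VL1..VL4).
#' @return A `landmark_set`.
#' @export
landmark_set <- function(entries) {
  entries <- as.matrix(entries)
  stopifnot(ncol(entries) == 3, all(is.finite(entries)))
  if (is.null(rownames(entries)) || anyDuplicated(rownames(entries)))
    stop_param("landmark entries need unique names")
  colnames(entries) <- c("x_mm", "y_mm", "z_mm")
  structure(list(entries = entries), class = "landmark_set")
}

#' Landmark discrepancy between two annotations
#'
#' 3D Euclidean distance shift per shared landmark, with the mean and
#' standard deviation across landmarks, in micrometres.
#'
#' @param a,b [landmark_set()]s sharing at least one name.
#' @return list(per_landmark_um named vector, mean_um, sd_um).
#' @export
landmark_discrepancy <- function(a, b) {
  stopifnot(inherits(a, "landmark_set"), inherits(b, "landmark_set"))
  shared <- intersect(rownames(a$entries), rownames(b$entries))
  if (!length(shared)) stop_param("no shared landmark names")
  d <- sqrt(rowSums((a$entries[shared, , drop = FALSE] -
                       b$entries[shared, , drop = FALSE])^2)) * 1000
  list(per_landmark_um = d, mean_um = mean(d),
       sd_um = if (length(d) > 1) sd(d) else 0)
}

#' Write / read landmarks as CSV (`name,x_mm,y_mm,z_mm`)
#'
#' @param landmarks a [landmark_set()].
#' @param path CSV path.
#' @return `read_landmarks` returns the [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  df <- data.frame(name = rownames(landmarks$entries), landmarks$entries,
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path)
  need <- c("name", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("malformed landmark CSV at ", path, ": need columns ",
         paste(need, collapse = ","))
  m <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- df$name
  landmark_set(m)
}

#' Random rigid+scale perturbation
#'
#' Draws a transform with uniformly random rotation axis and angle up to
#' `max_rotation_deg`, per-axis scales in `scale_range`, and a translation of
#' magnitude up to `max_translation_mm` in a random direction, centred on
#' `center`. Used to perturb phantom volumes with a known ground truth.
#'
#' @param seed RNG seed.
#' @param max_translation_mm,max_rotation_deg,scale_range perturbation
#'   bounds.
#' @param center rotation/scaling centre, mm.
#' @return An [affine3d()].
#' @export
random_affine_perturbation <- function(seed, max_translation_mm = 1,
                                       max_rotation_deg = 10,
                                       scale_range = c(0.95, 1.05),
                                       center = c(0, 0, 0)) {
  with_seed(seed, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0, max_rotation_deg) * pi / 180
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    S <- diag(runif(3, scale_range[1], scale_range[2]))
    td <- rnorm(3); td <- td / sqrt(sum(td^2))
    t_mm <- td * runif(1, 0, max_translation_mm)
    affine3d(R %*% S, t_mm, center)
  })
}

#' Registration parameter-recovery study on phantom pairs
#'
#' For each pair, a seeded vascular phantom is rasterized, a copy is moved
#' by a random rigid+scale perturbation (resampled through it), and the
#' registration is asked to undo it; the applied transform is the ground
#' truth. Reported errors are the translation of the residual map
#' (recovered composed with applied, evaluated at the volume centre) and
#' its rotation angle.
#'
#' @param n_pairs number of phantom pairs.
#' @param seed study seed (pair k uses seeds derived from it).
#' @param dim,spacing phantom grid (defaults 64 x 48 x 32 at
#'   0.1/0.1/0.2 mm).
#' @param snr rasterization SNR.
#' @param config an [mi_config()].
#' @param max_translation_mm,max_rotation_deg,scale_range perturbation
#'   bounds (see [random_affine_perturbation()]).
#' @return data frame with per-pair translation error (mm, per axis and
#'   norm) and rotation error (deg).
#' @export
registration_recovery <- function(n_pairs = 20, seed = 1,
                                  dim = c(64, 48, 32),
                                  spacing = c(0.1, 0.1, 0.2), snr = 20,
                                  config = mi_config(),
                                  max_translation_mm = 1,
                                  max_rotation_deg = 10,
                                  scale_range = c(0.95, 1.05)) {
  ext <- (dim - 1) * spacing
  center <- ext / 2
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    sk <- seed + 1000 * k
    tree <- generate_vessel_tree(sk, vessel_tree_params(extent_mm = ext))
    fixed <- normalize_for_registration(
      rasterize_doppler_volume(tree, spacing, snr, seed = sk + 1))
    T_true <- random_affine_perturbation(sk + 3, max_translation_mm,
                                         max_rotation_deg, scale_range,
                                         center)
    moving <- resample_volume(fixed, T_true)
    cfg <- config; cfg$seed <- sk
    reg <- register_affine(moving, fixed, cfg)
    resid <- compose_transforms(reg$transform, T_true) # ideally identity
    terr <- abs(apply_affine(resid, center) - center)
    out[[k]] <- data.frame(pair = k,
                           tx_err_mm = terr[1], ty_err_mm = terr[2],
                           tz_err_mm = terr[3],
                           t_err_mm = sqrt(sum(terr^2)),
                           rot_err_deg = rotation_angle(resid),
                           mi = reg$mi)
  }
  do.call(rbind, out)
}
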