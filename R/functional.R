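# Task-evoked activation mapping (GLM Z-scores, Bonferroni) and
# resting-state connectivity (zero-phase low-pass, seed maps, ROI Pearson
# matrices).

#' Block stimulation pattern
#'
#' A baseline followed by `n_trials` ON/OFF trials; the standard protocol is
#' 30 s baseline + 3 x (30 s ON / 30 s OFF) = 210 s.
#'
#' @param baseline_s,on_s,off_s durations, seconds (`>= 0`).
#' @param n_trials number of trials.
#' @return A `stimulus_pattern` with `total_s`.
#' @export
stimulus_pattern <- function(baseline_s = 30, n_trials = 3, on_s = 30,
                             off_s = 30) {
  stopifnot(baseline_s >= 0, on_s >= 0, off_s >= 0, n_trials >= 0)
  structure(list(baseline_s = baseline_s, n_trials = n_trials, on_s = on_s,
                 off_s = off_s,
                 total_s = baseline_s + n_trials * (on_s + off_s)),
            class = "stimulus_pattern")
}

#' GLM design matrix for a stimulation protocol
#'
#' Intercept plus a boxcar regressor sampled at the Doppler frame times
#' `t = 0, 1/rate, ...` over the protocol duration. The regressor is 1
#' during ON periods and 0 elsewhere; an optional gamma-kernel convolution
#' models the hemodynamic delay (off by default: cerebral blood volume
#' follows the stimulus closely at these time scales).
#'
#' @param stimulus a [stimulus_pattern()].
#' @param rate sampling rate, Hz.
#' @param convolve_hrf convolve the boxcar with a gamma kernel.
#' @param hrf_shape,hrf_scale gamma kernel parameters (seconds).
#' @return time x 2 matrix (intercept, regressor).
#' @export
build_design <- function(stimulus, rate, convolve_hrf = FALSE,
                         hrf_shape = 3, hrf_scale = 0.5) {
  stopifnot(inherits(stimulus, "stimulus_pattern"))
  check_positive(rate, "rate")
  if (stimulus$total_s <= 0) stop_param("zero-duration stimulus")
  n <- round(stimulus$total_s * rate)
  t_s <- (seq_len(n) - 1) / rate
  reg <- numeric(n)
  if (stimulus$n_trials > 0 && stimulus$on_s > 0) {
    period <- stimulus$on_s + stimulus$off_s
    for (k in seq_len(stimulus$n_trials) - 1) {
      on0 <- stimulus$baseline_s + k * period
      reg[t_s >= on0 & t_s < on0 + stimulus$on_s] <- 1
    }
  }
  if (convolve_hrf) {
    tk <- seq(0, 10, by = 1 / rate)
    kern <- stats::dgamma(tk, shape = hrf_shape, scale = hrf_scale)
    kern <- kern / sum(kern)
    reg <- stats::convolve(reg, rev(kern), type = "open")[seq_len(n)]
  }
  cbind(intercept = rep(1, n), regressor = reg)
}

#' Per-voxel GLM Z-scores
#'
#' Ordinary least squares of every voxel time course on the design;
#' `t = beta1 / SE(beta1)` is mapped to a Z-score through the t-distribution
#' function (`z = qnorm(pt(t, df))`), capped at `z_max`. Zero-variance
#' voxels get z = 0.
#'
#' @param series voxel x time matrix.
#' @param design time x p design matrix (full rank; column 2 is the tested
#'   regressor).
#' @param z_max cap on |z| (noise-free fits would otherwise overflow).
#' @return Numeric vector of Z-scores (one per voxel), with attribute `df`.
#' @export
glm_zscores <- function(series, design, z_max = 38) {
  X <- as.matrix(design)
  series <- as.matrix(series)
  if (ncol(series) != nrow(X))
    stop_param("time dimension mismatch: series has ", ncol(series),
               " samples, design ", nrow(X), " rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_param("rank-deficient design")
  df <- nrow(X) - ncol(X)
  XtXi <- chol2inv(qr.R(qrX))
  B <- series %*% X %*% XtXi # voxel x p (since (X'X)^-1 X' Y')' = Y X (X'X)^-1
  resid <- series - B %*% t(X)
  rss <- rowSums(resid^2)
  # voxels whose residuals vanish to numerical precision are noise-free
  zerovar <- rss <= 1e-16 * pmax(rowSums(series^2), .Machine$double.xmin)
  beta_zero <- abs(B[, 2]) <= 1e-8 * sqrt(pmax(rowSums(series^2), 0) / nrow(X))
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXi[2, 2])
  tval <- B[, 2] / se
  z <- numeric(length(tval))
  pos <- is.finite(tval) & tval >= 0
  neg <- is.finite(tval) & tval < 0
  # tail-stable t -> z mapping
  z[pos] <- -qnorm(pt(tval[pos], df, lower.tail = FALSE, log.p = TRUE),
                   log.p = TRUE)
  z[neg] <- qnorm(pt(tval[neg], df, lower.tail = TRUE, log.p = TRUE),
                  log.p = TRUE)
  z[!is.finite(tval)] <- 0
  z[zerovar & !beta_zero & B[, 2] > 0] <- z_max
  z[zerovar & !beta_zero & B[, 2] < 0] <- -z_max
  z[zerovar & beta_zero] <- 0
  z <- pmin(pmax(z, -z_max), z_max)
  attr(z, "df") <- df
  attr(z, "n_zero_variance") <- sum(zerovar)
  z
}

#' Bonferroni-corrected per-voxel threshold
#'
#' Divides the family-wise alpha by the number of voxels tested; with
#' alpha = 0.05 over 5000 voxels the per-voxel level is 1e-5.
#'
#' @param alpha family-wise error level.
#' @param n_voxels number of tests.
#' @return Per-voxel p threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_voxels) {
  if (n_voxels < 1) stop_param("n_voxels must be >= 1")
  stopifnot(alpha > 0, alpha <= 1)
  alpha / n_voxels
}

#' Activation map from Z-scores
#'
#' Two-sided test of each voxel's Z-score at `p_threshold`.
#'
#' @param z Z-score vector or grid (from [glm_zscores()]).
#' @param p_threshold per-voxel p threshold (see [bonferroni_threshold()]).
#' @return list(z, p_threshold, significant logical, z_threshold).
#' @export
activation_map <- function(z, p_threshold) {
  zt <- qnorm(1 - p_threshold / 2)
  list(z = z, p_threshold = p_threshold, significant = abs(z) >= zt,
       z_threshold = zt)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase lag, DC
#' gain 1) with reflection padding at the ends, row-wise over a series
#' matrix. A 0.1 Hz cutoff isolates the spontaneous low-frequency CBV
#' fluctuations used for connectivity.
#'
#' @param series voxel-or-ROI x time matrix (or a single vector).
#' @param cutoff cutoff frequency, Hz (`< rate/2`).
#' @param rate sampling rate, Hz.
#' @param order filter order.
#' @return Filtered series, same shape.
#' @export
lowpass <- function(series, cutoff = 0.1, rate = 2.5, order = 4) {
  check_positive(cutoff, "cutoff")
  if (cutoff >= rate / 2)
    stop_param("cutoff (", cutoff, " Hz) must be below Nyquist (", rate / 2, " Hz)")
  bt <- signal::butter(order, cutoff / (rate / 2), type = "low")
  filt1 <- function(x) {
    n <- length(x)
    p <- min(n - 1, 400)
    xe <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    y <- signal::filter(bt, xe)
    y <- rev(signal::filter(bt, rev(y)))
    y[(p + 1):(p + n)]
  }
  if (is.null(dim(series))) return(filt1(series))
  t(apply(series, 1, filt1))
}

#' Seed-based correlation map
#'
#' Pearson correlation of the seed-mean signal with every voxel (seed voxels
#' included, so a one-voxel seed reports r = 1 on itself).
#'
#' @param series voxel x time matrix (already low-pass filtered upstream).
#' @param seed_mask logical vector/grid over voxels.
#' @return Numeric vector of r per voxel (NA for zero-variance voxels),
#'   shaped like `seed_mask` when it is an array.
#' @export
seed_correlation_map <- function(series, seed_mask) {
  mask <- as.vector(seed_mask) > 0
  if (!any(mask)) stop_param("empty seed")
  series <- as.matrix(series)
  seed <- colMeans(series[mask, , drop = FALSE])
  if (sd(seed) == 0) stop_param("zero-variance seed signal")
  r <- suppressWarnings(as.vector(cor(t(series), seed)))
  if (!is.null(dim(seed_mask))) r <- array(r, dim(seed_mask))
  r
}

#' ROI connectivity matrix
#'
#' Pairwise Pearson correlation between ROI time series (symmetric, unit
#' diagonal).
#'
#' @param roi_signals ROI x time matrix with ROI rownames.
#' @return A `connectivity_matrix`: list(r, roi_ids).
#' @export
connectivity_matrix <- function(roi_signals) {
  roi_signals <- as.matrix(roi_signals)
  if (nrow(roi_signals) < 2) stop_param("need at least 2 ROIs")
  sds <- apply(roi_signals, 1, sd)
  if (any(sds == 0)) {
    bad <- rownames(roi_signals)[sds == 0] %||% which(sds == 0)
    stop_param("constant ROI signal: ", paste(bad, collapse = ", "))
  }
  r <- cor(t(roi_signals))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(r = r, roi_ids = rownames(roi_signals) %||%
                   as.character(seq_len(nrow(roi_signals)))),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x$r), " ROIs, mean |off-diagonal r| = ",
      format(mean(abs(x$r[upper.tri(x$r)])), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Fisher confidence interval for a Pearson correlation
#'
#' @param r observed correlation.
#' @param n sample count.
#' @param level confidence level.
#' @return c(lower, upper) on the r scale.
#' @export
fisher_ci <- function(r, n, level = 0.99) {
  z <- atanh(r)
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}
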