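# Shared oracles and fixture builders, all generated in code at test time.

# Independent trilinear interpolation of a 3D array at one continuous
# 0-based index (straight from the textbook formula, no shared code with
# the C++ sampler).
trilinear_oracle <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  if (ix < 0 || iy < 0 || iz < 0 || ix > d[1] - 1 || iy > d[2] - 1 ||
      iz > d[3] - 1) return(0)
  x0 <- min(floor(ix), d[1] - 2); y0 <- min(floor(iy), d[2] - 2)
  z0 <- min(floor(iz), d[3] - 2)
  x0 <- max(x0, 0); y0 <- max(y0, 0); z0 <- max(z0, 0)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    acc <- acc + w * arr[x0 + dx + 1, y0 + dy + 1, z0 + dz + 1]
  }
  acc
}

# Hard-binned joint-histogram mutual information (nats): the brute-force
# oracle for the Parzen metric on bin-centred data.
hard_mi_oracle <- function(fvals, mvals, nbins) {
  bin_of <- function(v) {
    vmin <- min(v); vmax <- max(v)
    w <- if (vmax > vmin) (vmax - vmin) / (nbins - 1) else 1
    pmin(pmax(round((v - vmin) / w), 0), nbins - 1)
  }
  tab <- table(factor(bin_of(fvals), levels = 0:(nbins - 1)),
               factor(bin_of(mvals), levels = 0:(nbins - 1)))
  P <- tab / sum(tab)
  pf <- rowSums(P); pm <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log(P[nz] / (pf[row(P)[nz]] * pm[col(P)[nz]])))
}

# Naive R implementation of the Parzen joint histogram (identity transform,
# matched grids): dual route for the C++ accumulation path.
parzen_joint_oracle <- function(fvals, mvals, nbins, kernel = "linear") {
  bins <- function(v) {
    vmin <- min(v); vmax <- max(v)
    list(min = vmin, w = if (vmax > vmin) (vmax - vmin) / (nbins - 1) else 1)
  }
  fb <- bins(fvals); mb <- bins(mvals)
  fbin <- pmin(pmax(round((fvals - fb$min) / fb$w), 0), nbins - 1)
  joint <- matrix(0, nbins, nbins)
  bsp3 <- function(t) {
    a <- abs(t)
    ifelse(a >= 2, 0, ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6, (2 - a)^3 / 6))
  }
  for (i in seq_along(fvals)) {
    b <- (mvals[i] - mb$min) / mb$w
    if (kernel == "linear") {
      b0 <- floor(b); w1 <- b - b0
      ks <- c(b0, b0 + 1); ws <- c(1 - w1, w1)
    } else {
      ks <- floor(b) + (-1:2); ws <- bsp3(b - ks)
    }
    for (j in seq_along(ks)) {
      kk <- min(max(ks[j], 0), nbins - 1)
      joint[fbin[i] + 1, kk + 1] <- joint[fbin[i] + 1, kk + 1] + ws[j]
    }
  }
  joint
}

mi_of_joint <- function(joint) {
  P <- joint / sum(joint)
  pf <- rowSums(P); pm <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log(P[nz] / (pf[row(P)[nz]] * pm[col(P)[nz]])))
}

# Volume with intensities on the 50 bin centres (levels k/(nbins-1)).
bin_centred_volume <- function(dim, nbins = 50, seed = 1, spacing = c(0.1, 0.1, 0.1)) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  vals <- withr_seed(sample(0:(nbins - 1), prod(dim), replace = TRUE))
  v <- array(vals / (nbins - 1), dim)
  v[1] <- 0; v[2] <- 1 # pin the range so bin centres stay exact
  doppler_volume(v, spacing)
}

# Brute-force minimum assignment cost by permutation enumeration (n <= 7).
perms <- function(n) {
  if (n == 1) return(matrix(1))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(p >= k, p + 1, p))
  }))
}

brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  pm <- perms(n)
  costs <- apply(pm, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(min_cost = min(costs), perm = pm[which.min(costs), ])
}

# Small smooth test volume (sum of Gaussian blobs) for resampling tests.
blob_volume <- function(dim = c(12, 10, 8), spacing = c(0.1, 0.1, 0.1),
                        seed = 1) {
  set.seed(seed)
  ax <- lapply(1:3, function(a) (seq_len(dim[a]) - 1) * spacing[a])
  v <- array(0, dim)
  for (k in 1:4) {
    c0 <- sapply(1:3, function(a) runif(1, 0.2, 0.8) * max(ax[[a]]))
    s0 <- runif(1, 0.1, 0.25)
    v <- v + exp(-(outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2, `+`),
                         (ax[[3]] - c0[3])^2, `+`)) / (2 * s0^2))
  }
  doppler_volume(v / max(v), spacing)
}

blur2d_for_test <- function(img, sigma) fusbps:::blur2(img, sigma)
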