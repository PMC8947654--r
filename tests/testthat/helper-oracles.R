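# Brute-force reference implementations, deliberately independent of the
# package's computational kernels: plain R loops over voxels.

# trilinear interpolation of arr (0-based continuous voxel coords), zero fill
trilinear_oracle <- function(arr, pts) {
  d <- dim(arr)
  get <- function(i, j, k) {
    if (i < 0 || j < 0 || k < 0 || i >= d[1] || j >= d[2] || k >= d[3]) 0
    else arr[i + 1, j + 1, k + 1]
  }
  apply(pts, 1, function(p) {
    f <- floor(p); fr <- p - f
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) fr[1] else 1 - fr[1]) *
           (if (dy) fr[2] else 1 - fr[2]) *
           (if (dz) fr[3] else 1 - fr[3])
      acc <- acc + w * get(f[1] + dx, f[2] + dy, f[3] + dz)
    }
    acc
  })
}

# direct (non-separable) zero-padded convolution with a 3-D Gaussian kernel
gauss3_conv_oracle <- function(arr, sigma_vox) {
  d <- dim(arr)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  kw <- exp(-(off$dx^2 + off$dy^2 + off$dz^2) / (2 * sigma_vox^2))
  kw <- kw / sum(kw)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    acc <- 0
    for (t in seq_len(nrow(off))) {
      ii <- i + off$dx[t]; jj <- j + off$dy[t]; kk <- k + off$dz[t]
      if (ii >= 1 && jj >= 1 && kk >= 1 && ii <= d[1] && jj <= d[2] &&
          kk <= d[3])
        acc <- acc + kw[t] * arr[ii, jj, kk]
    }
    out[i, j, k] <- acc
  }
  out
}

# two-way ANOVA mean squares from explicit elementwise sums
icc_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - grand)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse,
       consistency = (msr - mse) / (msr + (k - 1) * mse),
       absolute = (msr - mse) /
         (msr + (k - 1) * mse + k / n * (msc - mse)))
}

# partial-volume-weighted marginal entropy (nats), mirroring the binning
# contract but built separately in R
entropy_pv_oracle <- function(x, n_bins) {
  r <- range(x)
  pos <- (x - r[1]) / (r[2] - r[1]) * (n_bins - 1)
  pos <- pmin(pos, n_bins - 1 - 1e-12)
  i0 <- floor(pos); fr <- pos - i0
  h <- numeric(n_bins)
  for (t in seq_along(x)) {
    h[i0[t] + 1] <- h[i0[t] + 1] + (1 - fr[t])
    h[i0[t] + 2] <- h[i0[t] + 2] + fr[t]
  }
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p))
}

# small axis-aligned test volume with a given spacing/origin
toy_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- origin
  as_volume(values, aff)
}

toy_scheme <- function() {
  region_scheme(tibble::tibble(
    label_id = 1:6,
    parcel_name = c("f", "c", "p", "t", "s", "pons"),
    composite = c("frontal", "cingulate", "parietal", "temporal", "striatum",
                  ""),
    reference = c(rep(FALSE, 5), TRUE)))
}

# maximum rotation (deg) and world-mapping (mm) discrepancy between transforms
transform_errors <- function(t_est, t_true, radius = 40) {
  rot_err <- max(abs(t_est$rotations - t_true$rotations)) * 180 / pi
  A <- transform_matrix(t_true); B <- transform_matrix(t_est)
  pts <- rbind(c(0, 0, 0), diag(3) * radius, -diag(3) * radius)
  map_err <- max(apply(pts, 1, function(p)
    sqrt(sum(((A - B) %*% c(p, 1))[1:3]^2))))
  c(rot_deg = rot_err, map_mm = map_err)
}
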