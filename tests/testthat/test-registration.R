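smooth_blob <- function(n = 48, seed = 30) {
  # smooth anisotropic blob with internal structure: well-posed MI target
  set.seed(seed)
  c0 <- (n - 1) / 2
  x <- (seq_len(n) - 1 - c0)
  X <- array(x, rep(n, 3))
  Y <- array(rep(x, each = n), rep(n, 3))
  Z <- array(rep(x, each = n * n), rep(n, 3))
  r2 <- (X / (0.33 * n))^2 + (Y / (0.42 * n))^2 + (Z / (0.38 * n))^2
  vals <- 100 * exp(-r2) * (1 + 0.4 * sin(X / 4) * cos(Y / 5)) +
    20 * (r2 < 0.2)
  toy_volume(vals, origin = -rep(c0, 3))
}

test_that("self mutual information equals the marginal entropy", {
  # values quantised to the bin centres, so the partial-volume weighting
  # reduces to hard binning and I(X;X) = H(X) exactly
  v <- smooth_blob(32)
  r <- range(v$values)
  cfg <- mi_config(pyramid = 1)
  q <- round((v$values - r[1]) / (r[2] - r[1]) * (cfg$n_bins - 1))
  vq <- toy_volume(q)
  mi <- mutual_information(vq, vq, rigid_transform(), cfg)
  h <- entropy_pv_oracle(as.double(vq$values), cfg$n_bins)
  expect_equal(mi, h, tolerance = 1e-8)
})

test_that("independent noise volumes carry (almost) no mutual information", {
  set.seed(31)
  a <- toy_volume(array(stats::rnorm(64^3), c(64, 64, 64)))
  b <- toy_volume(array(stats::rnorm(64^3), c(64, 64, 64)))
  mi <- mutual_information(a, b, rigid_transform(), mi_config(n_bins = 32))
  expect_gte(mi, 0)
  expect_lt(mi, 0.05)
})

test_that("mutual information is invariant to intensity rescaling", {
  v <- smooth_blob(32)
  w <- smooth_blob(32, seed = 32)
  t0 <- rigid_transform(c(0, 0, 0.05), c(1, -2, 0.5))
  m1 <- mutual_information(v, w, t0)
  w2 <- w; w2$values <- 3.7 * w$values - 11
  expect_equal(mutual_information(v, w2, t0), m1, tolerance = 1e-10)
  v2 <- v; v2$values <- 0.2 * v$values + 5
  expect_equal(mutual_information(v2, w, t0), m1, tolerance = 1e-10)
})

test_that("resampling through transforms behaves on the lattice", {
  v <- smooth_blob(32)
  same <- resample_moving(v, rigid_transform(), v)
  expect_equal(same$values, v$values, tolerance = 1e-12)

  # integer-voxel translation is an exact shifted copy in the overlap
  sh <- resample_moving(v, rigid_transform(translation = c(4, 0, 0)), v)
  expect_equal(sh$values[1:28, , ], v$values[5:32, , ], tolerance = 1e-12)

  # t then t^-1 returns within interpolation error on a smooth volume
  t1 <- rigid_transform(c(0.04, -0.03, 0.08), c(2.3, -1.1, 0.7),
                        center = c(0, 0, 0))
  fwd <- resample_moving(v, t1, v)
  back <- resample_moving(fwd, invert_transform(t1), v)
  core <- as.double(back$values[5:28, 5:28, 5:28] -
                      v$values[5:28, 5:28, 5:28])
  rng <- diff(range(v$values))
  expect_lt(mean(abs(core)), 0.02 * rng)
})

test_that("self-registration returns the identity", {
  v <- smooth_blob(48)
  reg <- register_rigid(v, v, mi_config(pyramid = c(2, 1), max_iter = 30))
  expect_true(reg$converged)
  expect_lt(max(abs(reg$transform$rotations)) * 180 / pi, 0.1)
  expect_lt(max(abs(reg$transform$translation)), 0.1)
})

test_that("known misalignments are recovered on the phantom", {
  # coarse-grid sanity bounds: at 64 mm cubes the MI optimum itself sits up
  # to about a degree off the truth; sub-half-degree recovery is checked at
  # the 96-cube working size in the end-to-end suite
  s <- generate_subject(phantom_spec(grid_size = c(64, 64, 64)))
  mri <- conform(s$mri)
  reg <- register_rigid(mri, s$pet)
  err <- transform_errors(reg$transform, s$truth_transform, radius = 28)
  expect_lt(err["rot_deg"], 2)
  expect_lt(err["map_mm"], 1)
  expect_gte(reg$mi, mutual_information(mri, s$pet, rigid_transform(
    center = reg$transform$center), mi_config()))

  # pure translation, no rotation
  s2 <- generate_subject(phantom_spec(grid_size = c(64, 64, 64),
                                      misalign_rot_deg = c(0, 0, 0),
                                      misalign_trans_mm = c(4, 0, 0)))
  reg2 <- register_rigid(conform(s2$mri), s2$pet)
  err2 <- transform_errors(reg2$transform, s2$truth_transform, radius = 28)
  expect_lt(max(abs(reg2$transform$rotations)) * 180 / pi, 0.2)
  expect_lt(err2["map_mm"], 0.5)
})

test_that("registration error decreases with SNR", {
  errs <- vapply(c(0.20, 0.08, 0.01), function(ns) {
    s <- generate_subject(phantom_spec(grid_size = c(48, 48, 48),
                                       noise_sd = ns, seed = 5))
    reg <- register_rigid(conform(s$mri), s$pet)
    transform_errors(reg$transform, s$truth_transform, radius = 20)["map_mm"]
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("empty overlap raises an error", {
  v <- smooth_blob(16)
  far <- rigid_transform(translation = c(1000, 0, 0))
  expect_error(mutual_information(v, v, far), "overlap")
})
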