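slab_labels <- function(n = 24, k = 3) {
  # k z-slabs tiling an n^3 grid, no background
  lab <- array(0L, c(n, n, n))
  edges <- round(seq(0, n, length.out = k + 1))
  for (s in seq_len(k)) lab[, , (edges[s] + 1):edges[s + 1]] <- s
  as_labelmap(lab)
}

test_that("psf model converts FWHM to sigma", {
  p <- psf_model(2)
  expect_equal(p$sigma, 2 / (2 * sqrt(2 * log(2))), tolerance = 1e-15)
  expect_equal(psf_model(0)$fwhm, 0)
  expect_error(psf_model(-1))
})

test_that("zero blur gives the identity omega and a no-op correction", {
  lab <- slab_labels(16)
  g <- build_gtm(lab, psf_model(0))
  expect_equal(g$omega, diag(3), ignore_attr = TRUE)
  pet <- toy_volume(array(stats::rnorm(16^3, 50, 5), c(16, 16, 16)))
  g <- gtm_correct(g, pet, lab)
  expect_equal(unname(g$corrected_means), unname(g$observed_means),
               tolerance = 1e-12)
})

test_that("well-separated regions do not cross-talk", {
  lab <- array(0L, c(40, 12, 12))
  lab[2:6, , ] <- 1L
  lab[35:39, , ] <- 2L
  lm <- as_labelmap(lab)
  g <- build_gtm(lm, psf_model(2), include_background = FALSE)
  expect_lt(max(abs(g$omega[row(g$omega) != col(g$omega)])), 1e-6)
})

test_that("omega matches the brute-force 3-D convolution oracle", {
  lab <- array(0L, c(14, 10, 10))
  lab[1:7, , ] <- 1L
  lab[8:14, , ] <- 2L
  lm <- as_labelmap(lab)
  psf <- psf_model(2)
  g <- build_gtm(lm, psf, include_background = FALSE)
  for (j in 1:2) {
    ind <- array(0, dim(lab)); ind[lab == j] <- 1
    sm <- gauss3_conv_oracle(ind, psf$sigma)
    for (i in 1:2)
      expect_equal(g$omega[i, j], mean(sm[lab == i]), tolerance = 1e-8)
  }
})

block_labels <- function(n = 30) {
  # 3 x 3 x 3 blocks tiling an n^3 grid; block 14 is interior to every face
  lab <- array(0L, c(n, n, n))
  e <- round(seq(0, n, length.out = 4))
  id <- 0L
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
    id <- id + 1L
    lab[(e[a] + 1):e[a + 1], (e[b] + 1):e[b + 1], (e[cc] + 1):e[cc + 1]] <- id
  }
  as_labelmap(lab)
}

test_that("omega rows are stochastic where regions tile the interior", {
  g <- build_gtm(block_labels(30), psf_model(2), include_background = FALSE)
  expect_true(all(g$omega >= 0 & g$omega <= 1))
  expect_true(all(rowSums(g$omega) <= 1 + 1e-9))
  # the centre block sits > 4*sigma from every grid face: row sums to 1
  expect_equal(rowSums(g$omega)[14], 1, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("GTM inverts its own forward model on the phantom", {
  s <- generate_subject(phantom_spec(grid_size = c(64, 64, 64), noise_sd = 0,
                                     misalign_rot_deg = c(0, 0, 0),
                                     misalign_trans_mm = c(0, 0, 0),
                                     pet_spacing = NULL))
  truth_means <- unname(s$uptake) * 100
  g <- gtm_correct(build_gtm(s$labels, psf_model(2)), s$pet, s$labels)
  est <- g$corrected_means[as.character(1:12)]
  expect_lt(max(abs(est - truth_means) / truth_means), 0.01)

  s5 <- generate_subject(phantom_spec(grid_size = c(64, 64, 64),
                                      noise_sd = 0.05,
                                      misalign_rot_deg = c(0, 0, 0),
                                      misalign_trans_mm = c(0, 0, 0),
                                      pet_spacing = NULL))
  g5 <- gtm_correct(build_gtm(s5$labels, psf_model(2)), s5$pet, s5$labels)
  est5 <- g5$corrected_means[as.character(1:12)]
  expect_lt(max(abs(est5 - truth_means) / truth_means), 0.05)
})

test_that("a uniform image over a tiling parcellation is a fixed point", {
  lab <- block_labels(30)
  pet <- toy_volume(array(7.5, c(30, 30, 30)))
  # with zero blur the fixed point is exact for every region
  g0 <- gtm_correct(build_gtm(lab, psf_model(0), include_background = FALSE),
                    pet, lab)
  expect_equal(unname(g0$corrected_means), rep(7.5, 27), tolerance = 1e-12)
  # with blur, observed stays uniform; corrected is uniform up to the mass
  # the face-adjacent blocks lose over the grid boundary
  g <- gtm_correct(build_gtm(lab, psf_model(2), include_background = FALSE),
                   pet, lab)
  expect_equal(unname(g$observed_means), rep(7.5, 27), tolerance = 1e-9)
  expect_equal(unname(g$corrected_means[14]), 7.5, tolerance = 0.01 * 7.5)
})

test_that("corrected-mean bias shrinks as the assumed FWHM approaches truth", {
  s <- generate_subject(phantom_spec(grid_size = c(48, 48, 48), noise_sd = 0,
                                     misalign_rot_deg = c(0, 0, 0),
                                     misalign_trans_mm = c(0, 0, 0),
                                     pet_spacing = NULL))
  truth_means <- unname(s$uptake) * 100
  bias <- vapply(c(0.5, 1.25, 2), function(f) {
    g <- gtm_correct(build_gtm(s$labels, psf_model(f)), s$pet, s$labels)
    max(abs(g$corrected_means[as.character(1:12)] - truth_means) /
          truth_means)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("gtm_correct flags singular and ill-conditioned systems", {
  lab <- slab_labels(16)
  g <- build_gtm(lab, psf_model(0))
  g$omega <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  pet <- toy_volume(array(1, c(16, 16, 16)))
  expect_error(gtm_correct(g, pet, lab), "singular|merge")
  g2 <- build_gtm(lab, psf_model(0))
  g2$condition_number <- 1e6
  expect_warning(gtm_correct(g2, pet, lab), "condition")
  expect_error(build_gtm(lab, psf_model(2), region_ids = c(1, 9)), "9")
})
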