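test_that("the generator is deterministic given a seed", {
  sp <- phantom_spec(grid_size = c(32, 32, 32))
  a <- generate_subject(sp)
  b <- generate_subject(sp)
  expect_identical(a$mri$values, b$mri$values)
  expect_identical(a$pet$values, b$pet$values)
  expect_identical(a$labels$values, b$labels$values)
  c <- generate_subject(phantom_spec(grid_size = c(32, 32, 32), seed = 2))
  expect_false(identical(a$pet$values, c$pet$values))
})

test_that("the analytic truth hits the requested global level exactly", {
  for (lev in c(0.50, 0.82)) {
    s <- generate_subject(phantom_spec(grid_size = c(32, 32, 32),
                                       global_level = lev))
    expect_equal(s$truth$global_suvr, lev, tolerance = 1e-12)
    # truth is recomputable from label counts and uptake alone
    st <- tibble::tibble(
      label_id = 1:12,
      mean = unname(s$uptake) * 100,
      volume_mm3 = tabulate(s$labels$values[s$labels$values > 0], 12) *
        voxel_volume(s$labels))
    re <- compute_suvr(st, s$scheme, 100)
    expect_equal(re$global_suvr, s$truth$global_suvr, tolerance = 1e-12)
    expect_equal(re$composites$suvr, s$truth$composites$suvr,
                 tolerance = 1e-12)
  }
})

test_that("the degenerate phantom passes through the pipeline exactly", {
  s <- generate_subject(phantom_spec(grid_size = c(48, 48, 48), noise_sd = 0,
                                     fwhm = 0, mri_noise_sd = 0,
                                     misalign_rot_deg = c(0, 0, 0),
                                     misalign_trans_mm = c(0, 0, 0),
                                     pet_spacing = NULL))
  res <- run_pipeline(s$mri, s$pet, s$labels, s$scheme,
                      pipeline_config(pvc = FALSE, register = FALSE))
  expect_true(res$ok)
  expect_equal(res$report$global_suvr, s$truth$global_suvr,
               tolerance = 1e-10)
})

test_that("phantom misconfiguration that empties a parcel errors", {
  expect_error(
    generate_subject(phantom_spec(grid_size = c(32, 32, 32),
                                  pons_radius_frac = 0.005)),
    "emptied")
})

test_that("phantom subjects serialise to NIfTI/JSON/TSV", {
  s <- generate_subject(phantom_spec(grid_size = c(32, 32, 32)))
  d <- withr::local_tempdir()
  write_phantom(s, d)
  expect_true(all(file.exists(file.path(d, c("mri.nii.gz", "pet.nii.gz",
                                             "labels.nii.gz", "scheme.tsv",
                                             "truth_transform.json",
                                             "truth_suvr.json")))))
  lab <- load_labelmap(file.path(d, "labels.nii.gz"))
  expect_identical(labels_present(lab), 1:12)
  tt <- read_transform(file.path(d, "truth_transform.json"))
  expect_equal(tt$rotations, s$truth_transform$rotations, tolerance = 1e-12)
})

test_that("cohort tables reproduce constructed offsets and separations", {
  # zero noise: Bland-Altman reproduces the configured biases exactly
  tb <- generate_cohort(n_neg = 10, n_pos = 10, noise = 0,
                        offsets = c(0, -0.04, 0.02), seed = 3)
  w <- tidyr::pivot_wider(tb[tb$region == "global",
                             c("subject_id", "method", "suvr")],
                          names_from = "method", values_from = "suvr")
  ba <- bland_altman(w$proposed, w$petsurfer)
  expect_equal(ba$mean_diff, 0.04, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0, tolerance = 1e-12)
  ba2 <- bland_altman(w$proposed, w$pmod)
  expect_equal(ba2$mean_diff, -0.02, tolerance = 1e-12)

  # zero noise and zero offsets: every pairwise ICC is 1
  tb0 <- generate_cohort(n_neg = 10, n_pos = 10, noise = 0,
                         offsets = c(0, 0, 0), seed = 4)
  w0 <- tidyr::pivot_wider(tb0[tb0$region == "global",
                               c("subject_id", "method", "suvr")],
                           names_from = "method", values_from = "suvr")
  for (pr in list(c("proposed", "petsurfer"), c("proposed", "pmod"),
                  c("petsurfer", "pmod")))
    expect_equal(icc(as.matrix(w0[, pr]), "absolute")$icc, 1,
                 tolerance = 1e-12)

  # default separations give a decisive group difference
  tb1 <- generate_cohort(n_neg = 100, n_pos = 100, seed = 5)
  gl <- tb1[tb1$region == "global" & tb1$method == "proposed", ]
  r <- welch_ttest(gl$suvr[gl$group == 1], gl$suvr[gl$group == 0])
  expect_lt(r$p_value, 0.001)

  # empirical group means stay within 3 standard errors of the targets
  m_neg <- mean(gl$suvr[gl$group == 0]); m_pos <- mean(gl$suvr[gl$group == 1])
  expect_lt(abs(m_neg - 0.50), 3 * 0.04 / sqrt(100) + 3 * 0.015 / sqrt(100))
  expect_lt(abs(m_pos - 0.82), 3 * 0.15 / sqrt(100) + 3 * 0.015 / sqrt(100))
})
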