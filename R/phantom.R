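#' Digital phantom specification
#'
#' Describes a synthetic subject: an ellipsoidal "brain" subdivided into ten
#' cortical sector parcels (two per amyloid composite), a deep white-matter
#' core, and a pons sphere, on an isotropic MRI grid. PET activity is
#' piecewise-constant regional uptake (as multiples of the pons value),
#' blurred by a Gaussian PSF, degraded with additive Gaussian noise, and
#' resampled onto a distinct anisotropic PET grid under a known rigid
#' misalignment — so conformation, registration and partial-volume correction
#' are all exercised with known ground truth. Misalignment and the separate
#' PET grid can each be disabled for stage isolation.
#'
#' The default uptake profile places the five composites at the relative
#' levels typical of pons-referenced amyloid scans and rescales them so the
#' true global SUVR equals `global_level` exactly (0.50 is a typical negative
#' scan, 0.82 a typical positive one).
#'
#' @param grid_size MRI grid dimensions (voxels).
#' @param spacing MRI voxel size, mm.
#' @param global_level target true global SUVR (exact, by construction).
#' @param uptake optional named numeric of per-parcel uptake multiples of the
#'   pons value, overriding the profile (names = parcel labels 1..12).
#' @param pons_value absolute activity of the pons (arbitrary units).
#' @param fwhm PSF full width at half maximum, mm.
#' @param noise_sd additive Gaussian noise SD as a fraction of `pons_value`.
#' @param misalign_rot_deg,misalign_trans_mm the true rigid MRI-to-PET
#'   misalignment (Euler degrees / mm); zeros for perfect alignment.
#' @param pons_radius_frac pons sphere radius as a fraction of the smallest
#'   brain semi-axis; too small a value empties the parcel on a coarse grid
#'   (an error).
#' @param pet_spacing PET grid voxel size, mm (`NULL`: keep the MRI grid).
#' @param pet_fov_pad extra PET field of view beyond the MRI box, mm per side.
#' @param mri_noise_sd MRI intensity noise SD (absolute units).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_size = c(96, 96, 96), spacing = c(1, 1, 1),
                         global_level = 0.50, uptake = NULL,
                         pons_value = 100, fwhm = 2, noise_sd = 0.02,
                         misalign_rot_deg = c(0, 0, 5),
                         misalign_trans_mm = c(3, -2, 1),
                         pet_spacing = c(1.3364, 1.3364, 3),
                         pet_fov_pad = 16, pons_radius_frac = 0.15,
                         mri_noise_sd = 2, seed = 1) {
  stopifnot(all(grid_size >= 16), all(spacing > 0), global_level > 0,
            pons_value > 0, fwhm >= 0, noise_sd >= 0)
  structure(list(grid_size = as.integer(grid_size),
                 spacing = as.numeric(spacing),
                 global_level = global_level, uptake = uptake,
                 pons_value = pons_value, fwhm = fwhm, noise_sd = noise_sd,
                 misalign_rot_deg = misalign_rot_deg,
                 misalign_trans_mm = misalign_trans_mm,
                 pet_spacing = pet_spacing, pet_fov_pad = pet_fov_pad,
                 pons_radius_frac = pons_radius_frac,
                 mri_noise_sd = mri_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# relative composite uptake profile (multiples of the pons value) for a
# typical negative and positive pons-referenced amyloid scan
phantom_profile <- function(global_level) {
  if (global_level > 0.61) {
    prof <- c(frontal = 0.84, `anterior/posterior cingulate` = 0.87,
              `lateral parietal` = 0.83, `lateral temporal` = 0.76,
              striatum = 0.75)
  } else {
    prof <- c(frontal = 0.49, `anterior/posterior cingulate` = 0.52,
              `lateral parietal` = 0.50, `lateral temporal` = 0.47,
              striatum = 0.53)
  }
  prof
}

#' The phantom's region scheme
#'
#' Labels 1-10 are the cortical sector parcels (two per composite), 11 the
#' deep white-matter core (measured, unassigned), 12 the pons reference.
#'
#' @return a `region_scheme`.
#' @export
phantom_scheme <- function() {
  comps <- c("frontal", "anterior/posterior cingulate", "lateral parietal",
             "lateral temporal", "striatum")
  region_scheme(tibble::tibble(
    label_id = 1:12,
    parcel_name = c(paste0("sector_", 1:10), "deep_white", "pons"),
    composite = c(rep(comps, each = 2), "", ""),
    reference = c(rep(FALSE, 11), TRUE)),
    composite_order = comps)
}

phantom_labels <- function(spec) {
  gs <- spec$grid_size; sp <- spec$spacing
  c0 <- (gs - 1) / 2
  x <- (seq_len(gs[1]) - 1 - c0[1]) * sp[1]
  y <- (seq_len(gs[2]) - 1 - c0[2]) * sp[2]
  z <- (seq_len(gs[3]) - 1 - c0[3]) * sp[3]
  # deliberately unequal semi-axes (head longer front-to-back than wide) so
  # no rotation leaves the anatomy invariant and registration is well-posed
  ax <- 0.36 * gs[1] * sp[1]; ay <- 0.44 * gs[2] * sp[2]
  az <- 0.40 * gs[3] * sp[3]
  X <- array(x, gs)
  Y <- array(rep(y, each = gs[1]), gs)
  Z <- array(rep(z, each = gs[1] * gs[2]), gs)
  r2 <- (X / ax)^2 + (Y / ay)^2 + (Z / az)^2
  lab <- array(0L, gs)
  inner <- 0.55
  brain <- r2 <= 1
  core <- r2 <= inner^2
  shell <- brain & !core
  ang <- atan2(Y, X)
  sector <- pmin(9L, as.integer(floor((ang + pi) / (2 * pi / 10))))
  lab[shell] <- sector[shell] + 1L
  lab[core] <- 11L
  pc <- c(0, -0.15 * ay, -0.62 * az)
  pr <- spec$pons_radius_frac * min(ax, ay, az)
  pons <- ((X - pc[1])^2 + (Y - pc[2])^2 + (Z - pc[3])^2) <= pr^2
  lab[pons] <- 12L
  aff <- diag(4)
  diag(aff)[1:3] <- sp
  aff[1:3, 4] <- -c0 * sp
  lm <- as_labelmap(lab, aff, frame = "mri-space")
  empty <- setdiff(1:12, labels_present(lm))
  if (length(empty) > 0)
    stop("phantom parcel(s) emptied by configuration: ",
         paste(empty, collapse = ", "), call. = FALSE)
  lm
}

phantom_uptake <- function(spec, labels) {
  scheme <- phantom_scheme()
  if (!is.null(spec$uptake)) {
    u <- spec$uptake
    stopifnot(!is.null(names(u)), all(as.character(1:12) %in% names(u)))
    return(u[as.character(1:12)])
  }
  prof <- phantom_profile(spec$global_level)
  u <- numeric(12)
  names(u) <- as.character(1:12)
  for (co in scheme$composite_order)
    u[as.character(composite_labels(scheme, co))] <- prof[[co]]
  u["11"] <- 0.70   # nonspecific white-matter binding
  u["12"] <- 1.00   # pons defines the reference level
  # rescale composite members so the volume-weighted global hits the target
  counts <- tabulate(labels$values[labels$values > 0], nbins = 12)
  members <- unlist(lapply(scheme$composite_order,
                           function(co) composite_labels(scheme, co)))
  cur <- sum(u[as.character(members)] * counts[members]) / sum(counts[members])
  u[as.character(members)] <- u[as.character(members)] *
    (spec$global_level / cur)
  u
}

#' Generate one synthetic subject
#'
#' Builds the label map, MRI and PET volumes, the analytic pre-blur truth
#' SUVR report, and the true rigid MRI-to-PET transform. Byte-identical for a
#' fixed spec (including seed).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `mri`, `pet`, `labels`, `truth`
#'   (a `suvr_report`), `truth_transform` (`rigid_transform`), `scheme`,
#'   `uptake`, and `spec`.
#' @export
generate_subject <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  labels <- phantom_labels(spec)
  scheme <- phantom_scheme()
  u <- phantom_uptake(spec, labels)

  # analytic truth, pre-blur
  counts <- tabulate(labels$values[labels$values > 0], nbins = 12)
  vv <- voxel_volume(labels)
  truth_stats <- tibble::tibble(label_id = 1:12,
                                mean = unname(u) * spec$pons_value,
                                n_voxels = counts,
                                volume_mm3 = counts * vv)
  truth <- compute_suvr(truth_stats, scheme,
                        reference_mean = spec$pons_value,
                        provenance = list(source = "phantom-analytic"))

  # MRI: tissue contrast plus noise; cortical sectors get slightly different
  # T1 levels (as real regions do), giving registration azimuthal structure
  tissue <- c(60 + 3 * (0:9), 100, 90)
  mri_vals <- array(0, vol_dim(labels))
  nz <- labels$values > 0L
  mri_vals[nz] <- tissue[labels$values[nz]]
  mri_vals <- mri_vals +
    array(stats::rnorm(length(mri_vals), 0, spec$mri_noise_sd),
          vol_dim(labels))
  mri <- as_volume(mri_vals, labels$affine, frame = "mri-space")

  # PET: piecewise-constant activity, PSF blur, noise, move to the PET grid
  act <- array(0, vol_dim(labels))
  act[nz] <- (unname(u) * spec$pons_value)[labels$values[nz]]
  act <- as_volume(act, labels$affine, frame = "mri-space")
  blurred <- smooth_volume(act, psf_model(spec$fwhm))
  noisy <- blurred
  if (spec$noise_sd > 0)
    noisy$values <- noisy$values +
      array(stats::rnorm(length(noisy$values), 0,
                         spec$noise_sd * spec$pons_value),
            vol_dim(noisy))

  t_true <- rigid_transform(spec$misalign_rot_deg * pi / 180,
                            spec$misalign_trans_mm,
                            center = as.numeric(labels$affine %*%
                                       c((vol_dim(labels) - 1) / 2, 1))[1:3])
  if (is.null(spec$pet_spacing) && all(spec$misalign_rot_deg == 0) &&
      all(spec$misalign_trans_mm == 0)) {
    pet <- noisy
    pet$frame <- "pet-space"
  } else {
    psp <- if (is.null(spec$pet_spacing)) vol_spacing(labels)
           else rep_len(spec$pet_spacing, 3)
    # PET field of view extends beyond the MRI box (as scanner FOVs do), so
    # the moving image keeps full support over the fixed grid under any
    # plausible misalignment
    pad <- spec$pet_fov_pad
    fov <- vol_dim(labels) * vol_spacing(labels) + 2 * pad
    pdim <- pmax(8L, as.integer(ceiling(fov / psp)))
    paff <- diag(4)
    diag(paff)[1:3] <- psp
    paff[1:3, 4] <- labels$affine[1:3, 4] - pad
    template <- as_volume(array(0, pdim), paff, frame = "pet-space")
    # PET voxel at world q holds the activity at MRI-world T^-1(q)
    pet <- resample_moving(noisy, invert_transform(t_true), template,
                           fill = 0)
    pet$frame <- "pet-space"
  }
  list(mri = mri, pet = pet, labels = labels, truth = truth,
       truth_transform = t_true, scheme = scheme, uptake = u, spec = spec)
}

#' Generate a synthetic multi-method cohort SUVR table
#'
#' Draws per-subject latent SUVR profiles from two group distributions
#' (negative 0.50 +/- 0.04, positive 0.82 +/- 0.15 by default — typical
#' pons-referenced levels) and observes each subject through several
#' pseudo-methods, each adding a fixed between-method offset plus independent
#' measurement noise. Regional values scale the latent global by the typical
#' regional profile. The result is the long-format table consumed by
#' [run_agreement()].
#'
#' @param n_neg,n_pos subjects per group (>= 3).
#' @param methods pseudo-method names.
#' @param offsets fixed per-method offsets (same length as `methods`).
#' @param noise per-measurement Gaussian noise SD.
#' @param group_means,group_sds length-2 numerics (negative, positive).
#' @param seed RNG seed.
#' @return tibble: `subject_id`, `group` (0/1), `method`, `region`, `suvr`.
#' @export
generate_cohort <- function(n_neg = 135, n_pos = 83,
                            methods = c("proposed", "petsurfer", "pmod"),
                            offsets = c(0, -0.04, 0.02), noise = 0.015,
                            group_means = c(0.50, 0.82),
                            group_sds = c(0.04, 0.15), seed = 1) {
  stopifnot(n_neg >= 3, n_pos >= 3, length(offsets) == length(methods))
  set.seed(seed)
  n <- n_neg + n_pos
  group <- c(rep(0L, n_neg), rep(1L, n_pos))
  latent <- stats::rnorm(n, group_means[group + 1L], group_sds[group + 1L])
  latent <- pmax(latent, 0.05)
  profiles <- rbind(negative = phantom_profile(0.50) / 0.50,
                    positive = phantom_profile(0.82) / 0.82)
  regions <- c(colnames(profiles), "global")
  rows <- vector("list", length(methods))
  for (mi in seq_along(methods)) {
    reg_vals <- lapply(regions, function(r) {
      mult <- if (r == "global") rep(1, n) else profiles[group + 1L, r]
      latent * mult + offsets[mi] + stats::rnorm(n, 0, noise)
    })
    rows[[mi]] <- tibble::tibble(
      subject_id = rep(sprintf("S%03d", seq_len(n)), times = length(regions)),
      group = rep(group, times = length(regions)),
      method = methods[mi],
      region = rep(regions, each = n),
      suvr = unname(unlist(reg_vals)))
  }
  dplyr::bind_rows(rows)
}

#' Write a phantom subject to disk
#'
#' NIfTI volumes (`mri.nii.gz`, `pet.nii.gz`, `labels.nii.gz`), the scheme
#' TSV, the truth report JSON and the true transform JSON, under `dir`.
#'
#' @param subject result of [generate_subject()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(subject$mri, file.path(dir, "mri.nii.gz"))
  write_volume(subject$pet, file.path(dir, "pet.nii.gz"))
  write_volume(subject$labels, file.path(dir, "labels.nii.gz"))
  write_scheme(subject$scheme, file.path(dir, "scheme.tsv"))
  write_transform(subject$truth_transform,
                  file.path(dir, "truth_transform.json"))
  write_suvr_report(subject$truth,
                    json_path = file.path(dir, "truth_suvr.json"))
  invisible(dir)
}
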