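#' Pipeline configuration
#'
#' Bundles every tunable of the four-stage quantification pipeline
#' (conformation, co-registration, partial-volume correction,
#' quantification). Serializable to/from JSON; a digest of the configuration
#' is embedded in every report for provenance.
#'
#' @param conform_spacing working-grid voxel size, mm.
#' @param mi an [mi_config()].
#' @param psf a [psf_model()] (or numeric FWHM, mm).
#' @param pvc logical: apply GTM partial-volume correction.
#' @param classifier a [classifier_config()].
#' @param register logical: run co-registration (disable only for inputs
#'   already aligned to the MRI grid).
#' @param reference_from `"corrected"` (use the PVC-corrected pons mean in
#'   the SUVR denominator when PVC is on) or `"observed"`.
#' @param include_background model background as an explicit GTM region.
#' @param gtm_model_resampling fold the pipeline's own PET-to-working-grid
#'   interpolation (and the scanner-grid sampling it implies) into the GTM
#'   transfer matrix, so the correction inverts the full measurement chain
#'   rather than the PSF alone. Has no effect when PET already lives on the
#'   working grid.
#' @param save_intermediates persist conformed volumes, transform and GTM
#'   under the output directory.
#' @param seed RNG seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(conform_spacing = c(1, 1, 1), mi = mi_config(),
                            psf = psf_model(2), pvc = TRUE,
                            classifier = classifier_config(),
                            register = TRUE,
                            reference_from = c("corrected", "observed"),
                            include_background = TRUE,
                            gtm_model_resampling = TRUE,
                            save_intermediates = FALSE, seed = 1L) {
  if (is.numeric(psf)) psf <- psf_model(psf)
  structure(list(conform_spacing = conform_spacing, mi = mi, psf = psf,
                 pvc = isTRUE(pvc), classifier = classifier,
                 register = isTRUE(register),
                 reference_from = match.arg(reference_from),
                 include_background = isTRUE(include_background),
                 gtm_model_resampling = isTRUE(gtm_model_resampling),
                 save_intermediates = isTRUE(save_intermediates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#' @param cfg a `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(
    list(conform_spacing = cfg$conform_spacing,
         mi = unclass(cfg$mi), psf_fwhm = cfg$psf$fwhm, pvc = cfg$pvc,
         cutoff = cfg$classifier$cutoff, register = cfg$register,
         reference_from = cfg$reference_from,
         include_background = cfg$include_background,
         gtm_model_resampling = cfg$gtm_model_resampling,
         save_intermediates = cfg$save_intermediates, seed = cfg$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(conform_spacing = x$conform_spacing,
                  mi = do.call(mi_config, x$mi),
                  psf = psf_model(x$psf_fwhm), pvc = x$pvc,
                  classifier = classifier_config(x$cutoff),
                  register = x$register, reference_from = x$reference_from,
                  include_background = x$include_background,
                  gtm_model_resampling = x$gtm_model_resampling,
                  save_intermediates = x$save_intermediates, seed = x$seed)
}

new_run_record <- function(stages) {
  tibble::tibble(stage = stages, status = "pending", wall_time = NA_real_,
                 note = "")
}

#' Run the four-stage quantification pipeline
#'
#' Conform MRI and label map to the working grid; rigidly co-register PET to
#' the conformed MRI by mutual information and resample it there; optionally
#' apply GTM partial-volume correction at the parcel level; compute
#' volume-weighted composite and global SUVR against the pons reference and
#' classify. A stage failure marks all downstream stages skipped and is
#' reported in the run record, never silently passed over.
#'
#' @param mri,pet `amypet_volume`s or NIfTI paths.
#' @param labels `amypet_labelmap` or NIfTI path (in MRI space).
#' @param scheme a `region_scheme` or scheme TSV path.
#' @param config a [pipeline_config()].
#' @param out_dir directory for intermediates/reports (required when
#'   `config$save_intermediates`).
#' @return list: `report` (`suvr_report` or `NULL` on failure), `record`
#'   (run-record tibble), `transform`, `gtm`, `ok` (logical).
#' @export
run_pipeline <- function(mri, pet, labels, scheme = default_scheme(),
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(mri)) mri <- load_volume(mri, frame = "mri-space")
  if (is.character(pet)) pet <- load_volume(pet, frame = "pet-space")
  if (is.character(labels)) labels <- load_labelmap(labels)
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  if (config$save_intermediates && is.null(out_dir))
    stop("out_dir required when save_intermediates is on", call. = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  record <- new_run_record(c("conform", "registration", "pvc",
                             "quantification"))
  set_stage <- function(stage, status, secs = NA_real_, note = "") {
    i <- match(stage, record$stage)
    record$status[i] <<- status
    record$wall_time[i] <<- secs
    if (nzchar(note)) record$note[i] <<- note
  }
  fail <- function(stage, err) {
    set_stage(stage, "failed", note = conditionMessage(err))
    idx <- seq(match(stage, record$stage) + 1L, length.out =
                 nrow(record) - match(stage, record$stage))
    if (length(idx) > 0) record$status[idx] <<- "skipped"
    list(report = NULL, record = record, transform = NULL, gtm = NULL,
         ok = FALSE)
  }

  transform <- rigid_transform()
  gtm <- NULL
  notes <- character()

  # stage 1: conformation
  t0 <- proc.time()[3]
  res <- tryCatch({
    mri_c <- conform(mri, config$conform_spacing)
    lab_c <- conform(labels, config$conform_spacing)
    NULL
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail("conform", res))
  set_stage("conform", "ok", proc.time()[3] - t0)

  # stage 2: co-registration (PET moving, MRI fixed)
  t0 <- proc.time()[3]
  res <- tryCatch({
    if (config$register) {
      reg <- register_rigid(mri_c, pet, config$mi)
      transform <- reg$transform
      if (!reg$converged)
        notes <- c(notes, "registration did not converge")
    }
    pet_c <- resample_moving(pet, transform, mri_c, fill = 0)
    NULL
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail("registration", res))
  set_stage("registration", if (config$register) "ok" else "skipped",
            proc.time()[3] - t0,
            note = paste(notes, collapse = "; "))

  # stage 3: GTM partial-volume correction
  t0 <- proc.time()[3]
  res <- tryCatch({
    if (config$pvc) {
      post <- NULL
      if (config$gtm_model_resampling && !same_geometry(pet, mri_c)) {
        # the quantified PET went through sampling on the scanner grid and
        # trilinear interpolation onto the working grid; region indicators
        # must traverse the same chain or the GTM under-models the blur
        pet_template <- as_volume(array(0, vol_dim(pet)), pet$affine,
                                  frame = "pet-space")
        t_est <- transform
        post <- function(v)
          resample_moving(resample_moving(v, invert_transform(t_est),
                                          pet_template), t_est, mri_c)
      }
      gtm <- build_gtm(lab_c, config$psf,
                       include_background = config$include_background,
                       post_smooth = post)
      gtm <- gtm_correct(gtm, pet_c, lab_c)
    }
    NULL
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail("pvc", res))
  set_stage("pvc", if (config$pvc) "ok" else "skipped",
            proc.time()[3] - t0,
            note = if (config$pvc && gtm$condition_number > 1e4)
              sprintf("GTM condition number %.3g", gtm$condition_number)
            else "")

  # stage 4: SUVR quantification + classification
  t0 <- proc.time()[3]
  report <- NULL
  res <- tryCatch({
    chk <- validate_against(scheme, lab_c)
    if (chk$fatal)
      stop("reference label ", scheme$reference_label,
           " missing from label map", call. = FALSE)
    stats <- region_stats(pet_c, lab_c)
    if (config$pvc) {
      corr <- gtm$corrected_means[as.character(stats$label_id)]
      stats$mean <- ifelse(is.na(corr), stats$mean, unname(corr))
    }
    ref_row <- match(scheme$reference_label, stats$label_id)
    if (is.na(ref_row))
      stop("reference label ", scheme$reference_label,
           " missing from label map", call. = FALSE)
    ref_mean <- if (config$pvc && config$reference_from == "observed")
      region_stats(pet_c, lab_c, scheme$reference_label)$mean
    else stats$mean[ref_row]
    report <- compute_suvr(stats, scheme, ref_mean,
                           cfg = config$classifier,
                           pvc_applied = config$pvc,
                           provenance = list(
                             config_digest = rlang::hash(unclass(config)),
                             scheme_digest = rlang::hash(scheme$parcels),
                             transform = list(
                               rotations_deg = transform$rotations * 180 / pi,
                               translation_mm = transform$translation)))
    NULL
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail("quantification", res))
  set_stage("quantification", "ok", proc.time()[3] - t0)

  if (!is.null(out_dir)) {
    write_suvr_report(report, json_path = file.path(out_dir, "suvr.json"),
                      tsv_path = file.path(out_dir, "suvr.tsv"))
    if (config$save_intermediates) {
      write_volume(mri_c, file.path(out_dir, "mri_conformed.nii.gz"))
      write_volume(lab_c, file.path(out_dir, "labels_conformed.nii.gz"))
      write_volume(pet_c, file.path(out_dir, "pet_in_mri.nii.gz"))
      write_transform(transform, file.path(out_dir, "transform.json"))
      if (!is.null(gtm)) write_gtm(gtm, file.path(out_dir, "gtm.tsv"))
    }
  }
  list(report = report, record = record, transform = transform, gtm = gtm,
       ok = TRUE)
}

#' Load a long-format cohort SUVR table
#'
#' Expects tab-separated columns `subject_id`, `method`, `region`, `suvr`
#' (optionally `group` with 0/1 amyloid status). Malformed rows are reported
#' with their line number.
#'
#' @param path TSV path.
#' @return tibble.
#' @export
load_suvr_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "method", "region", "suvr")
  if (!all(need %in% names(df)))
    stop("SUVR table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$suvr))))
  if (length(bad) > 0)
    stop("non-numeric suvr at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  df$suvr <- as.numeric(df$suvr)
  tibble::as_tibble(df)
}

#' Cross-method agreement analysis of a cohort SUVR table
#'
#' For every method pair and region: two-way single-measure ICC (absolute and
#' consistency, with 95% bounds) and Bland-Altman bias with 95% limits of
#' agreement. If the table carries a `group` column (0/1), adds per-method,
#' per-region Welch t-tests of positive vs negative and per-method
#' classification metrics of the cutoff rule on the global SUVR against the
#' group labels.
#'
#' @param table long-format tibble (or TSV path) with columns `subject_id`,
#'   `method`, `region`, `suvr`, optionally `group`.
#' @param cfg a [classifier_config()] for the classification block.
#' @return an `agreement_report` list of tibbles: `icc`, `bland_altman`,
#'   `ttests` (or `NULL`), `classification` (or `NULL`).
#' @export
run_agreement <- function(table, cfg = classifier_config()) {
  if (is.character(table)) table <- load_suvr_table(table)
  table <- tibble::as_tibble(table)
  methods <- unique(table$method)
  if (length(methods) < 2)
    stop("need at least 2 methods for agreement analysis", call. = FALSE)
  regions <- unique(table$region)
  pairs <- utils::combn(methods, 2, simplify = FALSE)

  wide_region <- function(region) {
    sub <- table[table$region == region, c("subject_id", "method", "suvr")]
    tidyr::pivot_wider(sub, names_from = "method", values_from = "suvr")
  }

  icc_rows <- list(); ba_rows <- list()
  for (region in regions) {
    w <- wide_region(region)
    for (pr in pairs) {
      m <- as.matrix(w[, pr])
      for (form in c("absolute", "consistency")) {
        r <- icc(m, form)
        icc_rows[[length(icc_rows) + 1]] <- tibble::tibble(
          method_a = pr[1], method_b = pr[2], region = region,
          form = form, icc = r$icc, lower = r$lower, upper = r$upper)
      }
      ba <- bland_altman(m[, 1], m[, 2])
      ba_rows[[length(ba_rows) + 1]] <- tibble::tibble(
        method_a = pr[1], method_b = pr[2], region = region,
        mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
        loa_lower = ba$loa_lower, loa_upper = ba$loa_upper, n = ba$n)
    }
  }

  ttests <- NULL; classification <- NULL
  if ("group" %in% names(table)) {
    tt_rows <- list(); cl_rows <- list()
    for (m in methods) {
      for (region in regions) {
        sub <- table[table$method == m & table$region == region, ]
        if (length(unique(sub$group)) == 2) {
          r <- welch_ttest(sub$suvr[sub$group == 1], sub$suvr[sub$group == 0])
          tt_rows[[length(tt_rows) + 1]] <- tibble::tibble(
            method = m, region = region, t = r$t, df = r$df,
            p_value = r$p_value, mean_pos = r$mean_a, mean_neg = r$mean_b)
        }
      }
      gl <- table[table$method == m & table$region == "global", ]
      if (nrow(gl) > 0 && length(unique(gl$group)) == 2) {
        pred <- classify_amyloid(gl$suvr, cfg)
        cm <- classification_metrics(gl$group, pred)
        cl_rows[[length(cl_rows) + 1]] <-
          dplyr::bind_cols(tibble::tibble(method = m), cm)
      }
    }
    if (length(tt_rows)) ttests <- dplyr::bind_rows(tt_rows)
    if (length(cl_rows)) classification <- dplyr::bind_rows(cl_rows)
  }
  structure(list(icc = dplyr::bind_rows(icc_rows),
                 bland_altman = dplyr::bind_rows(ba_rows),
                 ttests = ttests, classification = classification,
                 cutoff = cfg$cutoff),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat("ICC (", nrow(x$icc), " rows):\n", sep = "")
  print(x$icc, n = 6)
  cat("Bland-Altman (", nrow(x$bland_altman), " rows):\n", sep = "")
  print(x$bland_altman, n = 6)
  if (!is.null(x$classification)) {
    cat("Classification at cutoff ", x$cutoff, ":\n", sep = "")
    print(x$classification)
  }
  invisible(x)
}

#' Write an agreement report as TSV files
#' @param x an `agreement_report`.
#' @param dir output directory.
#' @export
write_agreement <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$icc, file.path(dir, "icc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$bland_altman, file.path(dir, "bland_altman.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$ttests))
    utils::write.table(x$ttests, file.path(dir, "ttests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(x$classification))
    utils::write.table(x$classification, file.path(dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
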