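#' Amyloid-positivity classifier settings
#'
#' Global SUVR strictly greater than the cutoff is called positive (label 1);
#' at or below, negative (label 0). The default cutoff 0.61 is the published
#' threshold for pons-referenced amyloid SUVR.
#'
#' @param cutoff positive SUVR threshold, > 0.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(cutoff = 0.61) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  structure(list(cutoff = cutoff, comparison = "strict-greater"),
            class = "classifier_config")
}

#' Classify amyloid status from a global SUVR
#'
#' @param global_suvr finite numeric global SUVR value(s).
#' @param cfg a `classifier_config`.
#' @return integer vector: 1 (positive) where `global_suvr > cutoff`, else 0.
#' @export
classify_amyloid <- function(global_suvr, cfg = classifier_config()) {
  stopifnot(all(is.finite(global_suvr)))
  as.integer(global_suvr > cfg$cutoff)
}

#' Volume-weighted SUVR over composite regions
#'
#' For each composite, SUVR is the volume-weighted mean intensity of its
#' member parcels divided by the reference (pons) mean:
#' `(sum(mean_n * V_n) / sum(V_n)) / reference_mean`. The global SUVR is the
#' same quantity over the union of all composite members — algebraically the
#' volume-weighted mean of the composite SUVRs. The global value is
#' classified against the cutoff.
#'
#' @param parcel_stats tibble with columns `label_id`, `mean`, `volume_mm3`
#'   (e.g. from [region_stats()], with means replaced by GTM-corrected values
#'   when partial-volume correction is on). Must cover every composite member
#'   parcel.
#' @param scheme a `region_scheme`.
#' @param reference_mean mean intensity of the reference (pons) parcel, > 0.
#' @param cfg a `classifier_config`.
#' @param pvc_applied logical flag recorded in the report.
#' @param provenance named list (scheme/transform/config digests) carried
#'   into the report.
#' @return a `suvr_report`: per-parcel stats, per-composite tibble
#'   (`composite`, `suvr`, `volume_mm3`, `n_parcels`), `global_suvr`,
#'   `classification` (1/0), `reference_mean`, `cutoff`, `pvc_applied`.
#' @export
compute_suvr <- function(parcel_stats, scheme, reference_mean,
                         cfg = classifier_config(), pvc_applied = FALSE,
                         provenance = list()) {
  stopifnot(inherits(scheme, "region_scheme"))
  parcel_stats <- tibble::as_tibble(parcel_stats)
  need <- c("label_id", "mean", "volume_mm3")
  if (!all(need %in% names(parcel_stats)))
    stop("parcel_stats needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("reference mean must be positive (got ", reference_mean, ")",
         call. = FALSE)
  members <- unlist(lapply(scheme$composite_order,
                           function(co) composite_labels(scheme, co)))
  missing <- setdiff(members, parcel_stats$label_id)
  if (length(missing) > 0)
    stop("parcel_stats is missing composite member parcel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  wsuvr <- function(ids) {
    ps <- parcel_stats[match(ids, parcel_stats$label_id), ]
    sum(ps$mean * ps$volume_mm3) / sum(ps$volume_mm3) / reference_mean
  }
  composites <- tibble::tibble(
    composite = scheme$composite_order,
    suvr = vapply(scheme$composite_order,
                  function(co) wsuvr(composite_labels(scheme, co)), 1,
                  USE.NAMES = FALSE),
    volume_mm3 = vapply(scheme$composite_order, function(co) {
      ids <- composite_labels(scheme, co)
      sum(parcel_stats$volume_mm3[match(ids, parcel_stats$label_id)])
    }, 1, USE.NAMES = FALSE),
    n_parcels = vapply(scheme$composite_order,
                       function(co) length(composite_labels(scheme, co)),
                       integer(1), USE.NAMES = FALSE)
  )
  global_suvr <- wsuvr(members)
  structure(list(parcels = parcel_stats, composites = composites,
                 global_suvr = global_suvr,
                 classification = classify_amyloid(global_suvr, cfg),
                 reference_mean = reference_mean, cutoff = cfg$cutoff,
                 pvc_applied = isTRUE(pvc_applied), provenance = provenance),
            class = "suvr_report")
}

#' @export
print.suvr_report <- function(x, ...) {
  cat(sprintf(
    "<suvr_report> global SUVR %.4f (%s at cutoff %.2f)%s, reference mean %.4g\n",
    x$global_suvr, if (x$classification == 1L) "positive" else "negative",
    x$cutoff, if (x$pvc_applied) ", PVC applied" else "", x$reference_mean))
  print(x$composites)
  invisible(x)
}

#' Tidy an SUVR report
#'
#' One row per composite plus a `global` row, broom-style.
#'
#' @param x a `suvr_report`.
#' @param ... unused.
#' @return tibble with columns `region`, `suvr`, `volume_mm3`, `n_parcels`.
#' @method tidy suvr_report
#' @export
tidy.suvr_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::rename(x$composites, region = "composite"),
    tibble::tibble(region = "global", suvr = x$global_suvr,
                   volume_mm3 = sum(x$composites$volume_mm3),
                   n_parcels = sum(x$composites$n_parcels)))
}

#' @rdname tidy.suvr_report
#' @method glance suvr_report
#' @export
glance.suvr_report <- function(x, ...) {
  tibble::tibble(global_suvr = x$global_suvr,
                 classification = x$classification, cutoff = x$cutoff,
                 reference_mean = x$reference_mean,
                 pvc_applied = x$pvc_applied)
}

#' Write an SUVR report as JSON and TSV
#'
#' The JSON carries the full report (parcels, composites, global,
#' classification, provenance); the TSV is the flat per-composite + global
#' table from [tidy.suvr_report()].
#'
#' @param x a `suvr_report`.
#' @param json_path,tsv_path output paths (`NULL` to skip one).
#' @export
write_suvr_report <- function(x, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(x, "suvr_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(global_suvr = x$global_suvr, classification = x$classification,
           cutoff = x$cutoff, reference_mean = x$reference_mean,
           pvc_applied = x$pvc_applied,
           composites = x$composites, parcels = x$parcels,
           provenance = x$provenance),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(tidy.suvr_report(x), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}
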