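#' Region schemes: parcels, composites and the reference region
#'
#' A region scheme maps integer parcel labels to named parcels, groups parcels
#' into composite regions (by default the five used for amyloid reads:
#' frontal, anterior/posterior cingulate, lateral parietal, lateral temporal,
#' striatum), and designates one parcel — the pons — as the SUVR reference.
#' Parcels with an empty composite are measured but excluded from composites;
#' the reference parcel may not belong to any composite.
#'
#' @param parcels data frame with columns `label_id`, `parcel_name`,
#'   `composite` (`""`/`NA` = unassigned) and logical `reference` (exactly one
#'   `TRUE` row).
#' @param composite_order optional character vector fixing the reporting order
#'   of composites; defaults to order of first appearance.
#' @return an object of class `region_scheme`.
#' @export
region_scheme <- function(parcels, composite_order = NULL) {
  parcels <- tibble::as_tibble(parcels)
  need <- c("label_id", "parcel_name", "composite", "reference")
  if (!all(need %in% names(parcels)))
    stop("scheme needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  parcels$label_id <- as.integer(parcels$label_id)
  parcels$composite <- ifelse(is.na(parcels$composite), "", parcels$composite)
  parcels$reference <- as.logical(parcels$reference)

  dup <- which(duplicated(parcels$label_id))
  if (length(dup) > 0)
    stop("duplicate label_id ", parcels$label_id[dup[1]], " at row ", dup[1],
         call. = FALSE)
  if (sum(parcels$reference) != 1L)
    stop("exactly one row must be flagged as the reference region (found ",
         sum(parcels$reference), ")", call. = FALSE)
  ref_row <- which(parcels$reference)
  if (nzchar(parcels$composite[ref_row]))
    stop("reference parcel (row ", ref_row,
         ") may not belong to a composite", call. = FALSE)
  if (any(parcels$label_id == 0L))
    stop("label 0 is reserved for background (row ",
         which(parcels$label_id == 0L)[1], ")", call. = FALSE)

  comps <- unique(parcels$composite[nzchar(parcels$composite)])
  if (is.null(composite_order)) composite_order <- comps
  if (!setequal(composite_order, comps))
    stop("composite_order must name exactly the composites in the table",
         call. = FALSE)
  structure(list(parcels = parcels,
                 reference_label = parcels$label_id[ref_row],
                 composite_order = composite_order),
            class = "region_scheme")
}

#' @export
print.region_scheme <- function(x, ...) {
  cat(sprintf("<region_scheme> %d parcels, %d composites, reference label %d\n",
              nrow(x$parcels), length(x$composite_order), x$reference_label))
  for (co in x$composite_order)
    cat(sprintf("  %-28s %d parcels\n", co,
                sum(x$parcels$composite == co)))
  n_un <- sum(!nzchar(x$parcels$composite)) - 1L
  if (n_un > 0) cat("  (", n_un, " unassigned parcels)\n", sep = "")
  invisible(x)
}

#' Labels belonging to one composite
#' @param scheme a `region_scheme`.
#' @param composite composite name.
#' @return integer label vector.
#' @export
composite_labels <- function(scheme, composite) {
  stopifnot(inherits(scheme, "region_scheme"))
  if (!composite %in% scheme$composite_order)
    stop("unknown composite: ", composite, call. = FALSE)
  scheme$parcels$label_id[scheme$parcels$composite == composite]
}

#' Read / write a region scheme as TSV
#'
#' The on-disk format is a tab-separated table with columns `label_id`,
#' `parcel_name`, `composite` (empty = unassigned) and `reference` (0/1,
#' exactly one 1). `load_scheme()` validates on read; `write_scheme()`
#' round-trips exactly.
#'
#' @param path TSV file path.
#' @return `load_scheme`: a `region_scheme`.
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) stop("cannot read scheme file: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "character",
                                         "integer"),
                          na.strings = NULL)
  region_scheme(tibble::tibble(label_id = df$label_id,
                               parcel_name = df$parcel_name,
                               composite = df$composite,
                               reference = df$reference == 1L))
}

#' @param scheme scheme to write.
#' @rdname load_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "region_scheme"))
  df <- scheme$parcels
  df$reference <- as.integer(df$reference)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The shipped illustrative 97-parcel scheme
#'
#' A synthetic stand-in parcellation table (97 cortical/subcortical parcels
#' plus a pons reference) with the five standard amyloid composites. The
#' parcel inventory is illustrative — real pipelines supply their own
#' segmenter's scheme — but the composite structure matches the five-region
#' amyloid read.
#'
#' @return a `region_scheme`.
#' @export
default_scheme <- function() {
  load_scheme(system.file("extdata", "scheme_97_synthetic.tsv",
                          package = "amypet", mustWork = TRUE))
}

#' Cross-validate a scheme against a label map
#'
#' Reports scheme parcels missing from the map and map labels missing from
#' the scheme. A missing reference parcel is fatal for quantification and is
#' flagged as such.
#'
#' @param scheme a `region_scheme`.
#' @param labels an `amypet_labelmap`.
#' @return a `scheme_report` list: `missing_labels` (in scheme, not in map),
#'   `extra_labels` (in map, not in scheme), `reference_missing` (logical),
#'   `fatal` (logical).
#' @export
validate_against <- function(scheme, labels) {
  stopifnot(inherits(scheme, "region_scheme"),
            inherits(labels, "amypet_labelmap"))
  present <- labels_present(labels)
  missing <- setdiff(scheme$parcels$label_id, present)
  extra <- setdiff(present, scheme$parcels$label_id)
  ref_missing <- scheme$reference_label %in% missing
  structure(list(missing_labels = missing, extra_labels = extra,
                 reference_missing = ref_missing, fatal = ref_missing),
            class = "scheme_report")
}

#' @export
print.scheme_report <- function(x, ...) {
  cat("<scheme_report>\n")
  cat("  scheme labels missing from map:",
      if (length(x$missing_labels)) paste(x$missing_labels, collapse = ", ")
      else "none", "\n")
  cat("  map labels not in scheme:",
      if (length(x$extra_labels)) paste(x$extra_labels, collapse = ", ")
      else "none", "\n")
  if (x$reference_missing)
    cat("  FATAL: reference label missing from map\n")
  invisible(x)
}
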