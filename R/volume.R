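#' 3-D image volumes with world-space geometry
#'
#' An `amypet_volume` couples a 3-D numeric array with a 4x4 voxel-to-world
#' affine (RAS+ world convention, 0-based voxel indices) and a `frame` tag
#' recording which space the volume lives in (`"mri-space"`, `"pet-space"` or
#' `"conformed"`). An `amypet_labelmap` is a volume whose values are
#' non-negative integer parcel labels, 0 meaning background.
#'
#' @param values 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (last row `c(0,0,0,1)`).
#' @param frame space tag, one of `"mri-space"`, `"pet-space"`, `"conformed"`.
#' @return An object of class `amypet_volume` (or `amypet_labelmap`).
#' @examples
#' v <- as_volume(array(rnorm(8), c(2, 2, 2)))
#' vol_spacing(v)
#' @export
as_volume <- function(values, affine = diag(4), frame = "mri-space") {
  values <- unclass(values)
  attributes(values) <- list(dim = dim(values))
  v <- structure(list(values = values, affine = unname(affine), frame = frame),
                 class = "amypet_volume")
  validate_volume(v)
  v
}

#' @rdname as_volume
#' @export
as_labelmap <- function(values, affine = diag(4), frame = "mri-space") {
  values <- unclass(values)
  if (any(values[is.finite(values)] %% 1 != 0) || any(values < 0, na.rm = TRUE))
    stop("label map values must be non-negative integers", call. = FALSE)
  storage.mode(values) <- "integer"
  attributes(values) <- list(dim = dim(values))
  v <- structure(list(values = values, affine = unname(affine), frame = frame),
                 class = c("amypet_labelmap", "amypet_volume"))
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  if (length(dim(v$values)) != 3L)
    stop("volume values must be a 3-D array", call. = FALSE)
  if (!is.matrix(v$affine) || !all(dim(v$affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  sp <- vol_spacing(v)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("degenerate affine: zero or non-finite voxel spacing (pixdim)",
         call. = FALSE)
  ax <- apply(abs(v$affine[1:3, 1:3]), 2, which.max)
  if (length(unique(ax)) != 3L)
    stop("degenerate affine: axis directions are not a signed permutation ",
         "of the anatomical axes (srow)", call. = FALSE)
  if (!is.element(v$frame, c("mri-space", "pet-space", "conformed")))
    stop("unknown frame tag: ", v$frame, call. = FALSE)
  invisible(v)
}

#' Volume geometry accessors
#'
#' @param v an `amypet_volume`.
#' @return `vol_spacing`: mm per voxel along each grid axis; `vol_origin`:
#'   world coordinate of voxel (0,0,0); `vol_orientation`: three-letter
#'   orientation code (e.g. `"RAS"`, `"LPS"`); `vol_dim`: grid dimensions;
#'   `voxel_volume`: volume of one voxel in mm^3.
#' @export
vol_spacing <- function(v) sqrt(colSums(v$affine[1:3, 1:3]^2))

#' @rdname vol_spacing
#' @export
vol_origin <- function(v) v$affine[1:3, 4]

#' @rdname vol_spacing
#' @export
vol_dim <- function(v) dim(v$values)

#' @rdname vol_spacing
#' @export
voxel_volume <- function(v) abs(det(v$affine[1:3, 1:3]))

#' @rdname vol_spacing
#' @export
vol_orientation <- function(v) {
  pos <- c("R", "A", "S")
  neg <- c("L", "P", "I")
  code <- character(3)
  for (j in 1:3) {
    col <- v$affine[1:3, j]
    ax <- which.max(abs(col))
    code[j] <- if (col[ax] >= 0) pos[ax] else neg[ax]
  }
  paste(code, collapse = "")
}

#' Distinct nonzero labels of a label map
#' @param labels an `amypet_labelmap`.
#' @return sorted integer vector of the labels present.
#' @export
labels_present <- function(labels) {
  stopifnot(inherits(labels, "amypet_labelmap"))
  u <- sort(unique(as.integer(labels$values)))
  u[u != 0L]
}

same_geometry <- function(a, b, tol = 1e-4) {
  all(vol_dim(a) == vol_dim(b)) && all(abs(a$affine - b$affine) < tol)
}

#' @export
print.amypet_volume <- function(x, ...) {
  kind <- if (inherits(x, "amypet_labelmap")) "label map" else "volume"
  cat(sprintf("<amypet %s> %s, spacing %s mm, %s, frame '%s'\n", kind,
              paste(vol_dim(x), collapse = "x"),
              paste(signif(vol_spacing(x), 4), collapse = "x"),
              vol_orientation(x), x$frame))
  if (inherits(x, "amypet_labelmap")) {
    cat("  labels:", length(labels_present(x)), "distinct nonzero\n")
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$values),
                max(x$values)))
  }
  invisible(x)
}

#' Read and write NIfTI-1 volumes
#'
#' `load_volume()` reads a NIfTI-1 file (gzipped or not), applies the header's
#' intensity slope/intercept, squeezes a degenerate fourth axis (single time
#' point) with a warning, and decodes the voxel-to-world affine from the
#' sform/qform. `load_labelmap()` does the same and coerces to integer labels.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param frame frame tag to stamp on the result.
#' @return an `amypet_volume` / `amypet_labelmap`.
#' @export
load_volume <- function(path, frame = "mri-space") {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L) {
    if (d[4] == 1L) {
      warning("4-D image with a single time point; squeezing to 3-D",
              call. = FALSE)
      arr <- arr[, , , 1, drop = TRUE]
      dim(arr) <- d[1:3]
    } else {
      stop("expected a 3-D image, got 4-D with ", d[4], " volumes (dim field)",
           call. = FALSE)
    }
  } else if (length(d) != 3L) {
    stop("expected a 3-D image, got ", length(d), "-D (dim field)",
         call. = FALSE)
  }
  aff <- unname(structure(RNifti::xform(img), code = NULL, imagedim = NULL))
  aff <- matrix(as.numeric(aff[1:4, 1:4]), 4, 4)
  if (any(!is.finite(arr)))
    stop("non-finite voxel values after applying scl_slope/scl_inter",
         call. = FALSE)
  as_volume(arr, aff, frame = frame)
}

#' @rdname load_volume
#' @export
load_labelmap <- function(path, frame = "mri-space") {
  v <- load_volume(path, frame = frame)
  if (max(abs(v$values - round(v$values))) > 1e-6)
    stop("label map contains non-integer values", call. = FALSE)
  as_labelmap(round(v$values), v$affine, frame = frame)
}

#' @param v volume to write.
#' @rdname load_volume
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "amypet_volume"))
  arr <- v$values
  dt <- if (inherits(v, "amypet_labelmap")) "int32" else "double"
  img <- RNifti::asNifti(arr, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto an arbitrary target grid
#'
#' Maps every target voxel centre to world space via `target_affine`, pulls it
#' back through the source affine and interpolates: trilinear for intensity
#' volumes, nearest-neighbour for label maps (never inventing a label).
#' Samples falling outside the source grid get `fill` (default 0: PET/MRI
#' background is air).
#'
#' @param v source `amypet_volume` or `amypet_labelmap`.
#' @param target_affine 4x4 voxel-to-world affine of the target grid.
#' @param target_dim integer triple, target grid size.
#' @param method `"auto"` (trilinear for volumes, nearest for label maps),
#'   `"trilinear"` or `"nearest"`.
#' @param fill value for out-of-grid samples.
#' @param frame frame tag for the result (default: kept from `v`).
#' @return resampled volume of the same class as `v`.
#' @export
resample_to_grid <- function(v, target_affine, target_dim,
                             method = c("auto", "trilinear", "nearest"),
                             fill = 0, frame = v$frame) {
  method <- match.arg(method)
  is_lab <- inherits(v, "amypet_labelmap")
  nearest <- switch(method, auto = is_lab, trilinear = FALSE, nearest = TRUE)
  M <- solve(v$affine) %*% target_affine
  out <- resample_affine_cpp(as.double(v$values), dim(v$values), M[1:3, ],
                             as.integer(target_dim), nearest, fill)
  if (is_lab) as_labelmap(out, target_affine, frame = frame)
  else as_volume(out, target_affine, frame = frame)
}

#' Conform a volume to an isotropic RAS grid
#'
#' Re-orients to right-anterior-superior axis order and resamples to the
#' target spacing (default 1 mm isotropic), the working grid on which all
#' quantification happens. World coordinates are preserved: the target grid
#' covers the source field of view, axis-aligned in world space. Intensities
#' are interpolated trilinearly, label maps nearest-neighbour. A volume that
#' is already RAS, axis-aligned and at target spacing is returned unchanged
#' (up to the frame tag), making conformation idempotent.
#'
#' @param v volume or label map.
#' @param target_spacing mm triple, all positive.
#' @return conformed volume, frame tagged `"conformed"`.
#' @export
conform <- function(v, target_spacing = c(1, 1, 1)) {
  stopifnot(inherits(v, "amypet_volume"))
  target_spacing <- rep_len(as.numeric(target_spacing), 3L)
  if (any(target_spacing <= 0)) stop("target_spacing must be positive",
                                     call. = FALSE)
  R3 <- v$affine[1:3, 1:3]
  axis_aligned <- all(abs(R3 - diag(diag(R3))) < 1e-6 * max(abs(R3)))
  if (vol_orientation(v) == "RAS" && axis_aligned &&
      all(abs(vol_spacing(v) - target_spacing) < 1e-6)) {
    out <- v
    out$frame <- "conformed"
    return(out)
  }
  # world-space bounding box of the source voxel centres
  d <- vol_dim(v)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  w <- v$affine %*% rbind(t(corners), 1)
  lo <- apply(w[1:3, , drop = FALSE], 1, min)
  hi <- apply(w[1:3, , drop = FALSE], 1, max)
  out_dim <- pmax(1L, as.integer(floor((hi - lo) / target_spacing + 1 + 1e-6)))
  aff <- diag(4)
  diag(aff)[1:3] <- target_spacing
  aff[1:3, 4] <- lo
  resample_to_grid(v, aff, out_dim, frame = "conformed")
}

#' Per-region intensity statistics
#'
#' Mean intensity, voxel count and volume (mm^3) of each requested parcel,
#' computed over exactly the voxels carrying that label.
#'
#' @param v intensity volume.
#' @param labels label map sharing `v`'s grid and affine.
#' @param label_ids integer labels to report; default all labels present.
#' @return a tibble with columns `label_id`, `mean`, `n_voxels`, `volume_mm3`,
#'   one row per requested label.
#' @export
region_stats <- function(v, labels, label_ids = NULL) {
  stopifnot(inherits(v, "amypet_volume"), inherits(labels, "amypet_labelmap"))
  if (!same_geometry(v, labels))
    stop("volume and label map do not share grid geometry", call. = FALSE)
  present <- labels_present(labels)
  if (is.null(label_ids)) label_ids <- present
  label_ids <- as.integer(label_ids)
  missing <- setdiff(label_ids, c(0L, present))
  if (length(missing) > 0)
    stop("label(s) ", paste(missing, collapse = ", "),
         " absent from label map; available: ",
         paste(present, collapse = ", "), call. = FALSE)
  st <- label_stats_cpp(as.double(v$values), labels$values,
                        max(c(label_ids, present)))
  vv <- voxel_volume(v)
  n <- st$count[label_ids + 1L]
  tibble::tibble(
    label_id = label_ids,
    mean = st$sum[label_ids + 1L] / n,
    n_voxels = as.integer(n),
    volume_mm3 = n * vv
  )
}
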