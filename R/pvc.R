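#' Gaussian point-spread-function model
#'
#' Scanner resolution is modelled as an isotropic Gaussian point spread
#' function characterised by its full width at half maximum (mm). The
#' corresponding standard deviation is `fwhm / (2 * sqrt(2 * log(2)))`.
#' `fwhm = 0` means no blur.
#'
#' @param fwhm full width at half maximum in mm, >= 0.
#' @return an object of class `psf_model` with fields `fwhm` and `sigma` (mm).
#' @export
psf_model <- function(fwhm = 2) {
  stopifnot(is.numeric(fwhm), length(fwhm) == 1, fwhm >= 0)
  structure(list(fwhm = fwhm, sigma = fwhm / (2 * sqrt(2 * log(2)))),
            class = "psf_model")
}

# 1-D discretized Gaussian kernel (sigma in voxel units), truncated at
# ceiling(4*sigma) and normalized to unit sum; length-1 identity for sigma 0.
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Smooth a volume with a Gaussian PSF
#'
#' Separable convolution with the discretized Gaussian, zero boundary: signal
#' leaving the grid is lost, matching a zero (air) background. Sigma is
#' converted from mm to voxels per axis using the volume's spacing.
#'
#' @param v an `amypet_volume`.
#' @param psf a `psf_model` (or numeric FWHM in mm).
#' @return smoothed volume, same grid.
#' @export
smooth_volume <- function(v, psf) {
  stopifnot(inherits(v, "amypet_volume"))
  if (is.numeric(psf)) psf <- psf_model(psf)
  if (psf$fwhm == 0) return(v)
  sp <- vol_spacing(v)
  out <- as.double(v$values)
  for (ax in 0:2) {
    k <- gauss_kernel_1d(psf$sigma / sp[ax + 1])
    if (length(k) > 1) out <- conv3_axis_cpp(out, vol_dim(v), k, ax)
  }
  as_volume(out, v$affine, frame = v$frame)
}

#' Build the geometric transfer matrix
#'
#' For each pair of regions (i, j), `omega[i, j]` is the mean, over region
#' i's voxels, of the PSF-smoothed binary indicator of region j: the fraction
#' of region i's observed signal contributed by region j's true activity
#' under the blur model. With zero blur omega is the identity. Background
#' (label 0) is included as an explicit region by default so spill-out to
#' surrounding tissue/air is modelled; drop it with `include_background =
#' FALSE`.
#'
#' @param labels an `amypet_labelmap`.
#' @param psf a `psf_model` (or numeric FWHM, mm).
#' @param region_ids parcels to model; default all labels present.
#' @param include_background add label 0 as a region.
#' @param post_smooth optional function `amypet_volume -> amypet_volume`
#'   applied to each smoothed indicator, to fold further known parts of the
#'   measurement chain (e.g. the pipeline's own grid-resampling operator)
#'   into omega; `NULL` for the plain PSF-only transfer matrix.
#' @return a `gtm_system`: `region_ids`, `omega` (K x K), `psf`,
#'   `condition_number`; `observed_means`/`corrected_means` filled by
#'   [gtm_correct()].
#' @export
build_gtm <- function(labels, psf = psf_model(2), region_ids = NULL,
                      include_background = TRUE, post_smooth = NULL) {
  stopifnot(inherits(labels, "amypet_labelmap"))
  if (is.numeric(psf)) psf <- psf_model(psf)
  present <- labels_present(labels)
  if (is.null(region_ids)) region_ids <- present
  region_ids <- as.integer(region_ids)
  bad <- setdiff(region_ids, present)
  if (length(bad) > 0)
    stop("empty/absent region(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (include_background && any(labels$values == 0L))
    region_ids <- c(0L, setdiff(region_ids, 0L))
  K <- length(region_ids)
  lab <- labels$values
  masks_idx <- lapply(region_ids, function(id) which(lab == id))
  omega <- matrix(0, K, K)
  for (j in seq_len(K)) {
    ind <- numeric(length(lab))
    ind[masks_idx[[j]]] <- 1
    sm <- if (psf$fwhm == 0) ind else {
      out <- ind
      sp <- vol_spacing(labels)
      for (ax in 0:2) {
        k <- gauss_kernel_1d(psf$sigma / sp[ax + 1])
        if (length(k) > 1) out <- conv3_axis_cpp(out, vol_dim(labels), k, ax)
      }
      out
    }
    if (!is.null(post_smooth)) {
      dim(sm) <- vol_dim(labels)
      sm <- as.double(post_smooth(as_volume(sm, labels$affine,
                                            frame = labels$frame))$values)
    }
    for (i in seq_len(K)) omega[i, j] <- mean(sm[masks_idx[[i]]])
  }
  dimnames(omega) <- list(region_ids, region_ids)
  structure(list(region_ids = region_ids, omega = omega, psf = psf,
                 observed_means = NULL, corrected_means = NULL,
                 condition_number = kappa(omega, exact = TRUE)),
            class = "gtm_system")
}

#' Apply GTM partial-volume correction to regional PET means
#'
#' Measures the observed regional means of `pet` over the GTM's regions and
#' solves `omega %*% corrected = observed` by least squares (QR), yielding
#' partial-volume-corrected regional means. A condition number above 1e4
#' triggers a warning (consider merging small regions).
#'
#' @param system a `gtm_system` from [build_gtm()].
#' @param pet PET `amypet_volume` sharing the label map's grid.
#' @param labels the `amypet_labelmap` used to build the system.
#' @return the `gtm_system` with `observed_means` and `corrected_means`
#'   filled (named by region id).
#' @export
gtm_correct <- function(system, pet, labels) {
  stopifnot(inherits(system, "gtm_system"), inherits(pet, "amypet_volume"),
            inherits(labels, "amypet_labelmap"))
  if (!same_geometry(pet, labels))
    stop("PET and label map do not share grid geometry", call. = FALSE)
  st <- region_stats(pet, labels, system$region_ids)
  obs <- st$mean
  if (any(!is.finite(system$omega)) ||
      abs(det(system$omega)) < 1e-300)
    stop("singular geometric transfer matrix; merge regions that are too ",
         "small or too close relative to the PSF", call. = FALSE)
  if (system$condition_number > 1e4)
    warning(sprintf("GTM condition number %.3g > 1e4; correction may be
unstable", system$condition_number), call. = FALSE)
  corrected <- qr.solve(system$omega, obs)
  names(obs) <- names(corrected) <- system$region_ids
  system$observed_means <- obs
  system$corrected_means <- corrected
  system
}

#' @export
print.gtm_system <- function(x, ...) {
  cat(sprintf("<gtm_system> %d regions, PSF FWHM %.3g mm, condition %.3g\n",
              length(x$region_ids), x$psf$fwhm, x$condition_number))
  if (!is.null(x$corrected_means)) {
    df <- tibble::tibble(region = x$region_ids, observed = x$observed_means,
                         corrected = x$corrected_means)
    print(df, n = 8)
  }
  invisible(x)
}

#' Tidy a GTM system into one row per region
#' @param x a `gtm_system`.
#' @param ... unused.
#' @return tibble with columns `region_id`, `observed`, `corrected`.
#' @method tidy gtm_system
#' @export
tidy.gtm_system <- function(x, ...) {
  tibble::tibble(region_id = x$region_ids,
                 observed = if (is.null(x$observed_means)) NA_real_
                            else unname(x$observed_means),
                 corrected = if (is.null(x$corrected_means)) NA_real_
                             else unname(x$corrected_means))
}

#' Write GTM omega and means as TSV
#' @param system a `gtm_system`.
#' @param path output TSV path.
#' @export
write_gtm <- function(system, path) {
  om <- as.data.frame(system$omega)
  names(om) <- system$region_ids
  df <- cbind(data.frame(region_id = system$region_ids), om)
  if (!is.null(system$observed_means)) {
    df$observed_mean <- unname(system$observed_means)
    df$corrected_mean <- unname(system$corrected_means)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
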