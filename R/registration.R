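#' Mutual-information registration settings
#'
#' Settings for rigid PET-to-MRI co-registration by maximising the mutual
#' information (MI) of the joint intensity histogram, Mattes-style: linear
#' partial-volume bin weighting over a fixed number of bins, a steepest-ascent
#' optimizer whose step length is chosen by golden-section line search, and a
#' coarse-to-fine multiresolution pyramid for basin-of-attraction robustness
#' (set `pyramid = 1` to disable). All voxels contribute to the histogram (no
#' random sampling), so the metric — and the whole registration — is
#' deterministic.
#'
#' @param n_bins histogram bins per image (>= 8).
#' @param pyramid integer downsampling factors, coarse to fine; must end in 1.
#' @param max_iter maximum ascent iterations per pyramid level.
#' @param tol convergence tolerance on the MI gain per iteration (nats).
#' @param step0 initial line-search step at the finest level, in mm
#'   (rotations are scaled to comparable units via `rot_scale`).
#' @param line_tol golden-section termination, as a fraction of the bracket.
#' @param rot_scale mm of parameter space per radian of rotation; the default
#'   makes 1 degree comparable to 1 mm at a typical head radius.
#' @return an object of class `mi_config`.
#' @export
mi_config <- function(n_bins = 32, pyramid = c(4, 2, 1), max_iter = 100,
                      tol = 1e-5, step0 = 2, line_tol = 1e-3,
                      rot_scale = 180 / pi) {
  stopifnot(n_bins >= 8, max_iter >= 1, all(pyramid >= 1),
            pyramid[length(pyramid)] == 1)
  structure(list(n_bins = as.integer(n_bins), pyramid = as.integer(pyramid),
                 max_iter = as.integer(max_iter), tol = tol, step0 = step0,
                 line_tol = line_tol, rot_scale = rot_scale),
            class = "mi_config")
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information between a fixed and a transformed moving volume
#'
#' Resamples `moving` through the rigid transform onto `fixed`'s grid
#' (trilinear) and estimates the mutual information of the two intensity
#' distributions from their joint histogram with linear partial-volume bin
#' weighting. Only voxels where the transformed moving image has support
#' contribute. Returned in nats; non-negative up to estimator noise.
#'
#' @param fixed,moving `amypet_volume`s.
#' @param t `rigid_transform` mapping fixed world to moving world.
#' @param cfg an `mi_config`.
#' @return scalar MI in nats.
#' @export
mutual_information <- function(fixed, moving, t = rigid_transform(),
                               cfg = mi_config()) {
  mov <- resample_moving(moving, t, fixed, fill = NA_real_)
  mi_from_pair(as.double(fixed$values), as.double(mov$values), cfg$n_bins)
}

mi_from_pair <- function(fx, mv, n_bins) {
  ok <- is.finite(mv) & is.finite(fx)
  if (!any(ok)) stop("empty overlap between fixed and transformed moving image",
                     call. = FALSE)
  fx <- fx[ok]; mv <- mv[ok]
  rx <- range(fx); ry <- range(mv)
  if (rx[1] == rx[2]) rx[2] <- rx[1] + 1
  if (ry[1] == ry[2]) ry[2] <- ry[1] + 1
  h <- joint_hist_pv_cpp(fx, mv, n_bins, rx[1], rx[2], ry[1], ry[2])
  p <- h / sum(h)
  entropy_nats(rowSums(p)) + entropy_nats(colSums(p)) - entropy_nats(p)
}

#' Resample a moving volume through a rigid transform onto a reference grid
#'
#' For every voxel of `reference`, the world point is pushed through `t` into
#' moving-image world space and the moving image is interpolated there
#' (trilinear for intensities, nearest-neighbour for label maps); `fill`
#' outside the moving grid.
#'
#' @inheritParams mutual_information
#' @param reference volume whose grid and affine define the output.
#' @param fill out-of-support value (0 for air; `NA` to mark no-support).
#' @return resampled volume on `reference`'s grid, frame from `reference`.
#' @export
resample_moving <- function(moving, t, reference, fill = 0) {
  stopifnot(inherits(moving, "amypet_volume"),
            inherits(reference, "amypet_volume"),
            inherits(t, "rigid_transform"))
  M <- solve(moving$affine) %*% transform_matrix(t) %*% reference$affine
  nearest <- inherits(moving, "amypet_labelmap")
  out <- resample_affine_cpp(as.double(moving$values), dim(moving$values),
                             M[1:3, ], vol_dim(reference), nearest, fill)
  if (nearest) as_labelmap(out, reference$affine, frame = reference$frame)
  else as_volume(out, reference$affine, frame = reference$frame)
}

center_of_mass <- function(v) {
  w <- pmax(as.double(v$values), 0)
  s <- sum(w)
  d <- vol_dim(v)
  if (s == 0) {
    idx <- (d - 1) / 2
  } else {
    ax <- function(k) sum(slice_sums(w, d, k) * (seq_len(d[k]) - 1)) / s
    idx <- c(ax(1), ax(2), ax(3))
  }
  as.numeric(v$affine %*% c(idx, 1))[1:3]
}

slice_sums <- function(w, d, axis) {
  dim(w) <- d
  apply(w, axis, sum)
}

pyramid_level <- function(v, f) {
  if (f == 1) return(v)
  sig <- f / 2
  k <- gauss_kernel_1d(sig)
  sm <- as.double(v$values)
  for (ax in 0:2) sm <- conv3_axis_cpp(sm, vol_dim(v), k, ax)
  smv <- as_volume(sm, v$affine, frame = v$frame)
  S <- diag(c(f, f, f, 1))
  resample_to_grid(smv, v$affine %*% S,
                   pmax(1L, as.integer(floor((vol_dim(v) - 1) / f) + 1)),
                   method = "trilinear")
}

golden_section_max <- function(fun, lo, hi, tol_frac) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- fun(c1); f2 <- fun(c2)
  while ((b - a) > tol_frac * (hi - lo)) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- fun(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- fun(c1)
    }
  }
  s <- (a + b) / 2
  list(s = s, f = fun(s))
}

line_search <- function(fun, f0, step, tol_frac) {
  s1 <- step; f1 <- fun(s1)
  while (f1 <= f0 && s1 > step / 64) {
    s1 <- s1 / 2
    f1 <- fun(s1)
  }
  if (f1 <= f0) return(list(s = 0, f = f0))
  s2 <- 2 * s1; f2 <- fun(s2); n <- 0
  while (f2 > f1 && n < 20) {
    s1 <- s2; f1 <- f2
    s2 <- 2 * s2; f2 <- fun(s2)
    n <- n + 1
  }
  best <- golden_section_max(fun, 0, s2, tol_frac)
  if (best$f < f1) best <- list(s = s1, f = f1)
  best
}

#' Rigid PET-to-MRI registration by mutual-information ascent
#'
#' Finds the 6-parameter rigid transform (Euler x,y,z rotations about the
#' fixed image's centre of mass, plus translation) maximising the mutual
#' information of `fixed` against the resampled `moving` image. Optimisation
#' is steepest ascent on a finite-difference MI gradient, with each step
#' length chosen by bracketing (step doubling until the metric falls) followed
#' by golden-section line search, run coarse-to-fine over a multiresolution
#' pyramid. Initialised by aligning intensity centres of mass. Deterministic.
#' Non-convergence within `max_iter` is reported via `converged = FALSE`,
#' never an error.
#'
#' @inheritParams mutual_information
#' @return list with elements `transform` (`rigid_transform`), `mi` (final
#'   metric, nats), `converged` (logical), and `log` (tibble: pyramid level,
#'   iteration, MI, step length).
#' @export
register_rigid <- function(fixed, moving, cfg = mi_config()) {
  stopifnot(inherits(fixed, "amypet_volume"), inherits(moving, "amypet_volume"))
  center <- center_of_mass(fixed)
  init_t <- center_of_mass(moving) - center
  par <- c(0, 0, 0, init_t)          # rotations (rad), translation (mm)
  scales <- c(rep(cfg$rot_scale, 3), rep(1, 3))
  logs <- list()
  converged <- FALSE

  for (f in cfg$pyramid) {
    fx <- pyramid_level(fixed, f)
    mv <- pyramid_level(moving, f)
    fxv <- as.double(fx$values)
    objective <- function(p) {
      t <- rigid_transform(p[1:3] / scales[1:3], p[4:6], center)
      M <- solve(mv$affine) %*% transform_matrix(t) %*% fx$affine
      res <- resample_affine_cpp(as.double(mv$values), dim(mv$values),
                                 M[1:3, ], vol_dim(fx), FALSE, NA_real_)
      mi_from_pair(fxv, res, cfg$n_bins)
    }
    p <- par * scales
    fcur <- objective(p)
    h <- 0.1 * f
    converged <- FALSE
    for (it in seq_len(cfg$max_iter)) {
      g <- vapply(1:6, function(i) {
        e <- numeric(6); e[i] <- h
        (objective(p + e) - objective(p - e)) / (2 * h)
      }, numeric(1))
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) { converged <- TRUE; break }
      d <- g / gn
      ls <- line_search(function(s) objective(p + s * d), fcur,
                        cfg$step0 * f, cfg$line_tol)
      logs[[length(logs) + 1]] <- tibble::tibble(level = f, iter = it,
                                                 mi = ls$f, step = ls$s)
      gain <- ls$f - fcur
      p <- p + ls$s * d
      fcur <- ls$f
      if (gain < cfg$tol) { converged <- TRUE; break }
    }
    par <- p / scales
  }
  t_final <- rigid_transform(par[1:3], par[4:6], center)
  list(transform = t_final, mi = fcur, converged = converged,
       log = if (length(logs)) dplyr::bind_rows(logs)
             else tibble::tibble(level = integer(), iter = integer(),
                                 mi = double(), step = double()))
}
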