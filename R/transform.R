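#' 6-DOF rigid transforms
#'
#' A rigid transform is parameterised by three Euler angles (radians, applied
#' about the world x, then y, then z axis) and a translation, rotating about a
#' stated fixed `center` (world mm). Mapping of a world point p:
#' `R %*% (p - center) + center + translation`. In registration the transform
#' maps fixed-image (MRI) world coordinates into moving-image (PET) world
#' coordinates, the resampling convention.
#'
#' @param rotations numeric(3), Euler angles in radians (x, y, z order).
#' @param translation numeric(3), mm.
#' @param center numeric(3), world rotation centre in mm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(rotations = as.numeric(rotations),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

euler_matrix <- function(rot) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous 4x4 world-to-world matrix of a rigid transform
#' @param t a `rigid_transform`.
#' @return 4x4 matrix acting on world coordinates.
#' @export
transform_matrix <- function(t) {
  R <- euler_matrix(t$rotations)
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- t$center + t$translation - R %*% t$center
  A
}

#' Apply a rigid transform to world points
#' @param t a `rigid_transform`.
#' @param pts 3-row matrix (or numeric(3)) of world points.
#' @return transformed points, same shape.
#' @export
transform_points <- function(t, pts) {
  A <- transform_matrix(t)
  if (is.null(dim(pts))) pts <- matrix(pts, 3, 1)
  out <- A[1:3, 1:3] %*% pts + A[1:3, 4]
  if (ncol(out) == 1) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`, about the same centre.
#' @export
invert_transform <- function(t) {
  R <- euler_matrix(t$rotations)
  Ri <- t(R)
  # recover x,y,z Euler angles of the inverse rotation (Rz Ry Rx convention)
  rot <- matrix_to_euler(Ri)
  # solve for translation so that inverse(t)(t(p)) = p about the same centre
  A <- transform_matrix(t)
  Ainv <- solve(A)
  trans <- Ainv[1:3, 4] - t$center + Ri %*% t$center
  rigid_transform(rot, as.numeric(trans), t$center)
}

matrix_to_euler <- function(R) {
  # inverse of euler_matrix (R = Rz Ry Rx), gimbal-safe for |ry| < 90 deg
  ry <- asin(-R[3, 1])
  if (abs(cos(ry)) > 1e-10) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz)
}

#' Compose two rigid transforms
#' @param t2,t1 transforms; the result applies `t1` first, then `t2`.
#' @return the composed `rigid_transform`, about `t1`'s centre.
#' @export
compose_transforms <- function(t2, t1) {
  A <- transform_matrix(t2) %*% transform_matrix(t1)
  R <- A[1:3, 1:3]
  rot <- matrix_to_euler(R)
  trans <- A[1:3, 4] - t1$center + R %*% t1$center
  rigid_transform(rot, as.numeric(trans), t1$center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (deg) [%s]  trans (mm) [%s]  center [%s]\n",
    paste(sprintf("%.3f", x$rotations * 180 / pi), collapse = ", "),
    paste(sprintf("%.3f", x$translation), collapse = ", "),
    paste(sprintf("%.1f", x$center), collapse = ", ")))
  invisible(x)
}

#' Read / write a rigid transform as JSON
#'
#' Angles are stored in degrees, translation and centre in mm.
#'
#' @param t transform to write.
#' @param path JSON file path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(rotations_deg = t$rotations * 180 / pi,
                            translation_mm = t$translation,
                            center_mm = t$center),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotations_deg * pi / 180, x$translation_mm, x$center_mm)
}
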