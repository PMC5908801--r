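#' Rotation matrix for a ZYZ intrinsic Euler triple
#'
#' Returns the rotation `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)` mapping
#' reference-frame coordinates to imaging-frame coordinates
#' (`r_img = R %*% r_ref`). The beam travels along +z of the imaging frame,
#' so the third row of `R` projects a reference-frame position onto the
#' beam axis — the quantity that converts a block centre into a defocus
#' offset.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return 3 x 3 orthonormal matrix.
#' @export
euler_matrix <- function(rot, tilt, psi) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(psi) %*% ry(tilt) %*% rz(rot)
}

#' Euler angles of a rotation matrix
#'
#' Inverse of [euler_matrix()]: decomposes an orthonormal matrix into the
#' ZYZ triple with `tilt` in \[0, 180\]. At the gimbal-locked poles
#' (`tilt` 0 or 180) `rot` is set to 0 and the in-plane angle absorbed
#' into `psi`.
#'
#' @param R 3 x 3 rotation matrix.
#' @return Named numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
euler_from_matrix <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct)
  if (sin(tilt) > 1e-8) {
    psi <- atan2(R[2, 3], R[1, 3])
    rot <- atan2(R[3, 2], -R[3, 1])
  } else {
    rot <- 0
    # R reduces to Rz(psi + rot) (tilt ~ 0) or Rz(psi - rot) mirrored
    psi <- atan2(R[2, 1], R[1, 1])
    if (ct < 0) psi <- atan2(-R[2, 1], -R[1, 1])
  }
  deg <- 180 / pi
  c(rot = rot * deg %% 360, tilt = tilt * deg,
    psi = psi * deg %% 360)
}

#' Quasi-uniform Euler-angle coverage of the sphere
#'
#' Generates projection directions on a Fibonacci spiral so that
#' neighbouring directions are separated by roughly `step_deg` degrees
#' (the direction count scales as `4*pi/step^2`), optionally crossed with
#' in-plane rotations sampled at the same step. Poles are included in the
#' returned set.
#'
#' @param step_deg angular step in degrees.
#' @param inplane if `TRUE` (default) every direction is repeated for each
#'   in-plane angle `psi` in `seq(0, 360 - step, step)`; if `FALSE`,
#'   `psi = 0` throughout.
#' @return A data.frame with columns `rot`, `tilt`, `psi` (degrees).
#' @export
euler_coverage <- function(step_deg, inplane = TRUE) {
  if (step_deg <= 0 || step_deg > 180)
    stop("step_deg must lie in (0, 180]", call. = FALSE)
  step <- step_deg * pi / 180
  n <- max(2L, as.integer(ceiling(4 * pi / step^2)))
  i <- seq_len(n)
  # Fibonacci lattice on the sphere; endpoints nudged to include the poles
  z <- 1 - 2 * (i - 1) / (n - 1)
  golden <- pi * (3 - sqrt(5))
  az <- ((i - 1) * golden) %% (2 * pi)
  tilt <- acos(pmax(-1, pmin(1, z))) * 180 / pi
  rot <- az * 180 / pi
  if (inplane) {
    psi <- seq(0, 360 - step_deg, by = step_deg)
    out <- expand.grid(k = i, psi = psi)
    data.frame(rot = rot[out$k], tilt = tilt[out$k], psi = out$psi)
  } else {
    data.frame(rot = rot, tilt = tilt, psi = 0)
  }
}

#' Rotate a volume into the imaging frame of an Euler triple
#'
#' Trilinearly resamples `vol` so that the output z axis is the beam axis
#' of the orientation: `out(x) = vol(R^T (x - c) + c)` with `c` the grid
#' centre `N/2`.
#'
#' @param vol a [volume_grid()].
#' @param euler numeric length-3 `(rot, tilt, psi)` in degrees.
#' @return A [volume_grid()] of the same size.
#' @export
rotate_volume <- function(vol, euler) {
  R <- euler_matrix(euler[1], euler[2], euler[3])
  out <- cpp_affine_resample(vol$data, t(R))
  volume_grid(out, vol$voxel_size, vol$origin)
}
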