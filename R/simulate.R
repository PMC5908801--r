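#' Pseudo-atom density phantom
#'
#' Builds a synthetic protein-like density as a sum of isotropic Gaussian
#' blobs placed uniformly at random inside a sphere of the requested
#' diameter, then hard-masked at that diameter so the support invariant
#' (zero density outside radius t/2) holds exactly. Deterministic for a
#' given seed.
#'
#' @param diameter object diameter t in Angstrom; must fit in 80% of the
#'   box extent.
#' @param n_atoms number of Gaussian pseudo-atoms.
#' @param voxel_size Angstrom per voxel.
#' @param box cubic box side in voxels (even).
#' @param seed integer RNG seed.
#' @param sigma blob standard deviation in Angstrom (default one voxel,
#'   which keeps signal in the Thon-ring fitting band).
#' @return An object of class `phantom`: list with `volume`
#'   (a [volume_grid()]), `diameter` and `seed`.
#' @export
make_phantom <- function(diameter, n_atoms, voxel_size, box, seed = 1,
                         sigma = voxel_size) {
  if (diameter > 0.8 * box * voxel_size)
    stop("phantom diameter exceeds 80% of the box extent", call. = FALSE)
  vol <- array(0, c(box, box, box))
  if (n_atoms > 0) {
    set.seed(seed)
    # rejection-sample uniform points in the sphere, kept 3 sigma inside
    rmax <- diameter / 2 - 3 * sigma
    if (rmax <= 0) stop("diameter too small for blob sigma", call. = FALSE)
    pts <- matrix(numeric(0), 0, 3)
    while (nrow(pts) < n_atoms) {
      cand <- matrix(runif(3 * n_atoms * 2, -rmax, rmax), ncol = 3)
      cand <- cand[rowSums(cand^2) <= rmax^2, , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts <- pts[seq_len(n_atoms), , drop = FALSE]
    ctr <- box %/% 2
    half <- ceiling(4 * sigma / voxel_size)
    ax <- seq(-half, half)
    g1 <- function(d) exp(-(d * voxel_size)^2 / (2 * sigma^2))
    for (a in seq_len(n_atoms)) {
      v <- pts[a, ] / voxel_size + ctr      # 0-based voxel position
      i0 <- round(v)
      ix <- i0[1] + ax; iy <- i0[2] + ax; iz <- i0[3] + ax
      gx <- g1(ix - v[1]); gy <- g1(iy - v[2]); gz <- g1(iz - v[3])
      blob <- outer(outer(gx, gy), gz)
      vol[ix + 1, iy + 1, iz + 1] <- vol[ix + 1, iy + 1, iz + 1] + blob
    }
    # enforce zero support outside the sphere
    ax <- (seq_len(box) - 1 - ctr) * voxel_size
    r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
    vol[r2 > (diameter / 2)^2] <- 0
  }
  structure(list(volume = volume_grid(vol, voxel_size),
                 diameter = diameter, seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> t = %g A in ", x$diameter))
  print(x$volume)
  invisible(x)
}

as_volume <- function(x) {
  if (inherits(x, "phantom")) x$volume
  else if (inherits(x, "volume_grid")) x
  else stop("expected a phantom or volume_grid", call. = FALSE)
}

#' Simulation settings for a depth-of-field dataset
#'
#' @param layer_thickness slab thickness along the beam in Angstrom
#'   (default 20 A; the object is split into ~2 nm layers, each with its
#'   own defocus and CTF).
#' @param defocus_range particle-defocus sampling range in Angstrom
#'   (default 1.0 to 3.0 um).
#' @param euler_step angular step of the projection-direction coverage in
#'   degrees.
#' @param inplane whether to sample the in-plane angle at the same step
#'   (see [euler_coverage()]).
#' @param noise_sigma additive Gaussian noise level as a fraction of each
#'   image's RMS (0 = noise free).
#' @param hand_sign simulation handedness: +1 means defocus increases
#'   along +z of the imaging frame (beam direction).
#' @param seed RNG seed for defocus draws and noise.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(layer_thickness = 20,
                              defocus_range = c(10000, 30000),
                              euler_step = 15, inplane = FALSE,
                              noise_sigma = 0, hand_sign = 1, seed = 1) {
  if (layer_thickness <= 0) stop("layer_thickness must be > 0", call. = FALSE)
  if (diff(defocus_range) < 0)
    stop("defocus_range must be increasing", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(layer_thickness = layer_thickness,
                 defocus_range = defocus_range, euler_step = euler_step,
                 inplane = inplane, noise_sigma = noise_sigma,
                 hand_sign = hand_sign, seed = seed),
            class = "simulation_config")
}

#' Single-defocus (flat) image simulation
#'
#' The no-depth-of-field control: projects the rotated volume along the
#' beam axis and applies one CTF at the given defocus to the whole
#' projection.
#'
#' @param phantom a `phantom` or [volume_grid()].
#' @param euler `(rot, tilt, psi)` in degrees.
#' @param defocus defocus in Angstrom.
#' @param optics an [optics_model()].
#' @return Numeric matrix (the simulated image).
#' @export
simulate_image_flat <- function(phantom, euler, defocus, optics) {
  vol <- as_volume(phantom)
  rot <- rotate_volume(vol, euler)
  proj <- rowSums(rot$data, dims = 2)
  ctf <- ctf_2d(optics, defocus, nrow(proj))
  Re(stats::fft(stats::fft(proj) * ctf, inverse = TRUE)) / length(proj)
}

#' Depth-of-field (layered) image simulation
#'
#' Rotates the volume into the imaging frame, slices it into slabs of
#' `layer_thickness` along the beam axis, projects each slab, applies to
#' each slab the CTF of its own local defocus
#' `defocus + hand_sign * z_slab` (z in Angstrom from the volume centre),
#' and sums the filtered projections. With a single slab this reduces to
#' [simulate_image_flat()].
#'
#' @inheritParams simulate_image_flat
#' @param particle_defocus defocus of the plane through the volume centre,
#'   Angstrom, > 0.
#' @param layer_thickness slab thickness in Angstrom (> 0).
#' @param hand_sign +1 if defocus grows along +z (the default convention),
#'   -1 for the mirrored hand.
#' @return Numeric matrix (the simulated image).
#' @export
simulate_image_layered <- function(phantom, euler, particle_defocus, optics,
                                   layer_thickness = 20, hand_sign = 1) {
  if (layer_thickness <= 0)
    stop("layer_thickness must be > 0", call. = FALSE)
  vol <- as_volume(phantom)
  n <- dim(vol$data)[1]
  vx <- vol$voxel_size
  rot <- rotate_volume(vol, euler)$data
  # plane heights symmetric about the volume mid-plane, so slab centres are
  # symmetric and a single slab sits exactly at the particle defocus
  z <- (seq_len(n) - 1 - (n - 1) / 2) * vx
  slab <- floor((z - z[1]) / layer_thickness * (1 - 1e-12))
  acc <- matrix(0 + 0i, n, n)
  for (sid in unique(slab)) {
    idx <- which(slab == sid)
    proj <- rowSums(rot[, , idx, drop = FALSE], dims = 2)
    if (max(abs(proj)) == 0) next
    zc <- (min(z[idx]) + max(z[idx])) / 2     # mid-plane of covered extent
    ctf <- ctf_2d(optics, particle_defocus + hand_sign * zc, n)
    acc <- acc + stats::fft(proj) * ctf
  }
  Re(stats::fft(acc, inverse = TRUE)) / (n * n)
}

#' Simulate a full depth-of-field dataset
#'
#' One layered image per Euler triple of the angular coverage, each with a
#' particle defocus drawn uniformly from the configured range. Noise, when
#' requested, is additive Gaussian with standard deviation
#' `noise_sigma * RMS(image)`. Bit-reproducible for a fixed seed.
#'
#' @param phantom a `phantom` or [volume_grid()].
#' @param config a [simulation_config()].
#' @param optics an [optics_model()].
#' @return List with `stack` (an [image_stack()]) and `table`
#'   (a [particle_table()] carrying the true parameters).
#' @export
simulate_dataset <- function(phantom, config, optics) {
  vol <- as_volume(phantom)
  n <- dim(vol$data)[1]
  cov <- euler_coverage(config$euler_step, config$inplane)
  m <- nrow(cov)
  set.seed(config$seed)
  defoci <- runif(m, config$defocus_range[1], config$defocus_range[2])
  data <- array(0, c(n, n, m))
  for (i in seq_len(m)) {
    img <- simulate_image_layered(vol, as.numeric(cov[i, ]), defoci[i],
                                  optics, config$layer_thickness,
                                  config$hand_sign)
    if (config$noise_sigma > 0)
      img <- img + rnorm(length(img),
                         sd = config$noise_sigma * sqrt(mean(img^2)))
    data[, , i] <- img
  }
  list(stack = image_stack(data, vol$voxel_size),
       table = particle_table(rot = cov$rot, tilt = cov$tilt, psi = cov$psi,
                              shift_x = 0, shift_y = 0, defocus = defoci,
                              hand_sign = config$hand_sign))
}
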