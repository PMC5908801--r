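# Direct Fourier-inversion reconstruction: each image's FT is a central
# section of the object's 3D FT (Central Projection Theorem). Sections are
# spread into a padded 3D grid with a trilinear kernel, data weighted by the
# CTF (which both phase-flips and amplitude-weights) and weights by CTF^2,
# then normalised by a Wiener-regularised division.

#' Create an empty Fourier accumulator
#'
#' @param box reconstruction box side in voxels (the unpadded output size).
#' @param voxel_size Angstrom per voxel.
#' @param pad_factor zero-padding factor (>= 1) applied before insertion;
#'   padding refines the Fourier sampling under the trilinear kernel.
#' @return An environment of class `fourier_accumulator` holding the
#'   complex sum grids, the weight grid and the insertion count.
#' @export
fourier_accumulator <- function(box, voxel_size, pad_factor = 2) {
  if (pad_factor < 1) stop("pad_factor must be >= 1", call. = FALSE)
  p <- as.integer(round(box * pad_factor))
  if (p %% 2L) p <- p + 1L
  acc <- new.env(parent = emptyenv())
  acc$box <- as.integer(box)
  acc$p <- p
  acc$voxel_size <- voxel_size
  acc$sre <- array(0, c(p, p, p))
  acc$sim <- array(0, c(p, p, p))
  acc$wt <- array(0, c(p, p, p))
  acc$n_inserted <- 0L
  class(acc) <- "fourier_accumulator"
  acc
}

# checkerboard (-1)^(i+j[+k]) on unshifted FFT indices: multiplying an FT by
# it translates real space by half the box, i.e. moves the box centre to the
# array origin and back
checkerboard_2d <- function(p) {
  v <- rep_len(c(1, -1), p)
  outer(v, v)
}

# phase ramp undoing an origin shift of (sx, sy) pixels
shift_ramp <- function(p, sx, sy) {
  h <- c(seq(0, p %/% 2), seq(-(p - p %/% 2 - 1), -1))
  exp(2i * pi * (outer(h * sx, h * 0, `+`) + outer(h * 0, h * sy, `+`)) / p)
}

# pad an image into the centre of a p x p box and return the origin-phased FT
padded_image_ft <- function(image, p) {
  n <- nrow(image)
  pad <- matrix(0, p, p)
  off <- p %/% 2L - n %/% 2L
  pad[off + seq_len(n), off + seq_len(n)] <- image
  stats::fft(pad) * checkerboard_2d(p)
}

#' Insert one oriented image into a Fourier accumulator
#'
#' The image is zero-padded, its FT phase-shifted so the particle centre
#' sits at the origin (including the record's origin shift), multiplied by
#' the CTF and spread onto the central-section plane of the orientation
#' with a trilinear kernel; the weight grid accumulates CTF^2.
#'
#' @param acc a [fourier_accumulator()].
#' @param image square numeric matrix.
#' @param euler `(rot, tilt, psi)` degrees.
#' @param shift `(dx, dy)` origin shift in Angstrom (particle centre =
#'   box centre + shift).
#' @param ctf CTF matrix on the padded grid (`acc$p` x `acc$p`), or a
#'   single number for an idealised constant transfer (e.g. 1).
#' @return The accumulator, invisibly (modified in place).
#' @export
insert_slice <- function(acc, image, euler, shift = c(0, 0), ctf = 1) {
  p <- acc$p
  ft <- padded_image_ft(image, p)
  if (any(shift != 0))
    ft <- ft * shift_ramp(p, shift[1] / acc$voxel_size,
                          shift[2] / acc$voxel_size)
  if (length(ctf) == 1L) ctf <- matrix(ctf, p, p)
  R <- euler_matrix(euler[1], euler[2], euler[3])
  cpp_insert_slice(acc$sre, acc$sim, acc$wt, Re(ft), Im(ft), ctf, R)
  acc$n_inserted <- acc$n_inserted + 1L
  invisible(acc)
}

#' Finalise a Fourier accumulator into a volume
#'
#' Divides the accumulated data by the accumulated weights with a Wiener
#' floor, inverse-transforms and crops the padding.
#'
#' @param acc a [fourier_accumulator()].
#' @param wiener_floor regularisation constant added to the weights,
#'   expressed as a fraction of the maximum weight (default 0.01).
#' @return A [volume_grid()] of side `acc$box`.
#' @export
finalize_volume <- function(acc, wiener_floor = 0.01) {
  p <- acc$p
  wmax <- max(acc$wt)
  floor_abs <- if (wmax > 0) wiener_floor * wmax else 1
  fk <- complex(real = acc$sre, imaginary = acc$sim) / (acc$wt + floor_abs)
  dim(fk) <- c(p, p, p)
  v <- rep_len(c(1, -1), p)
  chk <- outer(outer(v, v), v)
  vol <- Re(stats::fft(fk * chk, inverse = TRUE)) / length(fk)
  n <- acc$box
  idx <- (p %/% 2L - n %/% 2L) + seq_len(n)
  volume_grid(vol[idx, idx, idx], acc$voxel_size)
}

# map a defocus-source keyword to a per-record defocus vector
defocus_column <- function(table, defocus_source) {
  col <- switch(defocus_source,
                particle = "defocus",
                true = "defocus",
                measured = "measured_defocus",
                local = "local_defocus",
                stop("unknown defocus_source: ", defocus_source,
                     call. = FALSE))
  if (!col %in% names(table))
    stop("particle table has no '", col, "' column", call. = FALSE)
  table[[col]]
}

#' Reconstruct a volume from oriented CTF-affected images
#'
#' Loops [insert_slice()] over all records of the particle table using the
#' chosen defocus per image and finalises with a Wiener-regularised
#' division.
#'
#' @param stack an [image_stack()].
#' @param table a [particle_table()]; `image_index` selects the stack
#'   image for each record (several records may share an image, as after
#'   symmetry expansion).
#' @param optics an [optics_model()].
#' @param defocus_source `"particle"` (the true/assigned particle
#'   defocus), `"measured"` (Thon-ring fit, column `measured_defocus`) or
#'   `"local"` (per-block local mean defocus, column `local_defocus`).
#' @param pad_factor,wiener_floor see [fourier_accumulator()] and
#'   [finalize_volume()].
#' @return A [volume_grid()].
#' @export
reconstruct <- function(stack, table, optics, defocus_source = "particle",
                        pad_factor = 2, wiener_floor = 0.01) {
  if (nrow(table) == 0) stop("empty particle table", call. = FALSE)
  defoci <- defocus_column(table, defocus_source)
  if (anyNA(defoci)) stop("NA defocus in particle table", call. = FALSE)
  n <- dim(stack$data)[1]
  acc <- fourier_accumulator(n, stack$voxel_size, pad_factor)
  for (i in seq_len(nrow(table))) {
    rec <- table[i, ]
    ctf <- ctf_2d_cached(optics, defoci[i], acc$p)
    insert_slice(acc, stack$data[, , rec$image_index],
                 c(rec$rot, rec$tilt, rec$psi),
                 c(rec$shift_x, rec$shift_y), ctf)
  }
  finalize_volume(acc, wiener_floor)
}

# CTF grids at the padded size are often reused across records with nearly
# identical defocus; memoise the most recent few
ctf_cache <- new.env(parent = emptyenv())
ctf_2d_cached <- function(optics, defocus, shape) {
  key <- sprintf("%.3f|%.6f|%.3f|%d", defocus, optics$wavelength,
                 optics$pixel_size, shape)
  val <- ctf_cache[[key]]
  if (is.null(val)) {
    if (length(ls(ctf_cache)) > 32) rm(list = ls(ctf_cache), envir = ctf_cache)
    val <- ctf_2d(optics, defocus, shape)
    ctf_cache[[key]] <- val
  }
  val
}

#' Depth-of-field resolution-limit experiment
#'
#' Generates a noise-free layered dataset of a pseudo-atom phantom of the
#' given diameter, reconstructs it conventionally (single defocus per
#' particle) with the known orientations, and reads the FSC-0.5 resolution
#' against the phantom. Because images are noise free and orientations
#' exact, the read-out isolates the depth-of-field (Ewald sphere) limit.
#'
#' @param diameter phantom diameter t in Angstrom.
#' @param optics an [optics_model()]; `pixel_size` sets the scale.
#' @param box simulation box in voxels.
#' @param euler_step angular step of the coverage in degrees.
#' @param layer_thickness simulator slab thickness in Angstrom.
#' @param defocus_mode `"true"` uses the assigned particle defoci;
#'   `"measured"` fits each image's defocus from its Thon rings first.
#' @param flat if `TRUE` simulate without depth of field (control run).
#' @param n_atoms pseudo-atoms in the phantom.
#' @param seed RNG seed.
#' @return Resolution in Angstrom at FSC threshold 0.5; the FSC curve is
#'   attached as attribute `"fsc"`.
#' @export
limit_experiment <- function(diameter, optics, box = 96, euler_step = 15,
                             layer_thickness = 20,
                             defocus_mode = c("true", "measured"),
                             flat = FALSE, n_atoms = 400, seed = 1) {
  defocus_mode <- match.arg(defocus_mode)
  vx <- optics$pixel_size
  ph <- make_phantom(diameter, n_atoms, vx, box, seed = seed)
  cfg <- simulation_config(layer_thickness =
                             if (flat) box * vx * 2 else layer_thickness,
                           euler_step = euler_step, inplane = FALSE,
                           seed = seed)
  ds <- simulate_dataset(ph, cfg, optics)
  if (defocus_mode == "measured") {
    rng <- cfg$defocus_range + c(-2000, 2000)
    ds$table$measured_defocus <- vapply(seq_len(nrow(ds$table)), function(i)
      fit_defocus(ds$stack$data[, , i], optics, rng[1], rng[2], step = 100),
      numeric(1))
  }
  rec <- reconstruct(ds$stack, ds$table, optics,
                     defocus_source = if (defocus_mode == "measured")
                       "measured" else "particle")
  curve <- fsc(rec, ph$volume)
  res <- resolution_at(curve, 0.5)
  attr(res, "fsc") <- curve
  res
}
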