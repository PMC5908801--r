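#' Cubic density volume
#'
#' A real-valued N x N x N density grid with a physical voxel size. The
#' rotation/FFT centre used throughout the package is the integer voxel
#' `N/2` in 0-based coordinates (the usual FFT-centre convention), and
#' voxel `(0,0,0)` is the array origin.
#'
#' @param data numeric 3D array, cubic with even side length.
#' @param voxel_size voxel edge length in Angstrom per pixel (> 0).
#' @param origin optional physical origin (Angstrom, length 3); defaults to
#'   minus the grid centre so that the rotation centre sits at (0,0,0).
#' @return An object of class `volume_grid` with fields `data`, `voxel_size`
#'   and `origin`.
#' @export
volume_grid <- function(data, voxel_size, origin = NULL) {
  d <- dim(data)
  if (length(d) != 3L || d[1] != d[2] || d[1] != d[3])
    stop("volume must be a cubic 3D array", call. = FALSE)
  if (d[1] %% 2L != 0L)
    stop("volume side length must be even", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be a single positive finite number", call. = FALSE)
  if (is.null(origin)) origin <- rep(-(d[1] %/% 2L) * voxel_size, 3L)
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("<volume_grid> %d^3 voxels, %.4g A/px (%.4g A extent)\n",
              n, x$voxel_size, n * x$voxel_size))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Stack of square particle images
#'
#' @param data numeric N x N x M array (M images of N x N pixels), or a
#'   single N x N matrix.
#' @param voxel_size pixel size in Angstrom per pixel.
#' @return An object of class `image_stack` with fields `data` and
#'   `voxel_size`.
#' @export
image_stack <- function(data, voxel_size) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  d <- dim(data)
  if (length(d) != 3L || d[1] != d[2])
    stop("stack must be an N x N x M array of square images", call. = FALSE)
  if (d[3] < 1L) stop("stack must contain at least one image", call. = FALSE)
  if (!is.numeric(voxel_size) || voxel_size <= 0 || !is.finite(voxel_size))
    stop("voxel_size must be positive and finite", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d images of %d x %d px, %.4g A/px\n",
              d[3], d[1], d[2], x$voxel_size))
  invisible(x)
}

#' @export
length.image_stack <- function(x) dim(x$data)[3]

#' Extract one image from a stack
#' @param stack an [image_stack()].
#' @param i image index (1-based).
#' @return numeric matrix.
#' @export
stack_image <- function(stack, i) stack$data[, , i]

#' Particle metadata table
#'
#' One row per particle image: ZYZ intrinsic Euler angles (degrees), 2D
#' origin shift (Angstrom), particle defocus (Angstrom, underfocus
#' positive) and the handedness sign relating the beam axis to increasing
#' defocus. Extra columns (measured or local defocus, block and symmetry
#' bookkeeping) are carried along and survive STAR round trips.
#'
#' @param rot,tilt,psi Euler angles in degrees; `tilt` must lie in
#'   \[0, 180\].
#' @param shift_x,shift_y origin shifts in Angstrom (the particle centre
#'   sits at the box centre plus the shift).
#' @param defocus particle defocus in Angstrom, underfocus positive.
#' @param hand_sign +1 or -1 per record.
#' @param image_index 1-based index into the companion image stack.
#' @param ... further equal-length annotation columns.
#' @return A `data.frame` of class `particle_table`.
#' @export
particle_table <- function(rot, tilt, psi, shift_x = 0, shift_y = 0,
                           defocus = NA_real_, hand_sign = 1L,
                           image_index = seq_along(rot), ...) {
  tbl <- data.frame(image_index = image_index, rot = rot, tilt = tilt,
                    psi = psi, shift_x = shift_x, shift_y = shift_y,
                    defocus = defocus, hand_sign = hand_sign, ...)
  validate_particle_table(tbl)
}

required_particle_cols <- c("image_index", "rot", "tilt", "psi",
                            "shift_x", "shift_y", "defocus", "hand_sign")

validate_particle_table <- function(tbl) {
  missing <- setdiff(required_particle_cols, names(tbl))
  if (length(missing))
    stop("particle table lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(tbl$tilt < 0 | tbl$tilt > 180))
    stop("tilt angles must lie in [0, 180] degrees", call. = FALSE)
  if (!all(tbl$hand_sign %in% c(-1, 1)))
    stop("hand_sign must be +1 or -1", call. = FALSE)
  class(tbl) <- unique(c("particle_table", class(tbl)))
  tbl
}

#' Electron-optical model
#'
#' Holds the microscope parameters entering the contrast transfer function.
#' The relativistic electron wavelength is derived from the acceleration
#' voltage unless `wavelength` is given explicitly; an explicit wavelength
#' is treated as a free parameter, which permits scaled-down studies of the
#' depth-of-field effect in small boxes.
#'
#' @param voltage acceleration voltage in kV.
#' @param cs spherical aberration in mm.
#' @param amplitude_contrast amplitude contrast fraction in \[0, 1).
#' @param pixel_size pixel size in Angstrom per pixel.
#' @param wavelength optional electron wavelength in Angstrom, overriding
#'   the value derived from `voltage`.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(voltage = 300, cs = 2.7, amplitude_contrast = 0.07,
                         pixel_size = 1, wavelength = NULL) {
  if (is.null(wavelength)) wavelength <- electron_wavelength(voltage)
  if (wavelength <= 0) stop("wavelength must be positive", call. = FALSE)
  if (amplitude_contrast < 0 || amplitude_contrast >= 1)
    stop("amplitude_contrast must lie in [0, 1)", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  structure(list(voltage = voltage, wavelength = wavelength, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "optics_model")
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf(
    "<optics_model> %g kV (lambda %.5f A), Cs %g mm, A %.3f, %.4g A/px\n",
    x$voltage, x$wavelength, x$cs, x$amplitude_contrast, x$pixel_size))
  invisible(x)
}
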