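#' Empirical depth-of-field resolution limit
#'
#' For an object of thickness `t` imaged with electrons of wavelength
#' `lambda`, the attainable spatial frequency under the flat-Ewald-sphere
#' approximation is `d ~ sqrt(2 / (t lambda))`. Note `d` is a frequency
#' (1/Angstrom); this function returns the corresponding real-space
#' resolution `1/d = sqrt(t lambda / 2)` in Angstrom, the convention used
#' for FSC read-outs. Both are printed by the CLI `limit` command.
#'
#' @param t object thickness along the beam in Angstrom (for globular
#'   particles, the diameter).
#' @param voltage acceleration voltage in kV; ignored when `wavelength`
#'   is given.
#' @param wavelength optional electron wavelength in Angstrom (overrides
#'   `voltage`).
#' @return Resolution limit in Angstrom (larger = worse).
#' @examples
#' empirical_limit(1200, 300)  # ~3.4 A for a 120 nm capsid at 300 kV
#' @export
empirical_limit <- function(t, voltage = 300, wavelength = NULL) {
  if (any(t <= 0)) stop("thickness t must be positive", call. = FALSE)
  if (is.null(wavelength)) wavelength <- electron_wavelength(voltage)
  sqrt(t * wavelength / 2)
}

#' Determine map handedness from block reconstructions
#'
#' Runs the block-based reconstruction twice, once adding and once
#' subtracting the per-block beam-axis defocus offsets, and returns the
#' sign whose map resolves finer against the reference. With the wrong
#' sign the local mean defoci are systematically off by twice the offset,
#' which degrades the map; with little depth-of-field effect (small
#' objects) the two maps are equivalent and the test is indeterminate.
#'
#' @param stack an [image_stack()].
#' @param table a [particle_table()].
#' @param block_set a [block_set()].
#' @param optics an [optics_model()].
#' @param reference a [volume_grid()] to compare against (e.g. a previous
#'   reconstruction or, in simulations, the model).
#' @param threshold FSC threshold for the resolution read-out.
#' @param ... passed to [block_reconstruct()].
#' @return `+1` or `-1`; `NA_integer_` with a warning when the two
#'   resolutions fall within one Fourier shell of each other
#'   (indeterminate). The per-sign resolutions are attached as attribute
#'   `"resolutions"`.
#' @export
handedness_test <- function(stack, table, block_set, optics, reference,
                            threshold = 0.5, ...) {
  res <- vapply(c(1, -1), function(h) {
    tbl <- table
    tbl$hand_sign <- h
    map <- block_reconstruct(stack, tbl, block_set, optics, ...)
    resolution_at(fsc(map, reference), threshold)
  }, numeric(1))
  names(res) <- c("+1", "-1")
  n <- dim(stack$data)[1]
  shell <- 1 / (n * stack$voxel_size)
  out <- if (abs(1 / res[1] - 1 / res[2]) < shell) {
    warning("handedness indeterminate: resolutions within one shell",
            call. = FALSE)
    NA_integer_
  } else if (res[1] < res[2]) 1L else -1L
  attr(out, "resolutions") <- res
  out
}
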