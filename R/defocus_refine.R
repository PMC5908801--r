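# Cooperative per-particle defocus refinement. Because the blocks of one
# particle share a single unknown (the particle defocus PDF_i; their local
# defoci differ only by the geometric offsets LDFV_ij, which are known from
# the orientation), the defocus can be scanned over a grid and scored by
# the summed phase agreement between phase-flipped sub-images and block
# projections -- no Ewald-corrected projector is required.

#' Defocus search settings
#'
#' @param range total search span in Angstrom (candidates cover
#'   current +/- range/2); default 2000 A (200 nm).
#' @param step grid step in Angstrom; default 100 A (10 nm).
#' @param band frequency band (1/Angstrom) over which phase residuals are
#'   evaluated; default `c(1/20, 1/6)`. Very low frequencies carry no
#'   defocus information and near-Nyquist terms are noise dominated.
#' @return A list of class `defocus_search_config`.
#' @export
defocus_search_config <- function(range = 2000, step = 100,
                                  band = c(1 / 20, 1 / 6)) {
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (range < step) stop("range must be >= step", call. = FALSE)
  structure(list(range = range, step = step, band = band),
            class = "defocus_search_config")
}

# band mask + |CTF| weights on the unshifted FFT grid of an n x n image
band_mask <- function(n, pixel_size, band) {
  f <- fft_freq(n, pixel_size)
  s <- sqrt(outer(f^2, f^2, `+`))
  s >= band[1] & s <= band[2]
}

#' Phase residual between a sub-image and a block projection
#'
#' The sub-image is phase-flipped with the CTF at the candidate local
#' defocus and compared with the projection of the block volume: the
#' residual is the |CTF|-weighted mean cosine of the per-pixel Fourier
#' phase difference inside the band,
#' `PR = sum(w cos(dtheta)) / sum(w)`, `w = |CTF|`. A perfect match gives
#' +1, a contrast-inverted match -1, unrelated images ~0.
#'
#' @param sub_image square numeric matrix (one extracted block image).
#' @param block_volume a [volume_grid()] of the block.
#' @param euler `(rot, tilt, psi)` degrees.
#' @param shift residual origin shift `(dx, dy)` in Angstrom.
#' @param local_defocus candidate LDF_ij in Angstrom.
#' @param optics an [optics_model()].
#' @param band frequency band in 1/Angstrom.
#' @param fproj optional precomputed `fft(projection)` (performance path
#'   for scans over many candidate defoci).
#' @return PR_ij in \[-1, 1\].
#' @export
phase_residual_block <- function(sub_image, block_volume, euler, shift,
                                 local_defocus, optics,
                                 band = c(1 / 20, 1 / 6), fproj = NULL) {
  n <- nrow(sub_image)
  vx <- optics$pixel_size
  if (is.null(fproj)) {
    proj <- rowSums(cpp_affine_resample(
      block_volume$data, t(euler_matrix(euler[1], euler[2], euler[3]))),
      dims = 2)
    if (max(abs(proj)) == 0)
      stop("all-zero block projection: phase undefined", call. = FALSE)
    fproj <- stats::fft(proj)
  }
  ctf <- ctf_2d(optics, local_defocus, n)
  fimg <- phase_flip(stats::fft(sub_image), ctf) *
    shift_ramp(n, shift[1] / vx, shift[2] / vx)
  mask <- band_mask(n, vx, band)
  mi <- Mod(fimg); mp <- Mod(fproj)
  ok <- mask & mi > 1e-12 * max(mi) & mp > 1e-12 * max(mp)
  if (!any(ok))
    stop("no usable Fourier pixels in the phase-residual band",
         call. = FALSE)
  cosd <- Re(fimg[ok] * Conj(fproj[ok])) / (mi[ok] * mp[ok])
  w <- abs(ctf[ok])
  if (sum(w) == 0) return(0)
  sum(w * cosd) / sum(w)
}

#' Summed phase residual of one particle at a candidate defocus
#'
#' Computes `LDF_ij = PDF_candidate + LDFV_ij` for every block sub-record
#' of the particle (including symmetry copies) and sums the per-block
#' phase residuals: `PR_i = sum_j PR_ij`.
#'
#' @param block_data list with one element per block, each a list
#'   `(stack, table)` from [extract_block_images()]; tables must carry
#'   `particle_id` and `ldfv` columns.
#' @param block_volumes list of block [volume_grid()]s.
#' @param particle_id particle identifier within the tables.
#' @param pdf_candidate candidate particle defocus in Angstrom.
#' @param optics an [optics_model()].
#' @param band frequency band in 1/Angstrom.
#' @param proj_cache optional list (parallel to `block_data`) of lists of
#'   precomputed projection FTs per sub-record row.
#' @return PR_i (sum over blocks and symmetry copies).
#' @export
particle_phase_residual <- function(block_data, block_volumes, particle_id,
                                    pdf_candidate, optics,
                                    band = c(1 / 20, 1 / 6),
                                    proj_cache = NULL) {
  pr <- 0
  for (j in seq_along(block_data)) {
    tbl <- block_data[[j]]$table
    rows <- which(tbl$particle_id == particle_id)
    for (r in rows) {
      rec <- tbl[r, ]
      fp <- if (!is.null(proj_cache)) proj_cache[[j]][[as.character(r)]]
      pr <- pr + phase_residual_block(
        block_data[[j]]$stack$data[, , rec$image_index], block_volumes[[j]],
        c(rec$rot, rec$tilt, rec$psi), c(rec$shift_x, rec$shift_y),
        pdf_candidate + rec$ldfv, optics, band, fproj = fp)
    }
  }
  pr
}

build_projection_cache <- function(block_data, block_volumes) {
  lapply(seq_along(block_data), function(j) {
    tbl <- block_data[[j]]$table
    out <- list()
    for (r in seq_len(nrow(tbl))) {
      proj <- rowSums(cpp_affine_resample(
        block_volumes[[j]]$data,
        t(euler_matrix(tbl$rot[r], tbl$tilt[r], tbl$psi[r]))), dims = 2)
      out[[as.character(r)]] <- stats::fft(proj)
    }
    out
  })
}

#' Refine one particle's defocus by the block phase-residual scan
#'
#' Scans candidate particle defoci over
#' `current +/- range/2` at the configured step, scores each with
#' [particle_phase_residual()], and returns the candidate with the
#' largest `|PR_i|`; ties break toward the candidate nearest the current
#' value. The absolute value makes the scan robust to a global contrast
#' inversion of the reference.
#'
#' @inheritParams particle_phase_residual
#' @param current current particle defocus in Angstrom.
#' @param config a [defocus_search_config()].
#' @return The refined defocus (Angstrom); the scanned candidates and
#'   their PR values are attached as attribute `"scan"`.
#' @export
refine_particle_defocus <- function(block_data, block_volumes, particle_id,
                                    current, config, optics,
                                    proj_cache = NULL) {
  if (is.null(proj_cache))
    proj_cache <- build_projection_cache(block_data, block_volumes)
  cands <- seq(current - config$range / 2, current + config$range / 2,
               by = config$step)
  pr <- vapply(cands, function(df)
    particle_phase_residual(block_data, block_volumes, particle_id, df,
                            optics, config$band, proj_cache), numeric(1))
  best <- abs(pr) >= max(abs(pr)) - 1e-12
  winners <- cands[best]
  out <- winners[which.min(abs(winners - current))]
  attr(out, "scan") <- data.frame(defocus = cands, pr = pr)
  out
}

#' Refine all particle defoci of a table
#'
#' Extracts block sub-images for every particle, refines each particle
#' defocus with [refine_particle_defocus()], writes the refined values
#' into the `defocus` column and recomputes each block's local mean
#' defocus, mirroring the workflow in which refined particle defoci feed
#' the final block reconstructions.
#'
#' @param stack an [image_stack()].
#' @param table a [particle_table()].
#' @param bset a [block_set()].
#' @param block_volumes list of block reference volumes.
#' @param optics an [optics_model()].
#' @param config a [defocus_search_config()].
#' @return The table with refined `defocus`.
#' @export
refine_defocus <- function(stack, table, bset, block_volumes, optics,
                           config = defocus_search_config()) {
  exp_tbl <- expand_by_symmetry(table, bset$symmetry)
  block_data <- lapply(bset$blocks, function(b)
    extract_block_images(stack, exp_tbl, b))
  proj_cache <- build_projection_cache(block_data, block_volumes)
  out <- table
  for (i in seq_len(nrow(table))) {
    out$defocus[i] <- refine_particle_defocus(
      block_data, block_volumes, i, table$defocus[i], config, optics,
      proj_cache)
  }
  out
}
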