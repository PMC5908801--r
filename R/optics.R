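#' Relativistic electron wavelength
#'
#' `lambda = 12.2639 / sqrt(V + 0.97845e-6 V^2)` Angstrom with `V` the
#' acceleration voltage in volts (de Broglie wavelength with the
#' relativistic correction).
#'
#' @param voltage_kv acceleration voltage in kV (> 0).
#' @return Wavelength in Angstrom.
#' @examples
#' electron_wavelength(300)  # ~0.01969 A
#' @export
electron_wavelength <- function(voltage_kv) {
  if (any(voltage_kv <= 0))
    stop("voltage must be positive", call. = FALSE)
  v <- voltage_kv * 1000
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

# unshifted FFT frequencies in cycles/A for an n-point axis
fft_freq <- function(n, voxel_size) {
  h <- c(seq(0, n %/% 2), seq(-(n - n %/% 2 - 1), -1))
  h / (n * voxel_size)
}

ctf_chi <- function(s, optics, defocus, phase_shift = 0) {
  l <- optics$wavelength
  cs_a <- optics$cs * 1e7   # mm -> A
  pi * l * defocus * s^2 - (pi / 2) * cs_a * l^3 * s^4 + phase_shift
}

#' Contrast transfer function on a radial frequency axis
#'
#' `CTF(s) = -sqrt(1 - A^2) sin(chi) - A cos(chi)` with
#' `chi(s) = pi lambda df s^2 - (pi/2) Cs lambda^3 s^4 + phase_shift`;
#' underfocus positive, `CTF(0) = -A`. No astigmatism is modelled.
#'
#' @param s spatial frequency in 1/Angstrom (vector).
#' @param optics an [optics_model()].
#' @param defocus defocus in Angstrom (underfocus positive).
#' @param phase_shift additional phase shift in radians.
#' @return Numeric vector of CTF values.
#' @export
ctf_1d <- function(s, optics, defocus, phase_shift = 0) {
  a <- optics$amplitude_contrast
  chi <- ctf_chi(s, optics, defocus, phase_shift)
  -sqrt(1 - a^2) * sin(chi) - a * cos(chi)
}

#' 2D contrast transfer function on the FFT frequency grid
#'
#' Evaluates [ctf_1d()] on the unshifted FFT grid of a square image
#' (element `[1,1]` is the zero frequency), so the result multiplies
#' `fft(image)` directly.
#'
#' @param optics an [optics_model()].
#' @param defocus defocus in Angstrom (underfocus positive).
#' @param shape image side length in pixels.
#' @param phase_shift additional phase shift in radians.
#' @return `shape` x `shape` numeric matrix.
#' @export
ctf_2d <- function(optics, defocus, shape, phase_shift = 0) {
  f <- fft_freq(shape, optics$pixel_size)
  s2 <- outer(f^2, f^2, `+`)
  a <- optics$amplitude_contrast
  chi <- ctf_chi(sqrt(s2), optics, defocus, phase_shift)
  -sqrt(1 - a^2) * sin(chi) - a * cos(chi)
}

#' Phase-flip a Fourier transform by the sign of the CTF
#'
#' Multiplies each Fourier component by `sign(CTF)`, undoing the CTF's
#' contrast reversals while leaving amplitudes untouched. Applying the same
#' flip twice restores the input.
#'
#' @param image_ft complex matrix (an image FFT on the same grid as `ctf`).
#' @param ctf real CTF matrix from [ctf_2d()].
#' @return Complex matrix.
#' @export
phase_flip <- function(image_ft, ctf) {
  s <- sign(ctf)
  s[s == 0] <- 1
  image_ft * s
}

#' Rotationally averaged power spectrum
#'
#' Mean of `|FFT|^2` over integer-radius frequency shells of a square
#' image. Shell `r` (0-based) collects pixels whose integer frequency
#' radius rounds to `r`; shell 0 is the DC term.
#'
#' @param image numeric square matrix.
#' @return Numeric vector of length `n/2 + 1` of mean shell power; the
#'   attribute `"counts"` holds the number of pixels per shell.
#' @export
radial_power_spectrum <- function(image) {
  n <- nrow(image)
  if (ncol(image) != n) stop("image must be square", call. = FALSE)
  p <- Mod(stats::fft(image))^2
  h <- c(seq(0, n %/% 2), seq(-(n - n %/% 2 - 1), -1))
  r <- round(sqrt(outer(h^2, h^2, `+`)))
  keep <- r <= n %/% 2
  sums <- tapply(p[keep], r[keep], sum)
  cnts <- tapply(rep(1, sum(keep)), r[keep], sum)
  out <- as.numeric(sums / cnts)
  attr(out, "counts") <- as.numeric(cnts)
  out
}

# smooth background of a radial spectrum: moving-minimum envelope followed
# by a moving-average smoother, both with window w (odd)
spectrum_baseline <- function(ps, w = 9L) {
  n <- length(ps)
  half <- w %/% 2L
  lo <- vapply(seq_len(n), function(i)
    min(ps[max(1, i - half):min(n, i + half)]), numeric(1))
  vapply(seq_len(n), function(i)
    mean(lo[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Measure defocus by fitting Thon rings
#'
#' Grid-searches the defocus maximising the normalised cross-correlation
#' between the rotationally averaged power spectrum of `image` --
#' background-subtracted and whitened by its smooth envelope (a
#' moving-minimum floor followed by a moving-average smoother) -- and the
#' model `CTF(df)^2`, inside a frequency band, then
#' refines the optimum by parabolic interpolation between neighbouring
#' grid points. On depth-of-field-affected images this recovers the
#' particle defocus (the defocus of the layer holding the centre of mass).
#'
#' @param image square numeric matrix with visible Thon rings.
#' @param optics an [optics_model()].
#' @param search_min,search_max defocus search bounds in Angstrom.
#' @param step search grid step in Angstrom.
#' @param band fitted frequency band in 1/Angstrom, clamped to the image's
#'   Nyquist range; default `c(1/30, 1/5)`.
#' @param min_correlation smallest peak correlation accepted as a genuine
#'   ring fit; below it the fit fails.
#' @return Fitted defocus in Angstrom. If no defocus in the range
#'   correlates with the spectrum (e.g. pure noise), `NA_real_` is
#'   returned with a warning of class `blockrec_fit_failure`.
#' @export
fit_defocus <- function(image, optics, search_min = 8000, search_max = 35000,
                        step = 100, band = c(1 / 30, 1 / 5),
                        min_correlation = 0.3) {
  n <- nrow(image)
  ps <- radial_power_spectrum(image)
  shells <- seq_along(ps) - 1
  s <- shells / (n * optics$pixel_size)
  nyq <- 0.5 / optics$pixel_size
  band <- c(max(band[1], 2 / (n * optics$pixel_size)), min(band[2], nyq))
  idx <- which(s >= band[1] & s <= band[2])
  if (length(idx) < 8)
    stop("fitted band contains too few shells", call. = FALSE)
  # whiten: the ring modulation relative to the smooth envelope, so rings
  # at all radii contribute comparably to the correlation
  bl <- spectrum_baseline(ps)[idx]
  obs <- (ps[idx] - bl) / pmax(bl, 1e-300)
  # an image without rings (e.g. pure noise) has only counting
  # fluctuations around the envelope
  if (sd(obs) < 0.5) {
    warning(structure(
      class = c("blockrec_fit_failure", "warning", "condition"),
      list(message = "no Thon-ring signal: defocus fit failed",
           call = sys.call())))
    return(NA_real_)
  }
  obs_cor <- function(model)
    if (sd(model) == 0) 0 else cor(obs, model)
  # model binned exactly like the data: CTF^2 averaged per annulus over
  # the same Fourier pixels, which reproduces the ring blurring of the
  # shell average (a point-sampled model biases the peak)
  f <- fft_freq(n, optics$pixel_size)
  s2d <- sqrt(outer(f^2, f^2, `+`))
  shell2d <- round(s2d * n * optics$pixel_size)
  sel <- shell2d %in% (idx - 1)
  pix_s <- s2d[sel]
  pix_shell <- factor(shell2d[sel], levels = idx - 1)
  pix_n <- as.numeric(table(pix_shell))
  model_at <- function(df) {
    m <- rowsum(ctf_1d(pix_s, optics, df)^2, pix_shell)[, 1] / pix_n
    m - spectrum_baseline(m)
  }
  grid <- seq(search_min, search_max, by = step)
  cc <- vapply(grid, function(df) obs_cor(model_at(df)), numeric(1))
  k <- which.max(cc)
  if (!is.finite(cc[k]) || cc[k] < min_correlation) {
    warning(structure(
      class = c("blockrec_fit_failure", "warning", "condition"),
      list(message = "no Thon-ring signal: defocus fit failed",
           call = sys.call())))
    return(NA_real_)
  }
  best <- grid[k]
  if (k > 1 && k < length(grid)) {
    y1 <- cc[k - 1]; y2 <- cc[k]; y3 <- cc[k + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y1 - y3) / den
      best <- best + delta * step
    }
  }
  best
}
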