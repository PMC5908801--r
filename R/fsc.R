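#' Fourier shell correlation between two volumes
#'
#' Normalised complex correlation per integer-radius frequency shell:
#' `FSC(r) = Re(sum(A conj(B))) / sqrt(sum|A|^2 sum|B|^2)` over the voxels
#' of shell r. Symmetric in its arguments and invariant under a common
#' positive rescaling of either volume.
#'
#' @param vol_a,vol_b [volume_grid()]s of identical size and voxel size.
#' @return A data.frame of class `fsc_curve` with columns `freq`
#'   (1/Angstrom, increasing), `fsc` and `n_voxels` (shell sizes).
#' @export
fsc <- function(vol_a, vol_b) {
  if (!identical(dim(vol_a$data), dim(vol_b$data)))
    stop("volumes must have identical dimensions", call. = FALSE)
  if (abs(vol_a$voxel_size - vol_b$voxel_size) > 1e-9)
    stop("volumes must share a voxel size", call. = FALSE)
  n <- dim(vol_a$data)[1]
  fa <- stats::fft(vol_a$data)
  fb <- stats::fft(vol_b$data)
  h <- c(seq(0, n %/% 2), seq(-(n - n %/% 2 - 1), -1))
  h2 <- h^2
  r <- round(sqrt(outer(outer(h2, h2, `+`), h2, `+`)))
  keep <- r <= n %/% 2
  rk <- r[keep]
  cross <- Re(fa * Conj(fb))[keep]
  pa <- (Mod(fa)^2)[keep]
  pb <- (Mod(fb)^2)[keep]
  num <- tapply(cross, rk, sum)
  da <- tapply(pa, rk, sum)
  db <- tapply(pb, rk, sum)
  cnt <- tapply(rep(1, length(rk)), rk, sum)
  den <- sqrt(da * db)
  val <- ifelse(den > 0, num / den, 0)
  structure(data.frame(freq = as.numeric(names(num)) /
                         (n * vol_a$voxel_size),
                       fsc = as.numeric(val),
                       n_voxels = as.numeric(cnt)),
            class = c("fsc_curve", "data.frame"))
}

#' Resolution read-out from an FSC curve
#'
#' Resolution is `1/frequency` at the first downward crossing of the
#' threshold, with the crossing frequency linearly interpolated between
#' neighbouring shells. A curve that never drops below the threshold
#' returns the Nyquist resolution (`2 * voxel size`).
#'
#' @param curve an `fsc_curve` from [fsc()].
#' @param threshold correlation threshold, conventionally 0.5 when
#'   comparing a map against the ground-truth model and 0.143 between
#'   independent half maps.
#' @return Resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.5) {
  f <- curve$freq
  v <- curve$fsc
  for (i in seq(2, length(v))) {
    if (v[i] < threshold && v[i - 1] >= threshold) {
      frac <- (v[i - 1] - threshold) / (v[i - 1] - v[i])
      fc <- f[i - 1] + frac * (f[i] - f[i - 1])
      return(1 / fc)
    }
  }
  1 / f[length(f)]
}
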