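# Shared fixtures. Everything is generated in code; the expensive
# desk-scale Ewald benchmark is computed once per test run and cached.

# Fourier ring correlation between two square images (2D analogue of fsc)
frc <- function(a, b) {
  n <- nrow(a)
  fa <- stats::fft(a); fb <- stats::fft(b)
  h <- c(seq(0, n %/% 2), seq(-(n - n %/% 2 - 1), -1))
  r <- round(sqrt(outer(h^2, h^2, `+`)))
  keep <- r <= n %/% 2
  num <- tapply(Re(fa * Conj(fb))[keep], r[keep], sum)
  da <- tapply((Mod(fa)^2)[keep], r[keep], sum)
  db <- tapply((Mod(fb)^2)[keep], r[keep], sum)
  as.numeric(num / sqrt(da * db))
}

# independently written ZYZ matrix (plain trigonometry, not euler_matrix)
zyz_oracle <- function(rot, tilt, psi) {
  d <- pi / 180
  cr <- cos(rot * d); sr <- sin(rot * d)
  ct <- cos(tilt * d); st <- sin(tilt * d)
  cp <- cos(psi * d); sp <- sin(psi * d)
  matrix(c(cp * ct * cr - sp * sr,  sp * ct * cr + cp * sr, -st * cr,
           -cp * ct * sr - sp * cr, -sp * ct * sr + cp * cr,  st * sr,
           cp * st,                  sp * st,                 ct),
         3, 3)
}

# scaled-down Ewald study conditions: a 150 A phantom in a 96^3 box at
# 2 A/px with the wavelength treated as a free optics parameter, chosen so
# the empirical depth-of-field limit sits at 5 A (2.5x the voxel size);
# defoci scaled to 300-500 A so CTF rings stay resolvable on this grid
bench_conditions <- function() {
  t_diam <- 150
  lambda <- 2 * 5^2 / t_diam
  list(
    diameter = t_diam,
    optics = optics_model(cs = 0, amplitude_contrast = 0.07,
                          pixel_size = 2, wavelength = lambda),
    limit = empirical_limit(t_diam, wavelength = lambda),
    box = 96, euler_step = 12, layer_thickness = 20,
    defocus_range = c(300, 500))
}

bench_block_set <- function(a = 45) {
  ctrs <- rbind(c(0, 0, 0), c(a, 0, 0), c(-a, 0, 0), c(0, a, 0),
                c(0, -a, 0), c(0, 0, a), c(0, 0, -a))
  block_set(lapply(seq_len(nrow(ctrs)), function(i)
    block_spec(ctrs[i, ], radius = 60, sub_box = 64)),
    symmetry = "C1", r_keep = 25, r_blend = 40)
}

# particles from the benchmark conditions with ground-truth block volumes
# cut from the phantom, pre-extracted into per-block sub-images
refine_fixture <- function(n_particles, seed = 2) {
  bc <- bench_conditions()
  ph <- make_phantom(bc$diameter, 400, 2, bc$box, seed = 1)
  cfg <- simulation_config(layer_thickness = 20,
                           defocus_range = bc$defocus_range,
                           euler_step = 45, inplane = FALSE, seed = seed)
  ds <- simulate_dataset(ph, cfg, bc$optics)
  keep <- seq_len(min(n_particles, length(ds$stack)))
  stack <- image_stack(ds$stack$data[, , keep, drop = FALSE], 2)
  tbl <- ds$table[keep, ]
  tbl$image_index <- seq_along(keep)
  bs <- bench_block_set()
  bvols <- lapply(bs$blocks, function(b)
    extract_block_volume(ph$volume, b))
  exp_tbl <- expand_by_symmetry(tbl, "C1")
  bd <- lapply(bs$blocks, function(b)
    extract_block_images(stack, exp_tbl, b))
  list(optics = bc$optics, stack = stack, table = tbl, bset = bs,
       bvols = bvols, block_data = bd)
}

.bench_cache <- new.env(parent = emptyenv())

# noise-free layered benchmark dataset plus conventional and block-based
# reconstructions; hand = -1 gives the mirrored-convention dataset
bench_data <- function(hand = 1) {
  key <- paste0("h", hand)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  bc <- bench_conditions()
  ph <- make_phantom(bc$diameter, 400, bc$optics$pixel_size, bc$box,
                     seed = 1)
  cfg <- simulation_config(layer_thickness = bc$layer_thickness,
                           defocus_range = bc$defocus_range,
                           euler_step = bc$euler_step, inplane = FALSE,
                           hand_sign = hand, seed = 1)
  ds <- simulate_dataset(ph, cfg, bc$optics)
  out <- list(conditions = bc, phantom = ph, config = cfg,
              stack = ds$stack, table = ds$table)
  .bench_cache[[key]] <- out
  out
}

bench_result <- function(what, hand = 1) {
  key <- paste0(what, "_h", hand)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  bd <- bench_data(hand)
  bc <- bd$conditions
  val <- switch(what,
    conventional = {
      rec <- reconstruct(bd$stack, bd$table, bc$optics)
      resolution_at(fsc(rec, bd$phantom$volume), 0.5)
    },
    block = {
      tbl <- bd$table
      tbl$hand_sign <- 1
      map <- block_reconstruct(bd$stack, tbl, bench_block_set(), bc$optics)
      resolution_at(fsc(map, bd$phantom$volume), 0.5)
    },
    block_wrong_hand = {
      tbl <- bd$table
      tbl$hand_sign <- -1
      map <- block_reconstruct(bd$stack, tbl, bench_block_set(), bc$optics)
      resolution_at(fsc(map, bd$phantom$volume), 0.5)
    })
  .bench_cache[[key]] <- val
  val
}
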