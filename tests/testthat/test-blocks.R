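test_that("block defocus offsets follow the rotation geometry", {
  expect_equal(local_defocus_offset(c(0, 0, 0), c(0, 0, 350)), 350)
  expect_equal(local_defocus_offset(c(0, 0, 0), c(0, 0, 350), -1), -350)
  for (e in list(c(0, 0, 0), c(30, 60, 10), c(200, 120, 300)))
    expect_equal(local_defocus_offset(e, c(0, 0, 0)), 0)
  # matrix oracle: the offset is the third row of the hand-derived ZYZ
  # matrix applied to the centre
  set.seed(8)
  for (i in 1:8) {
    e <- c(runif(1, 0, 360), runif(1, 0, 180), runif(1, 0, 360))
    cc <- rnorm(3, sd = 100)
    expect_equal(local_defocus_offset(e, cc),
                 sum(zyz_oracle(e[1], e[2], e[3])[3, ] * cc),
                 tolerance = 1e-10)
  }
  # 90 degree tilt brings the reference x axis onto the beam axis
  expect_equal(local_defocus_offset(c(0, 90, 0), c(100, 0, 0)), -100)
})

test_that("local mean defocus is the exact sum of Eq.-style terms", {
  expect_identical(local_mean_defocus(20000, 300), 20300)
  expect_identical(local_mean_defocus(20000, 0), 20000)
  # flipping the hand negates only the offset term
  e <- c(40, 70, 20); cc <- c(50, -30, 80)
  expect_equal(local_mean_defocus(15000, local_defocus_offset(e, cc, -1)),
               2 * 15000 -
                 local_mean_defocus(15000, local_defocus_offset(e, cc, 1)))
})

test_that("point groups have the right order and group structure", {
  sizes <- c(C1 = 1, C2 = 2, C6 = 6, D2 = 4, D7 = 14, T = 12, O = 24,
             I = 60)
  for (g in names(sizes)) {
    grp <- symmetry_group(g)
    expect_equal(length(grp), unname(sizes[g]), info = g)
    key <- function(m) paste(sprintf("%.4f", round(m, 5) + 0),
                             collapse = ",")
    keys <- vapply(grp, key, character(1))
    expect_true(key(diag(3)) %in% keys, info = g)
    # closure under composition, orthonormality
    for (a in grp[seq_len(min(6, length(grp)))]) {
      expect_equal(crossprod(a), diag(3), tolerance = 1e-9)
      for (b in grp[seq_len(min(6, length(grp)))])
        expect_true(key(a %*% b) %in% keys, info = g)
    }
  }
  expect_error(symmetry_group("X9"), "unknown")
})

test_that("symmetry expansion composes orientations and conserves counts", {
  set.seed(9)
  tbl <- particle_table(rot = runif(10, 0, 360), tilt = runif(10, 5, 175),
                        psi = runif(10, 0, 360),
                        defocus = runif(10, 10000, 30000))
  expect_equal(nrow(expand_by_symmetry(tbl, "C1")), 10)
  expect_equal(nrow(expand_by_symmetry(tbl, "C2")), 20)
  expect_equal(nrow(expand_by_symmetry(tbl, "I")), 600)
  ex <- expand_by_symmetry(tbl, "C4")
  expect_equal(nrow(ex), 40)
  grp <- symmetry_group("C4")
  for (row in c(1, 7, 22)) {
    i <- ex$particle_id[row]; k <- ex$sym_op[row]
    R0 <- euler_matrix(tbl$rot[i], tbl$tilt[i], tbl$psi[i])
    Rr <- euler_matrix(ex$rot[row], ex$tilt[row], ex$psi[row])
    expect_equal(Rr, R0 %*% grp[[k]], tolerance = 1e-9)
  }
  expect_equal(ex$defocus, rep(tbl$defocus, each = 4))
})

test_that("a centred whole-box block extraction is the identity crop", {
  opt <- optics_model(pixel_size = 2)
  ph <- make_phantom(70, 60, 2, 48, seed = 2)
  cfg <- simulation_config(euler_step = 40, inplane = FALSE, seed = 5)
  ds <- simulate_dataset(ph, cfg, opt)
  ex <- extract_block_images(ds$stack,
                             expand_by_symmetry(ds$table, "C1"),
                             block_spec(c(0, 0, 0), 40, 48))
  expect_equal(ex$stack$data, ds$stack$data)
  expect_equal(ex$table$shift_x, rep(0, nrow(ex$table)))
  expect_equal(ex$table$ldfv, rep(0, nrow(ex$table)))
  expect_equal(ex$table$local_defocus, ds$table$defocus)
  expect_true(all(ex$table$edge_pad == 0))
})

test_that("extraction windows track the projected block centre", {
  # phantom with a single blob at the block centre: the extracted
  # sub-image must have the blob at its centre for every orientation
  n <- 64; vx <- 2
  cc <- c(28, -16, 20)
  ctr <- n %/% 2
  ax <- seq_len(n) - 1
  g1 <- function(x0) exp(-(ax - x0)^2 / (2 * 1.5^2))
  blob <- outer(outer(g1(ctr + cc[1] / vx), g1(ctr + cc[2] / vx)),
                g1(ctr + cc[3] / vx))
  vol <- volume_grid(blob, vx)
  opt <- optics_model(cs = 0, amplitude_contrast = 0.3, pixel_size = vx,
                      wavelength = 1e-10)     # CTF = -A: pure projection
  eulers <- data.frame(rot = c(0, 40, 150), tilt = c(0, 70, 120),
                       psi = c(0, 10, 250))
  imgs <- array(0, c(n, n, 3))
  for (i in 1:3)
    imgs[, , i] <- -simulate_image_layered(
      vol, as.numeric(eulers[i, ]), 500, opt)
  tbl <- particle_table(rot = eulers$rot, tilt = eulers$tilt,
                        psi = eulers$psi, defocus = 500)
  ex <- extract_block_images(image_stack(imgs, vx),
                             expand_by_symmetry(tbl, "C1"),
                             block_spec(cc, 20, 32))
  half <- 16
  for (i in 1:3) {
    sub <- ex$stack$data[, , i]
    peak <- arrayInd(which.max(sub), dim(sub))
    # blob at window centre up to the recorded sub-pixel residual
    expect_lte(max(abs(peak - 1 - half)), 1)
    expect_lt(abs(ex$table$shift_x[i]), vx)
    expect_lt(abs(ex$table$shift_y[i]), vx)
    # defocus offset equals the blob's beam-axis coordinate
    R <- euler_matrix(eulers$rot[i], eulers$tilt[i], eulers$psi[i])
    expect_equal(ex$table$ldfv[i], as.numeric((R %*% cc)[3]),
                 tolerance = 1e-9)
  }
})

test_that("windows beyond the image edge are padded and flagged", {
  stack <- image_stack(array(rnorm(48 * 48 * 1), c(48, 48, 1)), 2)
  tbl <- particle_table(rot = 0, tilt = 0, psi = 0, defocus = 10000)
  ex <- extract_block_images(stack, expand_by_symmetry(tbl, "C1"),
                             block_spec(c(44, 0, 0), 20, 32))
  expect_equal(ex$table$edge_pad, 1L)
  expect_true(all(is.finite(ex$stack$data)))
})

test_that("local refinement recovers deliberate misalignments", {
  opt <- optics_model(voltage = 300, pixel_size = 2)
  ph <- make_phantom(70, 100, 2, 48, seed = 4)
  e_true <- c(50, 70, 20)
  img <- simulate_image_flat(ph, e_true, 16000, opt)
  stack <- image_stack(array(img, c(48, 48, 1)), 2)
  mk_tbl <- function(e, sx = 0, sy = 0) {
    t <- particle_table(rot = e[1], tilt = e[2], psi = e[3],
                        shift_x = sx, shift_y = sy, defocus = 16000)
    t$ldfv <- 0; t$local_defocus <- 16000; t$particle_id <- 1L
    t$sym_op <- 1L
    t
  }
  # unperturbed parameters stay put
  t0 <- local_refine(stack, mk_tbl(e_true), ph$volume, opt,
                     angle_range = 2, angle_step = 1, shift_range = 6)
  expect_equal(c(t0$rot, t0$tilt, t0$psi), e_true, tolerance = 1e-9)
  expect_equal(c(t0$shift_x, t0$shift_y), c(0, 0))
  # an empty search range is the identity
  tn <- local_refine(stack, mk_tbl(e_true + c(1, -1, 1)), ph$volume, opt,
                     angle_range = 0, angle_step = 1, shift_range = 0)
  expect_equal(tn$rot, e_true[1] + 1)
  # +/-2 degree and +/-2 px errors are recovered within one step
  tp <- local_refine(stack, mk_tbl(e_true + c(2, -2, 2), 4, -4),
                     ph$volume, opt, angle_range = 3, angle_step = 1,
                     shift_range = 8)
  expect_lte(max(abs(c(tp$rot, tp$tilt, tp$psi) - e_true)), 1)
  expect_lte(max(abs(c(tp$shift_x, tp$shift_y))), 2)
})

test_that("combining blocks preserves constants and single blocks", {
  n <- 32; vx <- 2
  vol <- volume_grid(array(rnorm(n^3), c(n, n, n)), vx)
  bs1 <- block_set(list(block_spec(c(0, 0, 0), 30, n)),
                   r_keep = 200, r_blend = 10)
  out <- combine_blocks(list(vol), bs1, n, vx)
  expect_equal(out$data, vol$data, tolerance = 1e-12)
  # two constant-valued blocks blend to the same constant
  k <- volume_grid(array(5, c(n, n, n)), vx)
  bs2 <- block_set(list(block_spec(c(-10, 0, 0), 30, n),
                        block_spec(c(10, 0, 0), 30, n)),
                   r_keep = 8, r_blend = 30)
  both <- combine_blocks(list(k, k), bs2, n, vx)
  ctr <- n %/% 2
  ax <- (seq_len(n) - 1 - ctr) * vx
  r2a <- outer(outer((ax + 10)^2, ax^2, `+`), ax^2, `+`)
  r2b <- outer(outer((ax - 10)^2, ax^2, `+`), ax^2, `+`)
  covered <- pmin(r2a, r2b) < 30^2   # inside both sub-boxes and blend reach
  expect_equal(both$data[covered], rep(5, sum(covered)), tolerance = 1e-9)
})

test_that("symmetrisation is idempotent and fixes symmetric maps", {
  rms <- function(a) sqrt(mean(a^2))
  ph <- make_phantom(70, 60, 2, 48, seed = 2)
  expect_identical(symmetrize(ph$volume, "C1")$data, ph$volume$data)
  # 90 degree rotations are exact lattice maps: idempotent to rounding
  s1 <- symmetrize(ph$volume, "C4")
  s2 <- symmetrize(s1, "C4")
  expect_lt(rms(s2$data - s1$data), 1e-9 * rms(s1$data))
  # oblique rotations re-interpolate, so idempotence holds to the
  # trilinear error of the map's frequency content (smooth map here)
  sm <- make_phantom(70, 60, 2, 48, seed = 2, sigma = 6)
  t1 <- symmetrize(sm$volume, "C3")
  t2 <- symmetrize(t1, "C3")
  expect_lt(rms(t2$data - t1$data), 5e-3 * rms(t1$data))
  expect_gt(cor(as.vector(t1$data), as.vector(t2$data)), 0.9999)
})

test_that("a zero-offset single block reproduces the conventional map", {
  opt <- optics_model(voltage = 300, pixel_size = 2)
  ph <- make_phantom(70, 100, 2, 48, seed = 4)
  cfg <- simulation_config(euler_step = 18, inplane = FALSE, seed = 4)
  ds <- simulate_dataset(ph, cfg, opt)
  conv <- reconstruct(ds$stack, ds$table, opt)
  bs <- block_set(list(block_spec(c(0, 0, 0), 46, 48)),
                  symmetry = "C1", r_keep = 300, r_blend = 10)
  blk <- block_reconstruct(ds$stack, ds$table, bs, opt)
  curve <- fsc(blk, conv)
  expect_true(all(curve$fsc[-1] > 0.999))
})
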