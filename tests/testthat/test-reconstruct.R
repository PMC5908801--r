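test_that("a single inserted central section is reproduced on its plane", {
  ph <- make_phantom(70, 60, 2, 48, seed = 2)
  proj <- rowSums(ph$volume$data, dims = 2)
  acc <- fourier_accumulator(48, 2, pad_factor = 2)
  insert_slice(acc, proj, c(0, 0, 0), c(0, 0), 1)
  rec <- finalize_volume(acc, wiener_floor = 1e-9)
  # one central section makes the volume constant along z, each z plane
  # proportional to the projection
  for (k in c(1, 16, 40))
    expect_gt(cor(as.vector(rec$data[, , k]), as.vector(proj)), 0.999)
})

test_that("duplicate slices normalise away and empty data give zero", {
  ph <- make_phantom(70, 60, 2, 48, seed = 2)
  proj <- rowSums(ph$volume$data, dims = 2)
  a1 <- fourier_accumulator(48, 2)
  insert_slice(a1, proj, c(20, 40, 0), c(0, 0), 1)
  r1 <- finalize_volume(a1, 1e-6)
  a2 <- fourier_accumulator(48, 2)
  insert_slice(a2, proj, c(20, 40, 0), c(0, 0), 1)
  insert_slice(a2, proj, c(20, 40, 0), c(0, 0), 1)
  r2 <- finalize_volume(a2, 1e-6)
  expect_equal(r2$data, r1$data, tolerance = 1e-9)

  r0 <- finalize_volume(fourier_accumulator(32, 1))
  expect_equal(r0$data, array(0, c(32, 32, 32)))
})

test_that("orthogonal sections of a Gaussian ball land exactly on axes", {
  # analytic oracle: projections and 3D FT of an isotropic Gaussian are
  # closed-form; axis-aligned sections involve no interpolation, so the
  # normalised accumulator must match the analytic transform on-plane
  n <- 48; ctr <- n %/% 2; sg <- 4
  ax <- seq_len(n) - 1 - ctr
  proj <- sqrt(2 * pi) * sg * exp(-outer(ax^2, ax^2, `+`) / (2 * sg^2))
  acc <- fourier_accumulator(n, 1, pad_factor = 1)
  insert_slice(acc, proj, c(0, 0, 0), c(0, 0), 1)     # z section
  insert_slice(acc, proj, c(0, 90, 0), c(0, 0), 1)    # x section
  fk <- complex(real = acc$sre, imaginary = acc$sim) /
    pmax(acc$wt, 1e-12)
  dim(fk) <- c(n, n, n)
  h <- c(seq(0, n / 2), seq(-(n / 2 - 1), -1))
  gauss_ft <- function(hx, hy, hz)                    # continuous FT
    (2 * pi * sg^2)^1.5 * exp(-2 * pi^2 * sg^2 * (hx^2 + hy^2 + hz^2) / n^2)
  for (q in 2:8) {
    expect_equal(Re(fk[q + 1, 1, 1]), gauss_ft(q, 0, 0), tolerance = 1e-3)
    expect_equal(Re(fk[1, q + 1, 1]), gauss_ft(0, q, 0), tolerance = 1e-3)
    expect_equal(Re(fk[1, 1, q + 1]), gauss_ft(0, 0, q), tolerance = 1e-3)
    expect_lt(abs(Im(fk[q + 1, 1, 1])) / gauss_ft(q, 0, 0), 1e-6)
  }
})

test_that("an idealised fully covered reconstruction is near exact", {
  ph <- make_phantom(100, 150, 2, 64, seed = 2)
  cov <- euler_coverage(10, inplane = FALSE)
  acc <- fourier_accumulator(64, 2, pad_factor = 2)
  for (i in seq_len(nrow(cov))) {
    e <- as.numeric(cov[i, ])
    proj <- rowSums(rotate_volume(ph$volume, e)$data, dims = 2)
    insert_slice(acc, proj, e, c(0, 0), 1)
  }
  rec <- finalize_volume(acc, wiener_floor = 1e-3)
  curve <- fsc(rec, ph$volume)
  # trilinear insertion keeps the map essentially exact through 0.85
  # Nyquist and > 0.95 at 0.9 Nyquist
  expect_true(all(curve$fsc[2:round(0.85 * 32)] > 0.99))
  expect_gt(curve$fsc[round(0.9 * 32)], 0.95)
})

test_that("growing the Wiener floor shrinks the map monotonically", {
  ph <- make_phantom(70, 60, 2, 48, seed = 2)
  proj <- rowSums(ph$volume$data, dims = 2)
  acc <- fourier_accumulator(48, 2)
  insert_slice(acc, proj, c(0, 0, 0), c(0, 0), 1)
  norms <- vapply(c(0.01, 0.1, 1, 10),
                  function(f) sqrt(sum(finalize_volume(acc, f)$data^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("reconstruct recovers flat-simulated data and checks its inputs", {
  opt <- optics_model(voltage = 300, cs = 2.7, amplitude_contrast = 0.07,
                      pixel_size = 2)
  ph <- make_phantom(70, 100, 2, 48, seed = 4)
  # moderate defoci keep the CTF rings resolved on this small grid
  cfg <- simulation_config(euler_step = 16, inplane = FALSE, seed = 4,
                           layer_thickness = 1e6,   # no depth of field
                           defocus_range = c(8000, 16000))
  ds <- simulate_dataset(ph, cfg, opt)
  rec <- reconstruct(ds$stack, ds$table, opt)
  curve <- fsc(rec, ph$volume)
  expect_true(all(curve$fsc[2:16] > 0.95))
  expect_error(reconstruct(ds$stack, ds$table[0, ], opt), "empty")
  expect_error(reconstruct(ds$stack, ds$table, opt, "measured"),
               "measured_defocus")
})

test_that("origin shifts are honoured during insertion", {
  opt <- optics_model(voltage = 300, pixel_size = 2)
  ph <- make_phantom(70, 100, 2, 48, seed = 4)
  cfg <- simulation_config(euler_step = 20, inplane = FALSE, seed = 4,
                           layer_thickness = 1e6)
  ds <- simulate_dataset(ph, cfg, opt)
  # translate every image by an integer pixel offset and record the shift
  sh <- array(0, dim(ds$stack$data))
  sh[3:48, 5:48, ] <- ds$stack$data[1:46, 1:44, ]
  tbl <- ds$table
  tbl$shift_x <- 2 * 2   # +2 px in x, in Angstrom
  tbl$shift_y <- 4 * 2
  rec <- reconstruct(image_stack(sh, 2), tbl, opt)
  ref <- reconstruct(ds$stack, ds$table, opt)
  expect_gt(cor(as.vector(rec$data), as.vector(ref$data)), 0.95)
})

test_that("FSC behaves as a normalised shell correlation", {
  set.seed(12)
  v <- volume_grid(array(rnorm(32^3), c(32, 32, 32)), 2)
  curve <- fsc(v, v)
  expect_equal(curve$fsc, rep(1, nrow(curve)), tolerance = 1e-12)
  expect_true(all(diff(curve$freq) > 0))
  # scale invariance and symmetry
  w <- volume_grid(array(rnorm(32^3), c(32, 32, 32)), 2)
  s <- v; s$data <- 3.7 * s$data
  expect_equal(fsc(v, w)$fsc, fsc(w, v)$fsc, tolerance = 1e-12)
  expect_equal(fsc(s, w)$fsc, fsc(v, w)$fsc, tolerance = 1e-9)
  # independent noise decorrelates
  cu <- fsc(v, w)
  expect_true(all(abs(cu$fsc[-1]) < 3 / sqrt(cu$n_voxels[-1])))
})

test_that("resolution read-out finds a low-pass filter edge", {
  set.seed(13)
  n <- 48
  v <- volume_grid(array(rnorm(n^3), c(n, n, n)), 2)
  fk <- stats::fft(v$data)
  h <- c(seq(0, n / 2), seq(-(n / 2 - 1), -1))
  r <- sqrt(outer(outer(h^2, h^2, `+`), h^2, `+`)) / (n * 2)
  fk[r > 1 / 10] <- 0          # hard cut at 10 A
  lp <- volume_grid(Re(stats::fft(fk, inverse = TRUE)) / n^3, 2)
  res <- resolution_at(fsc(v, lp), 0.5)
  expect_lt(abs(res - 10), 1)
  # a perfect copy never crosses: Nyquist is reported
  expect_equal(resolution_at(fsc(v, v), 0.5), 4, tolerance = 0.1)
})

test_that("reconstruction is equivariant under a global rotation", {
  opt <- optics_model(voltage = 300, pixel_size = 2)
  ph <- make_phantom(70, 100, 2, 48, seed = 4)
  cfg <- simulation_config(euler_step = 18, inplane = FALSE, seed = 4,
                           layer_thickness = 1e6)
  ds <- simulate_dataset(ph, cfg, opt)
  rec <- reconstruct(ds$stack, ds$table, opt)
  # compose every orientation with a fixed extra rotation G: the map
  # becomes the G-rotated phantom reconstruction
  G <- euler_matrix(0, 0, 35)
  tbl <- ds$table
  for (i in seq_len(nrow(tbl))) {
    R <- euler_matrix(tbl$rot[i], tbl$tilt[i], tbl$psi[i]) %*% G
    e <- euler_from_matrix(R)
    tbl$rot[i] <- e[1]; tbl$tilt[i] <- e[2]; tbl$psi[i] <- e[3]
  }
  rec2 <- reconstruct(ds$stack, tbl, opt)
  back <- rotate_volume(rec2, euler_from_matrix(G))
  expect_gt(cor(as.vector(rec$data), as.vector(rec2$data)), 0.2)
  expect_gt(cor(as.vector(rec$data), as.vector(back$data)), 0.95)
})
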