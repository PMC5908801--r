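# Block-based reconstruction: split a large object into blocks small enough
# that a single defocus per block is accurate, reconstruct each block from
# sub-images with its local mean defocus, and reassemble in real space.

#' Define a block
#'
#' @param center block centre in Angstrom, a length-3 vector in the
#'   reference (unrotated) frame relative to the object centre.
#' @param radius nominal block radius in Angstrom.
#' @param sub_box side of the extracted sub-image / block reconstruction
#'   box in pixels (even); must satisfy `2 * radius <= sub_box * voxel`.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(center, radius, sub_box) {
  if (length(center) != 3) stop("center must have length 3", call. = FALSE)
  if (sub_box %% 2L) stop("sub_box must be even", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  structure(list(center = as.numeric(center), radius = radius,
                 sub_box = as.integer(sub_box)), class = "block_spec")
}

#' Define a set of blocks with symmetry and blending radii
#'
#' @param blocks list of [block_spec()]s.
#' @param symmetry point-group name (`"C1"`, `"Cn"`, `"Dn"`, `"T"`,
#'   `"O"`, `"I"`).
#' @param r_keep radius (Angstrom) around each block centre inside which
#'   the nearest block's density is copied unchanged during assembly.
#' @param r_blend width (Angstrom) of the linear cross-fade outside
#'   `r_keep`.
#' @return An object of class `block_set`.
#' @export
block_set <- function(blocks, symmetry = "C1", r_keep = NULL,
                      r_blend = NULL) {
  if (inherits(blocks, "block_spec")) blocks <- list(blocks)
  stopifnot(all(vapply(blocks, inherits, logical(1), "block_spec")))
  if (is.null(r_keep)) r_keep <- min(vapply(blocks, `[[`, 1, "radius")) / 2
  if (is.null(r_blend)) r_blend <- r_keep
  structure(list(blocks = blocks, symmetry = symmetry,
                 r_keep = r_keep, r_blend = r_blend), class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set> %d blocks, symmetry %s, r_keep %g A, r_blend %g A\n",
              length(x$blocks), x$symmetry, x$r_keep, x$r_blend))
  invisible(x)
}

rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * c_ + s * K + (1 - c_) * outer(a, a)
}

group_closure <- function(gens) {
  key <- function(m) {
    v <- round(m, 6)
    v[v == 0] <- 0                  # collapse negative zero
    paste(sprintf("%.6f", v), collapse = ",")
  }
  elems <- list(diag(3))
  names(elems) <- key(diag(3))
  queue <- gens
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    k <- key(g)
    if (!is.null(elems[[k]])) next
    elems[[k]] <- g
    for (e in elems) {
      queue <- c(queue, list(g %*% e, e %*% g))
      if (length(elems) > 120)
        stop("symmetry group closure exceeded 120 elements", call. = FALSE)
    }
  }
  unname(elems)
}

#' Rotation matrices of a point group
#'
#' Supported groups: cyclic `Cn` (n-fold about z), dihedral `Dn` (`Cn`
#' plus a 2-fold about x), tetrahedral `T` (12 operators), octahedral `O`
#' (24) and icosahedral `I` (60, 2-fold axes on the coordinate axes).
#'
#' @param name group name, e.g. `"C1"`, `"C4"`, `"D2"`, `"I"`.
#' @return An object of class `symmetry_group`: list of 3 x 3 rotation
#'   matrices, closed under composition and containing the identity.
#' @export
symmetry_group <- function(name) {
  name <- toupper(trimws(name))
  phi <- (1 + sqrt(5)) / 2
  mats <- if (grepl("^C[0-9]+$", name)) {
    n <- as.integer(sub("^C", "", name))
    lapply(seq_len(n) - 1, function(k) rotation_about(c(0, 0, 1), 2 * pi * k / n))
  } else if (grepl("^D[0-9]+$", name)) {
    n <- as.integer(sub("^D", "", name))
    group_closure(list(rotation_about(c(0, 0, 1), 2 * pi / n),
                       rotation_about(c(1, 0, 0), pi)))
  } else if (name == "T") {
    group_closure(list(rotation_about(c(0, 0, 1), pi),
                       rotation_about(c(1, 1, 1), 2 * pi / 3)))
  } else if (name == "O") {
    group_closure(list(rotation_about(c(0, 0, 1), pi / 2),
                       rotation_about(c(1, 1, 1), 2 * pi / 3)))
  } else if (name == "I") {
    group_closure(list(rotation_about(c(0, 1, phi), 2 * pi / 5),
                       rotation_about(c(1, 1, 1), 2 * pi / 3)))
  } else stop("unknown symmetry group: ", name, call. = FALSE)
  structure(mats, class = "symmetry_group", name = name)
}

#' Beam-axis defocus offset of a block centre
#'
#' Under orientation `euler` the block centre `c_j` sits at imaging-frame
#' position `R c_j`; its z component (beam axis) is the defocus variation
#' LDFV between the particle centre and the block centre, signed by the
#' handedness convention. With the identity orientation a block at
#' reference `(0, 0, z0)` has `LDFV = hand_sign * z0`.
#'
#' @param euler `(rot, tilt, psi)` in degrees.
#' @param center block centre (Angstrom, reference frame).
#' @param hand_sign +1 or -1.
#' @return LDFV in Angstrom.
#' @export
local_defocus_offset <- function(euler, center, hand_sign = 1) {
  R <- euler_matrix(euler[1], euler[2], euler[3])
  hand_sign * as.numeric(R[3, ] %*% as.numeric(center))
}

#' Local mean defocus of a block
#'
#' `LDF_ij = PDF_i + LDFV_ij`: the particle defocus plus the block's
#' beam-axis offset.
#'
#' @param particle_defocus PDF_i in Angstrom.
#' @param ldfv LDFV_ij in Angstrom from [local_defocus_offset()].
#' @return LDF_ij in Angstrom.
#' @export
local_mean_defocus <- function(particle_defocus, ldfv) particle_defocus + ldfv

#' Expand a particle table by a symmetry group
#'
#' Each record becomes `|G|` records whose orientation composes the
#' particle orientation with a group rotation
#' (`R_new = R(euler) %*% R_g`), so one image of a symmetric object
#' contributes `|G|` projections of the asymmetric unit. Columns
#' `particle_id` and `sym_op` track the provenance.
#'
#' @param table a [particle_table()].
#' @param group a [symmetry_group()] or group name.
#' @return An expanded [particle_table()] with `nrow(table) * |G|` rows.
#' @export
expand_by_symmetry <- function(table, group) {
  if (is.character(group)) group <- symmetry_group(group)
  n <- nrow(table)
  g <- length(group)
  out <- table[rep(seq_len(n), each = g), , drop = FALSE]
  out$particle_id <- rep(seq_len(n), each = g)
  out$sym_op <- rep(seq_len(g), times = n)
  if (g > 1) {
    for (i in seq_len(n)) {
      R0 <- euler_matrix(table$rot[i], table$tilt[i], table$psi[i])
      for (k in seq_len(g)) {
        e <- euler_from_matrix(R0 %*% group[[k]])
        row <- (i - 1) * g + k
        out$rot[row] <- e[1]; out$tilt[row] <- e[2]; out$psi[row] <- e[3]
      }
    }
  }
  rownames(out) <- NULL
  validate_particle_table(out)
}

#' Extract per-block sub-images
#'
#' For every record of the (symmetry-expanded) table, cuts a
#' `sub_box` window centred at the projected block centre
#' `(R c_j)_{x,y}` plus the particle shift, at nearest-pixel precision;
#' the residual sub-pixel offset is written into the sub-record's shift
#' columns rather than interpolated away. Each sub-record receives the
#' block's defocus offset (`ldfv`) and local mean defocus
#' (`local_defocus`). Windows that cross the image edge are padded with
#' the image mean and flagged in column `edge_pad`.
#'
#' @param stack an [image_stack()].
#' @param expanded_table a [particle_table()], typically from
#'   [expand_by_symmetry()].
#' @param block a [block_spec()].
#' @return List with `stack` (sub-images) and `table` (sub-records).
#' @export
extract_block_images <- function(stack, expanded_table, block) {
  n <- dim(stack$data)[1]
  vx <- stack$voxel_size
  sb <- block$sub_box
  m <- nrow(expanded_table)
  sub <- array(0, c(sb, sb, m))
  tbl <- expanded_table
  tbl$ldfv <- 0; tbl$local_defocus <- tbl$defocus; tbl$edge_pad <- 0L
  ctr <- n %/% 2L
  half <- sb %/% 2L
  for (i in seq_len(m)) {
    rec <- expanded_table[i, ]
    R <- euler_matrix(rec$rot, rec$tilt, rec$psi)
    pos <- as.numeric(R %*% block$center)          # imaging frame, A
    cx <- ctr + (pos[1] + rec$shift_x) / vx        # 0-based pixel centre
    cy <- ctr + (pos[2] + rec$shift_y) / vx
    wx <- round(cx); wy <- round(cy)
    ix <- (wx - half):(wx + half - 1L) + 1L        # 1-based
    iy <- (wy - half):(wy + half - 1L) + 1L
    img <- stack$data[, , rec$image_index]
    inx <- ix >= 1 & ix <= n
    iny <- iy >= 1 & iy <= n
    win <- matrix(mean(img), sb, sb)
    if (any(inx) && any(iny)) {
      win[which(inx), which(iny)] <- img[ix[inx], iy[iny]]
    }
    if (!all(inx) || !all(iny)) tbl$edge_pad[i] <- 1L
    sub[, , i] <- win
    tbl$shift_x[i] <- (cx - wx) * vx               # residual, A
    tbl$shift_y[i] <- (cy - wy) * vx
    tbl$ldfv[i] <- rec$hand_sign * pos[3]
    tbl$local_defocus[i] <- rec$defocus + tbl$ldfv[i]
  }
  tbl$image_index <- seq_len(m)
  list(stack = image_stack(sub, vx), table = validate_particle_table(tbl))
}

#' Locally refine orientations and shifts against a block density
#'
#' Exhaustive grid search over Euler-angle offsets; for each candidate
#' orientation the in-plane shift is resolved on the pixel lattice from
#' the CTF-weighted cross-correlation map between the phase-flipped
#' sub-image and the matched-filter projection of the block volume, and
#' restricted to the requested shift range. Records are updated only when
#' a candidate improves the correlation.
#'
#' @param sub_stack,sub_table output of [extract_block_images()].
#' @param block_volume a [volume_grid()] of the block.
#' @param optics an [optics_model()].
#' @param angle_range,angle_step search half-range and step for each of
#'   the three Euler angles, degrees; a zero range searches nothing.
#' @param shift_range shift search half-range in Angstrom.
#' @return The refined sub-table.
#' @export
local_refine <- function(sub_stack, sub_table, block_volume, optics,
                         angle_range = 2, angle_step = 1, shift_range = 6) {
  offs <- if (angle_range > 0) seq(-angle_range, angle_range, by = angle_step)
          else 0
  grid <- expand.grid(dr = offs, dt = offs, dp = offs)
  n <- dim(sub_stack$data)[1]
  vx <- sub_stack$voxel_size
  shift_px <- floor(shift_range / vx)
  out <- sub_table
  for (i in seq_len(nrow(sub_table))) {
    rec <- sub_table[i, ]
    ctf <- ctf_2d(optics, rec$local_defocus, n)
    fimg <- phase_flip(stats::fft(sub_stack$data[, , i]), ctf) *
      shift_ramp(n, rec$shift_x / vx, rec$shift_y / vx)
    best <- list(score = -Inf)
    for (k in seq_len(nrow(grid))) {
      e <- c(rec$rot + grid$dr[k], min(180, max(0, rec$tilt + grid$dt[k])),
             rec$psi + grid$dp[k])
      proj <- rowSums(cpp_affine_resample(block_volume$data,
                                          t(euler_matrix(e[1], e[2], e[3]))),
                      dims = 2)
      fproj <- stats::fft(proj) * abs(ctf)
      denom <- sqrt(sum(Mod(fimg)^2) * sum(Mod(fproj)^2))
      if (denom == 0) next
      cc <- Re(stats::fft(fimg * Conj(fproj), inverse = TRUE)) / denom
      # admissible integer shifts (circular indices)
      adm <- c(0:shift_px, if (shift_px > 0) (n - shift_px):(n - 1)) + 1L
      ccw <- cc[adm, adm, drop = FALSE]
      j <- arrayInd(which.max(ccw), dim(ccw))
      sc <- ccw[j]
      if (sc > best$score) {
        dd <- adm[c(j)] - 1L
        dd <- ifelse(dd > n / 2, dd - n, dd)
        best <- list(score = sc, euler = e, dshift = dd * vx)
      }
    }
    if (is.finite(best$score)) {
      out$rot[i] <- best$euler[1]
      out$tilt[i] <- best$euler[2]
      out$psi[i] <- best$euler[3]
      out$shift_x[i] <- rec$shift_x + best$dshift[1]
      out$shift_y[i] <- rec$shift_y + best$dshift[2]
    }
  }
  out
}

#' Reconstruct one block with its local mean defoci
#'
#' Delegates to [reconstruct()] with `defocus_source = "local"`, so every
#' sub-record contributes with `LDF_ij = PDF_i + LDFV_ij`.
#'
#' @param sub_stack,sub_table output of [extract_block_images()] (possibly
#'   after [local_refine()]).
#' @param optics an [optics_model()].
#' @param ... passed to [reconstruct()].
#' @return A [volume_grid()] in the block's sub-box frame (block centre at
#'   the grid centre).
#' @export
reconstruct_block <- function(sub_stack, sub_table, optics, ...) {
  reconstruct(sub_stack, sub_table, optics, defocus_source = "local", ...)
}

#' Assemble block volumes into the full frame
#'
#' Each output voxel within `r_keep` of its nearest block centre copies
#' that block's density (trilinearly resampled into the full frame).
#' Outside the kept cores, blocks are cross-faded with weights falling
#' linearly in `(distance - r_keep)` over `r_blend` and normalised to sum
#' to one wherever any block contributes.
#'
#' @param block_volumes list of [volume_grid()]s, one per block of
#'   `block_set`, each centred on its block centre.
#' @param bset a [block_set()].
#' @param full_box output box side in voxels.
#' @param voxel_size Angstrom per voxel of the output frame.
#' @return A [volume_grid()] of side `full_box`.
#' @export
combine_blocks <- function(block_volumes, bset, full_box, voxel_size) {
  nb <- length(bset$blocks)
  stopifnot(length(block_volumes) == nb)
  n <- as.integer(full_box)
  ctr <- n %/% 2L
  ax <- (seq_len(n) - 1 - ctr) * voxel_size
  coords <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  dist <- matrix(0, nrow(coords), nb)
  for (j in seq_len(nb))
    dist[, j] <- sqrt(rowSums(sweep(coords, 2, bset$blocks[[j]]$center)^2))
  w <- pmax(0, 1 - pmax(0, dist - bset$r_keep) / bset$r_blend)
  dim(w) <- dim(dist)
  # voxels inside a kept core take the nearest block only
  core <- dist <= bset$r_keep
  has_core <- rowSums(core) > 0
  if (any(has_core)) {
    nearest <- max.col(-dist[has_core, , drop = FALSE], ties.method = "first")
    w[has_core, ] <- 0
    w[cbind(which(has_core), nearest)] <- 1
  }
  # a block can only contribute where the point falls inside its grid
  for (j in seq_len(nb)) {
    bv <- block_volumes[[j]]
    sb <- dim(bv$data)[1]
    pts <- sweep(coords, 2, bset$blocks[[j]]$center) / bv$voxel_size +
      sb %/% 2L
    inside <- pts[, 1] >= 0 & pts[, 1] <= sb - 1 &
      pts[, 2] >= 0 & pts[, 2] <= sb - 1 &
      pts[, 3] >= 0 & pts[, 3] <= sb - 1
    w[!inside, j] <- 0
  }
  tot <- rowSums(w)
  ok <- tot > 0
  vals <- numeric(nrow(coords))
  for (j in seq_len(nb)) {
    sel <- ok & w[, j] > 0
    if (!any(sel)) next
    bv <- block_volumes[[j]]
    sb <- dim(bv$data)[1]
    pts <- sweep(coords[sel, , drop = FALSE], 2, bset$blocks[[j]]$center) /
      bv$voxel_size + sb %/% 2L
    vals[sel] <- vals[sel] +
      (w[sel, j] / tot[sel]) * cpp_trilinear_sample(bv$data, pts)
  }
  volume_grid(array(vals, c(n, n, n)), voxel_size)
}

#' Symmetrise a volume over a point group
#'
#' Replaces every voxel by the mean of its group-rotated copies, sampled
#' trilinearly. Idempotent up to interpolation error.
#'
#' @param vol a [volume_grid()].
#' @param group a [symmetry_group()] or group name.
#' @return A [volume_grid()].
#' @export
symmetrize <- function(vol, group) {
  if (is.character(group)) group <- symmetry_group(group)
  if (length(group) == 1L) return(vol)
  acc <- array(0, dim(vol$data))
  for (g in group) acc <- acc + cpp_affine_resample(vol$data, g)
  volume_grid(acc / length(group), vol$voxel_size, vol$origin)
}

#' End-to-end block-based reconstruction
#'
#' Expands the table by the block set's symmetry group, then per block:
#' extracts sub-images with local mean defoci, optionally refines
#' orientations/shifts against a reference block, and reconstructs the
#' block with its local defoci. The blocks are reassembled with
#' [combine_blocks()] and symmetrised.
#'
#' @param stack an [image_stack()].
#' @param table a [particle_table()] (defocus = particle defocus).
#' @param bset a [block_set()].
#' @param optics an [optics_model()].
#' @param full_box output box (defaults to the stack image size).
#' @param refine optional list of arguments for [local_refine()]; `NULL`
#'   (default) skips refinement. A reference map per block is then
#'   reconstructed from the unrefined parameters first.
#' @param use_local_defocus set `FALSE` to reconstruct every block with
#'   the unmodified particle defocus (the "blocks without local defocus"
#'   control).
#' @param ... passed to [reconstruct()].
#' @return A [volume_grid()]; per-block maps are attached as attribute
#'   `"block_volumes"`.
#' @export
block_reconstruct <- function(stack, table, bset, optics, full_box = NULL,
                              refine = NULL, use_local_defocus = TRUE, ...) {
  if (is.null(full_box)) full_box <- dim(stack$data)[1]
  exp_tbl <- expand_by_symmetry(table, bset$symmetry)
  bvols <- vector("list", length(bset$blocks))
  for (j in seq_along(bset$blocks)) {
    ext <- extract_block_images(stack, exp_tbl, bset$blocks[[j]])
    if (!use_local_defocus) ext$table$local_defocus <- ext$table$defocus
    if (!is.null(refine)) {
      ref_map <- reconstruct_block(ext$stack, ext$table, optics, ...)
      ext$table <- do.call(local_refine,
                           c(list(ext$stack, ext$table, ref_map, optics),
                             refine))
    }
    bvols[[j]] <- reconstruct_block(ext$stack, ext$table, optics, ...)
  }
  out <- combine_blocks(bvols, bset, full_box, stack$voxel_size)
  out <- symmetrize(out, bset$symmetry)
  attr(out, "block_volumes") <- bvols
  out
}
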