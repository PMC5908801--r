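# MRC2014 mode-2 (32-bit float) volumes and image stacks.
# Little-endian on write; both endiannesses accepted on read (machine stamp).

mrc_read_header <- function(con, endian) {
  h <- list()
  ints <- readBin(con, "integer", n = 10, size = 4, endian = endian)
  h$nx <- ints[1]; h$ny <- ints[2]; h$nz <- ints[3]; h$mode <- ints[4]
  h$nstart <- ints[5:7]; h$m <- ints[8:10]
  h$cella <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  h$cellb <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  h$mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = endian)
  h$dstats <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  h$ispg <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  h$nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  invisible(readBin(con, "raw", n = 100))          # extra space
  h$origin <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  h$map <- rawToChar(readBin(con, "raw", n = 4))
  h$machst <- readBin(con, "raw", n = 4)
  h$rms <- readBin(con, "numeric", n = 1, size = 4, endian = endian)
  h$nlabl <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  invisible(readBin(con, "raw", n = 800))          # labels
  h
}

mrc_detect_endian <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 212)
  machst <- readBin(con, "raw", n = 4)
  if (identical(as.integer(machst[1]), 0x11L)) "big" else "little"
}

mrc_read <- function(path) {
  endian <- mrc_detect_endian(path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- mrc_read_header(con, endian)
  if (!identical(h$map, "MAP ") && h$mode > 100)
    stop("not an MRC file (missing MAP stamp): ", path, call. = FALSE)
  if (h$mode != 2L)
    stop("only MRC mode 2 (float32) is supported, got mode ", h$mode,
         call. = FALSE)
  if (h$nsymbt > 0) invisible(readBin(con, "raw", n = h$nsymbt))
  n <- as.numeric(h$nx) * h$ny * h$nz
  data <- readBin(con, "numeric", n = n, size = 4, endian = endian)
  if (length(data) != n)
    stop("truncated MRC data block in ", path, call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("MRC data contains non-finite values: ", path, call. = FALSE)
  mx <- if (h$m[1] > 0) h$m[1] else h$nx
  voxel <- if (h$cella[1] > 0) h$cella[1] / mx else 1
  list(data = array(data, c(h$nx, h$ny, h$nz)), voxel_size = voxel,
       origin = h$origin, header = h)
}

mrc_write <- function(data, voxel_size, path, is_stack = FALSE,
                      origin = NULL) {
  if (anyNA(data) || any(!is.finite(data)))
    stop("refusing to write non-finite values to MRC", call. = FALSE)
  d <- dim(data)
  if (is.null(origin)) origin <- c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(d, 2L))                                   # nx ny nz mode
  wi(c(0L, 0L, 0L))                              # nxstart
  wi(d)                                          # mx my mz
  wf(d * voxel_size)                             # cella
  wf(c(90, 90, 90))                              # cellb
  wi(c(1L, 2L, 3L))                              # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))        # dmin dmax dmean
  wi(if (is_stack) 0L else 1L)                   # ispg
  wi(0L)                                         # nsymbt
  writeBin(raw(100), con)                        # extra
  wf(origin)                                     # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.vector(data)))                        # rms
  wi(1L)
  lab <- charToRaw(sprintf("%-80s", "blockrec"))
  writeBin(c(lab, raw(800 - length(lab))), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read / write a cubic volume in MRC format
#'
#' MRC2014 mode-2 (32-bit float) only. `write_volume` followed by
#' `read_volume` is the identity on the density values up to float32
#' rounding and preserves the voxel size exactly as `cella/mx`.
#'
#' @param path file path.
#' @return `read_volume` returns a [volume_grid()].
#' @export
read_volume <- function(path) {
  m <- mrc_read(path)
  d <- dim(m$data)
  if (d[1] != d[2] || d[1] != d[3])
    stop(sprintf("volume is not cubic (%d x %d x %d): %s",
                 d[1], d[2], d[3], path), call. = FALSE)
  volume_grid(m$data, m$voxel_size)
}

#' @param vol a [volume_grid()].
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  storage.mode(vol$data) <- "double"
  mrc_write(vol$data, vol$voxel_size, path, is_stack = FALSE)
}

#' Read / write a particle image stack in MRC format
#'
#' Stacks are stored as nz images of nx x ny pixels (MRC mode 2,
#' `ispg = 0`).
#'
#' @param path file path.
#' @return `read_stack` returns an [image_stack()].
#' @export
read_stack <- function(path) {
  m <- mrc_read(path)
  image_stack(m$data, m$voxel_size)
}

#' @param stack an [image_stack()].
#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  mrc_write(stack$data, stack$voxel_size, path, is_stack = TRUE)
}
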