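# STAR-dialect particle tables: one data block, a loop_ header of named
# tags, whitespace-delimited rows. Core columns use RELION tag names so the
# tables are legible to standard cryo-EM tooling; package-specific columns
# are prefixed _blk_. Values are printed with 17 significant digits so a
# write/read cycle is lossless for doubles.

star_tag_map <- c(
  image_index = "_blkImageIndex",
  rot         = "_rlnAngleRot",
  tilt        = "_rlnAngleTilt",
  psi         = "_rlnAnglePsi",
  shift_x     = "_rlnOriginXAngst",
  shift_y     = "_rlnOriginYAngst",
  defocus     = "_rlnDefocusU",
  hand_sign   = "_blkHandSign"
)

#' Write a particle table as a STAR-dialect text file
#'
#' @param tbl a [particle_table()].
#' @param path output path.
#' @export
write_particles <- function(tbl, path) {
  tbl <- validate_particle_table(tbl)
  num <- vapply(tbl, is.numeric, logical(1))
  if (any(vapply(tbl[num], function(x) any(!is.finite(x)), logical(1))))
    stop("refusing to write non-finite values to particle table",
         call. = FALSE)
  tags <- ifelse(names(tbl) %in% names(star_tag_map),
                 star_tag_map[names(tbl)],
                 paste0("_blk_", names(tbl)))
  lines <- c("", "data_particles", "", "loop_",
             sprintf("%s #%d", tags, seq_along(tags)))
  fmt_col <- function(x) {
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  }
  body <- do.call(paste, c(lapply(tbl, fmt_col), list(sep = "\t")))
  writeLines(c(lines, body, ""), path)
  invisible(path)
}

#' Read a particle table from a STAR-dialect text file
#'
#' The first `data_` block's first `loop_` is parsed. Mandatory columns
#' (Euler angles, shifts, defocus, image index, hand sign) must be present;
#' a missing one raises a schema error. Unknown tags are kept as extra
#' columns.
#'
#' @param path file path.
#' @return A [particle_table()].
#' @export
read_particles <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ld <- which(startsWith(lines, "data_"))
  if (!length(ld)) stop("no data_ block in ", path, call. = FALSE)
  ll <- which(lines == "loop_")
  ll <- ll[ll > ld[1]]
  if (!length(ll)) stop("no loop_ in ", path, call. = FALSE)
  i <- ll[1] + 1L
  tags <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("\\s+#\\d+$", "", lines[i]))
    i <- i + 1L
  }
  rows <- character()
  while (i <= length(lines) && !startsWith(lines[i], "data_")) {
    rows <- c(rows, lines[i])
    i <- i + 1L
  }
  fields <- strsplit(rows, "\\s+")
  if (length(fields) && any(lengths(fields) != length(tags)))
    stop("row width does not match tag count in ", path, call. = FALSE)
  cols <- lapply(seq_along(tags), function(j)
    vapply(fields, `[[`, character(1), j))
  rev_map <- stats::setNames(names(star_tag_map), star_tag_map)
  nm <- ifelse(tags %in% names(rev_map), rev_map[tags],
               sub("^_blk_", "", tags))
  tbl <- as.data.frame(lapply(cols, function(x) {
    y <- suppressWarnings(as.numeric(x))
    if (anyNA(y)) x else y
  }), col.names = nm, optional = TRUE)
  names(tbl) <- nm
  missing <- setdiff(required_particle_cols, names(tbl))
  if (length(missing))
    stop("particle table schema error, missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  validate_particle_table(tbl)
}
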