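# Plain-text, versioned serialization for voxel masks and dose grids.
# Line-oriented; masks are run-length encoded along the flattened
# (x-fastest) voxel order. Paths ending in .gz are transparently gzipped.

open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write / read a voxel-mask structure as versioned text
#'
#' The `SVOL 1` dialect stores the grid (origin, spacing, shape), the
#' structure name and a run-length encoding of the flattened mask. It
#' round-trips [structure_volume()] objects exactly.
#'
#' @param s a [structure_volume()].
#' @param path output file; a `.gz` suffix enables gzip compression.
#' @return `write_structure_text()` returns `path` invisibly;
#'   `read_structure_text()` returns the [structure_volume()].
#' @export
write_structure_text <- function(s, path) {
  r <- rle(as.integer(s$mask))
  con <- open_text(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "SVOL 1",
    paste("name", s$name),
    paste("shape", paste(s$grid$shape, collapse = " ")),
    paste("origin", paste(sprintf("%.6g", s$grid$origin), collapse = " ")),
    paste("spacing", paste(sprintf("%.6g", s$grid$spacing), collapse = " ")),
    paste("rle_values", paste(r$values, collapse = " ")),
    paste("rle_lengths", paste(r$lengths, collapse = " "))
  ), con)
  invisible(path)
}

read_kv_lines <- function(lines) {
  sp <- regexpr(" ", lines)
  keys <- ifelse(sp > 0, substr(lines, 1, sp - 1), lines)
  vals <- ifelse(sp > 0, substring(lines, sp + 1), "")
  stats::setNames(as.list(vals), keys)
}

num_field <- function(kv, key) as.numeric(strsplit(kv[[key]], " +")[[1]])

#' @rdname write_structure_text
#' @export
read_structure_text <- function(path) {
  con <- open_text(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 1L || lines[1] != "SVOL 1") {
    arc_format_error(sprintf("'%s' is not an SVOL version-1 structure file", path))
  }
  kv <- read_kv_lines(lines[-1])
  grid <- grid_spec(origin = num_field(kv, "origin"),
                    spacing = num_field(kv, "spacing"),
                    shape = num_field(kv, "shape"))
  vals <- as.integer(num_field(kv, "rle_values"))
  lens <- as.integer(num_field(kv, "rle_lengths"))
  flat <- inverse.rle(structure(list(values = vals, lengths = lens), class = "rle"))
  if (length(flat) != prod(grid$shape)) {
    arc_format_error("structure file mask length does not match grid shape")
  }
  structure_volume(kv[["name"]], grid, array(flat == 1L, grid$shape))
}

#' Write / read a dose grid as versioned text
#'
#' The `DGRID 1` dialect stores the grid header and dose values (Gy) in
#' flattened x-fastest order at `%.9g` precision.
#'
#' @param d a [dose_grid()].
#' @param path output file; a `.gz` suffix enables gzip compression.
#' @return `write_dose_text()` returns `path` invisibly;
#'   `read_dose_text()` returns the [dose_grid()].
#' @export
write_dose_text <- function(d, path) {
  con <- open_text(path, "wb")
  on.exit(close(con))
  writeLines(c(
    "DGRID 1",
    paste("shape", paste(d$grid$shape, collapse = " ")),
    paste("origin", paste(sprintf("%.6g", d$grid$origin), collapse = " ")),
    paste("spacing", paste(sprintf("%.6g", d$grid$spacing), collapse = " ")),
    paste("dose", paste(sprintf("%.9g", as.vector(d$dose)), collapse = " "))
  ), con)
  invisible(path)
}

#' @rdname write_dose_text
#' @export
read_dose_text <- function(path) {
  con <- open_text(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 1L || lines[1] != "DGRID 1") {
    arc_format_error(sprintf("'%s' is not a DGRID version-1 dose file", path))
  }
  kv <- read_kv_lines(lines[-1])
  grid <- grid_spec(origin = num_field(kv, "origin"),
                    spacing = num_field(kv, "spacing"),
                    shape = num_field(kv, "shape"))
  vals <- num_field(kv, "dose")
  if (length(vals) != prod(grid$shape)) {
    arc_format_error("dose file value count does not match grid shape")
  }
  dose_grid(grid, array(vals, grid$shape))
}

# Even-odd point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize planar contours into a voxel mask
#'
#' Converts closed planar contours (as exported in RT-STRUCT files) into a
#' [structure_volume()] by even-odd fill: contours are matched to the grid
#' slice whose z voxel-centre lies within half a slice spacing of the contour
#' plane, and overlapping contours on one slice toggle (so holes are
#' supported).
#'
#' @param contours list of numeric matrices, each `n x 3` (x, y, z in mm) with
#'   constant z per contour, vertices in order, implicitly closed.
#' @param grid a [grid_spec()].
#' @param name label for the resulting structure.
#' @return A [structure_volume()].
#' @export
contours_to_mask <- function(contours, grid, name = "structure") {
  axes <- grid_axes(grid)
  mask <- array(FALSE, grid$shape)
  px <- rep(axes$x, times = grid$shape[2])
  py <- rep(axes$y, each = grid$shape[1])
  for (ct in contours) {
    ct <- as.matrix(ct)
    if (ncol(ct) != 3L || nrow(ct) < 3L) {
      arc_input_error("contours_to_mask: each contour must be an n x 3 matrix with n >= 3")
    }
    z0 <- ct[1, 3]
    ks <- which(abs(axes$z - z0) <= grid$spacing[3] / 2 + 1e-9)
    if (length(ks) == 0L) next
    k <- ks[which.min(abs(axes$z[ks] - z0))]
    inside <- point_in_polygon(px, py, ct[, 1], ct[, 2])
    slab <- matrix(inside, grid$shape[1], grid$shape[2])
    mask[, , k] <- xor(mask[, , k], slab)
  }
  structure_volume(name, grid, mask)
}
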