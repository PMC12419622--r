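#' Regular 3D voxel grid specification
#'
#' Defines the sampling of all voxel masks and dose arrays in the package:
#' `origin` is the physical position (mm) of the centre of voxel `[1, 1, 1]`,
#' `spacing` the voxel pitch (mm) and `shape` the number of voxels along each
#' axis. Axes are fixed as x = left-right, y = anterior-posterior,
#' z = inferior-superior (superior = +z).
#'
#' @param origin numeric length-3, mm.
#' @param spacing numeric length-3, mm per voxel, all > 0.
#' @param shape integer length-3 voxel counts, all > 0.
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(origin = c(-20, -20, -20), spacing = c(1, 1, 1),
#'                shape = c(41, 41, 41))
#' @export
grid_spec <- function(origin = c(0, 0, 0), spacing = c(1, 1, 1), shape) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  if (length(origin) != 3L || length(spacing) != 3L || length(shape) != 3L) {
    arc_input_error("grid_spec: origin, spacing and shape must have length 3")
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    arc_input_error("grid_spec: spacing must be positive on all axes")
  }
  if (any(is.na(shape)) || any(shape <= 0L)) {
    arc_input_error("grid_spec: shape must be positive on all axes")
  }
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# Physical coordinates of voxel centres along each axis.
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

# min/max voxel-centre coordinates per axis: 2 x 3 matrix.
grid_extent <- function(grid) {
  rbind(min = grid$origin,
        max = grid$origin + (grid$shape - 1) * grid$spacing)
}

grid_voxel_cc <- function(grid) prod(grid$spacing) / 1000

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    identical(a$shape, b$shape)
}

#' Named voxel-mask structure on a grid
#'
#' A contoured structure (target or organ at risk) stored as a boolean voxel
#' mask; the derived `volume_cc` is the number of true voxels times the voxel
#' volume.
#'
#' @param name character label, e.g. `"GTV"`.
#' @param grid a [grid_spec()].
#' @param mask logical array with `dim(mask) == grid$shape`.
#' @return A `structure_volume` object with fields `name`, `grid`, `mask`,
#'   `volume_cc`.
#' @export
structure_volume <- function(name, grid, mask) {
  if (!inherits(grid, "grid_spec")) arc_input_error("structure_volume: grid must be a grid_spec")
  if (!is.logical(mask) || !identical(dim(mask), as.integer(grid$shape))) {
    arc_input_error("structure_volume: mask must be a logical array matching grid shape")
  }
  s <- structure(list(name = as.character(name), grid = grid, mask = mask),
                 class = "structure_volume")
  s$volume_cc <- structure_volume_cc(s)
  s
}

#' @export
print.structure_volume <- function(x, ...) {
  cat(sprintf("<structure_volume> '%s': %.4g cc (%d voxels) on %d x %d x %d grid\n",
              x$name, x$volume_cc, sum(x$mask),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Volume of a structure in cc
#'
#' @param s a [structure_volume()].
#' @return Volume in cc (true voxel count times voxel volume / 1000 mm^3).
#' @export
structure_volume_cc <- function(s) {
  sum(s$mask) * prod(s$grid$spacing) / 1000
}

#' Anisotropic margin specification
#'
#' Six non-negative directional margins in mm, named by the anatomical
#' direction they expand toward.
#'
#' @param sup,inf,left,right,ant,post margins in mm, each >= 0.
#' @return A `margin_spec` object.
#' @seealso [margin_spec_iso()] for an isotropic margin.
#' @export
margin_spec <- function(sup = 0, inf = 0, left = 0, right = 0, ant = 0, post = 0) {
  m <- c(sup = sup, inf = inf, left = left, right = right, ant = ant, post = post)
  if (any(!is.finite(m)) || any(m < 0)) {
    arc_input_error("margin_spec: all margins must be finite and non-negative")
  }
  structure(as.list(m), class = "margin_spec")
}

#' @rdname margin_spec
#' @param mm isotropic margin in mm.
#' @export
margin_spec_iso <- function(mm) {
  margin_spec(sup = mm, inf = mm, left = mm, right = mm, ant = mm, post = mm)
}

#' @export
print.margin_spec <- function(x, ...) {
  cat(sprintf("<margin_spec> sup %g, inf %g, left %g, right %g, ant %g, post %g mm\n",
              x$sup, x$inf, x$left, x$right, x$ant, x$post))
  invisible(x)
}

#' Radius of a sphere of given volume
#'
#' @param volume_cc sphere volume in cc.
#' @return Radius in mm, `(3 V / (4 pi))^(1/3)` with V in mm^3.
#' @examples
#' sphere_radius_mm(0.51)  # 4.957 mm
#' @export
sphere_radius_mm <- function(volume_cc) {
  (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)
}

#' Voxelize a sphere of prescribed volume
#'
#' Builds a spherical structure by the voxel-centre-inside rule: a voxel is in
#' the mask when its centre lies within the sphere radius of `center`. At a
#' 1 mm isotropic grid the voxelized volume agrees with the requested volume
#' to within about 2 percent for clinically sized targets.
#'
#' @param center numeric length-3 sphere centre, mm.
#' @param volume_cc requested volume in cc, > 0.
#' @param grid a [grid_spec()]; the sphere must fit inside the grid's
#'   voxel-centre extent or an error naming the violating axis is raised.
#' @param name label for the resulting structure.
#' @return A [structure_volume()].
#' @export
make_sphere_structure <- function(center, volume_cc, grid, name = "sphere") {
  if (!is.numeric(volume_cc) || length(volume_cc) != 1L || volume_cc <= 0) {
    arc_input_error("make_sphere_structure: volume_cc must be a positive scalar")
  }
  center <- as.numeric(center)
  if (length(center) != 3L) arc_input_error("make_sphere_structure: center must have length 3")
  r <- sphere_radius_mm(volume_cc)
  ext <- grid_extent(grid)
  ax_names <- c("x", "y", "z")
  for (a in 1:3) {
    if (center[a] - r < ext["min", a] || center[a] + r > ext["max", a]) {
      arc_geometry_error(sprintf(
        "sphere of radius %.3f mm at %g mm extends beyond the grid along axis %s",
        r, center[a], ax_names[a]))
    }
  }
  axes <- grid_axes(grid)
  d2 <- outer(outer((axes$x - center[1])^2, (axes$y - center[2])^2, "+"),
              (axes$z - center[3])^2, "+")
  structure_volume(name, grid, d2 <= r * r)
}

# Voxels of the mask with at least one false 6-neighbour (grid border counts
# as outside). Used for cheap dilation sources and BEV silhouettes.
surface_mask <- function(mask) {
  d <- dim(mask)
  interior <- mask
  shift_ok <- function(axis, dir) {
    out <- array(FALSE, d)
    n <- d[axis]
    if (n < 2L) return(out)
    idx_to <- switch(axis, `1` = 2:n, `2` = 2:n, `3` = 2:n)
    if (axis == 1L) {
      if (dir > 0) out[1:(n - 1), , ] <- mask[2:n, , ] else out[2:n, , ] <- mask[1:(n - 1), , ]
    } else if (axis == 2L) {
      if (dir > 0) out[, 1:(n - 1), ] <- mask[, 2:n, ] else out[, 2:n, ] <- mask[, 1:(n - 1), ]
    } else {
      if (dir > 0) out[, , 1:(n - 1)] <- mask[, , 2:n] else out[, , 2:n] <- mask[, , 1:(n - 1)]
    }
    out
  }
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      interior <- interior & shift_ok(axis, dir)
    }
  }
  mask & !interior
}

# Physical coordinates (n x 3 matrix) of TRUE voxels.
mask_coords <- function(mask, grid) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(grid$origin[1] + (idx[, 1] - 1) * grid$spacing[1],
        grid$origin[2] + (idx[, 2] - 1) * grid$spacing[2],
        grid$origin[3] + (idx[, 3] - 1) * grid$spacing[3])
}

#' Expand a structure by anisotropic margins
#'
#' Morphological (Minkowski) dilation of the voxel mask by a
#' half-ellipsoid-per-octant kernel: an offset `p` belongs to the kernel when
#' `(px/mx)^2 + (py/my)^2 + (pz/mz)^2 <= 1`, where each half-axis takes the
#' directional margin of the octant `p` points into (e.g. `+z` offsets use the
#' superior margin). This is the common planning-system expansion convention;
#' vendor implementations differ in detail, so volumes printed by commercial
#' systems are reference values rather than exact targets.
#'
#' @param s a [structure_volume()].
#' @param m a [margin_spec()].
#' @param name label for the result; defaults to `s$name` plus a suffix.
#' @return The dilated [structure_volume()], always a voxelwise superset of
#'   the input. All-zero margins return the input mask unchanged.
#'   If the expansion would cross the grid boundary an error is raised
#'   (masks are never silently truncated).
#' @export
expand_margin <- function(s, m, name = paste0(s$name, "+margin")) {
  if (!inherits(m, "margin_spec")) arc_input_error("expand_margin: m must be a margin_spec")
  mv <- unlist(m[c("sup", "inf", "left", "right", "ant", "post")])
  if (all(mv == 0)) {
    return(structure_volume(name, s$grid, s$mask))
  }
  sp <- s$grid$spacing
  # Kernel offsets in voxel steps; +x = left, +y = posterior, +z = superior.
  # Plain centre-to-centre Minkowski dilation (the scipy/ITK convention). A
  # binary mask only localizes the surface to within half a voxel, so any
  # offset-kernel dilation carries an O(spacing/2) radial bias relative to
  # the continuous Minkowski sum; see the methods vignette for the measured
  # effect and why no half-voxel "correction" convention removes it.
  steps <- function(mpos, mneg, h) seq.int(-ceiling(mneg / h), ceiling(mpos / h))
  ix <- steps(m$left, m$right, sp[1])
  iy <- steps(m$post, m$ant, sp[2])
  iz <- steps(m$sup, m$inf, sp[3])
  off <- as.matrix(expand.grid(i = ix, j = iy, k = iz))
  omm <- sweep(off, 2, sp, `*`)
  term <- function(v, mpos, mneg) {
    t <- numeric(length(v))
    pos <- v > 0
    neg <- v < 0
    t[pos] <- if (mpos == 0) Inf else (v[pos] / mpos)^2
    t[neg] <- if (mneg == 0) Inf else (v[neg] / mneg)^2
    t
  }
  inside <- term(omm[, 1], m$left, m$right) +
    term(omm[, 2], m$post, m$ant) +
    term(omm[, 3], m$sup, m$inf) <= 1 + 1e-9
  off <- off[inside, , drop = FALSE]

  src <- which(surface_mask(s$mask), arr.ind = TRUE)
  out <- s$mask
  shp <- s$grid$shape
  for (k in seq_len(nrow(off))) {
    ni <- src[, 1] + off[k, 1]
    nj <- src[, 2] + off[k, 2]
    nk <- src[, 3] + off[k, 3]
    if (any(ni < 1L | ni > shp[1] | nj < 1L | nj > shp[2] | nk < 1L | nk > shp[3])) {
      arc_geometry_error(
        "expand_margin: expansion would extend beyond the grid boundary; enlarge the grid instead of truncating")
    }
    out[cbind(ni, nj, nk)] <- TRUE
  }
  structure_volume(name, s$grid, out)
}
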