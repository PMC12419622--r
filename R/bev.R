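#' Project 3D points into the beam's-eye view
#'
#' Maps points (patient coordinates, mm) into the isocenter-plane coordinates
#' of the beam's-eye view at a gantry angle. The gantry follows IEC 61217:
#' at 0 degrees the source sits anterior of the patient at distance `sad`
#' from the isocenter, at 90 degrees on the patient's left. The BEV x axis is
#' the leaf-travel direction; the BEV y axis is patient z (collimator 0,
#' coplanar arc).
#'
#' In `divergent` mode each point is projected from the source onto the
#' isocenter plane by similar triangles (the physically correct model);
#' `parallel` mode simply drops the beam-axis coordinate, a small-angle
#' approximation useful for cross-checks.
#'
#' @param points numeric `n x 3` matrix of (x, y, z) in mm.
#' @param gantry_angle gantry angle in degrees.
#' @param machine a [machine_model()] (supplies `sad`).
#' @param mode `"divergent"` (default) or `"parallel"`.
#' @return A `bev_silhouette`: list with `gantry_angle` and `points`
#'   (`n x 2` matrix of BEV x, y in mm at the isocenter plane).
#' @export
project_points_bev <- function(points, gantry_angle, machine,
                               mode = c("divergent", "parallel")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  if (ncol(points) != 3L) arc_input_error("project_points_bev: points must be n x 3")
  th <- gantry_angle * pi / 180
  xb <- points[, 1] * cos(th) + points[, 2] * sin(th)
  yb <- points[, 3]
  if (mode == "divergent") {
    depth <- machine$sad + (-points[, 1] * sin(th) + points[, 2] * cos(th))
    if (any(depth <= 1e-6)) {
      arc_geometry_error("project_points_bev: point at or behind the source in divergent mode")
    }
    sc <- machine$sad / depth
    xb <- xb * sc
    yb <- yb * sc
  }
  structure(list(gantry_angle = gantry_angle %% 360,
                 points = cbind(x = xb, y = yb)),
            class = "bev_silhouette")
}

#' Project a structure's silhouette into the beam's-eye view
#'
#' Extracts the structure's surface voxels (6-connectivity; cheap and
#' sufficient because interior voxels can never set the silhouette extremes)
#' and projects their centres with [project_points_bev()]. Set
#' `voxels = "all"` to project the full volume, which serves as the brute
#' force oracle for the surface shortcut.
#'
#' @param s a non-empty [structure_volume()].
#' @param gantry_angle gantry angle in degrees.
#' @param machine a [machine_model()].
#' @param mode projection mode, see [project_points_bev()].
#' @param voxels `"surface"` (default) or `"all"`.
#' @return A `bev_silhouette`.
#' @export
project_to_bev <- function(s, gantry_angle, machine,
                           mode = c("divergent", "parallel"),
                           voxels = c("surface", "all")) {
  mode <- match.arg(mode)
  voxels <- match.arg(voxels)
  if (!any(s$mask)) arc_input_error("project_to_bev: structure is empty")
  m <- if (voxels == "surface") surface_mask(s$mask) else s$mask
  project_points_bev(mask_coords(m, s$grid), gantry_angle, machine, mode)
}

#' @export
print.bev_silhouette <- function(x, ...) {
  cat(sprintf("<bev_silhouette> gantry %.2f deg, %d points\n",
              x$gantry_angle, nrow(x$points)))
  invisible(x)
}

#' Per-leaf-pair aperture
#'
#' Open intervals at the isocenter plane for one gantry angle. Closed pairs
#' are parked with both tips at x = 0 and contribute zero open area (and full
#' blocking, since their open interval has zero width).
#'
#' @param gantry_angle degrees.
#' @param left,right numeric vectors of leaf tip positions per pair, mm;
#'   `left <= right` for open pairs.
#' @param open logical vector: which pairs are open.
#' @param machine a [machine_model()].
#' @return An `aperture` object.
#' @export
aperture <- function(gantry_angle, left, right, open, machine) {
  np <- machine$n_pairs
  if (length(left) != np || length(right) != np || length(open) != np) {
    arc_input_error("aperture: left/right/open must have one entry per leaf pair")
  }
  if (any(open & (left > right + 1e-9))) {
    arc_domain_error("aperture: open pairs must satisfy left <= right")
  }
  structure(list(gantry_angle = gantry_angle %% 360,
                 left = as.numeric(left), right = as.numeric(right),
                 open = as.logical(open), machine = machine),
            class = "aperture")
}

#' @export
print.aperture <- function(x, ...) {
  cat(sprintf("<aperture> gantry %.2f deg, %d/%d pairs open, %.1f mm^2 open area\n",
              x$gantry_angle, sum(x$open), length(x$open), aperture_open_area(x)))
  invisible(x)
}

#' Fit the conformal aperture to a BEV silhouette
#'
#' For each leaf-pair band `[y_i, y_{i+1})` (half-open, so bands partition the
#' plane): if any silhouette point falls in the band the pair opens from the
#' band's minimum x minus `margin_mm` to its maximum x plus `margin_mm`
#' (clamped to the machine's leaf travel limit); otherwise it is closed. With
#' `margin_mm = 0` this is the zero-margin reference aperture used by the
#' intrusion metric.
#'
#' @param silhouette a `bev_silhouette` from [project_to_bev()].
#' @param machine a [machine_model()].
#' @param margin_mm non-negative margin added on both sides of each open pair.
#' @return An [aperture()]. An empty silhouette yields all pairs closed.
#' @export
fit_conformal_aperture <- function(silhouette, machine, margin_mm = 0) {
  if (margin_mm < 0) arc_input_error("fit_conformal_aperture: margin_mm must be >= 0")
  b <- machine$leaf_pair_boundaries
  np <- machine$n_pairs
  left <- numeric(np); right <- numeric(np); open <- logical(np)
  pts <- silhouette$points
  if (!is.null(pts) && nrow(pts) > 0L) {
    band <- findInterval(pts[, 2], b)  # i when b[i] <= y < b[i+1]
    keep <- band >= 1L & band <= np & pts[, 2] < b[np + 1L]
    if (any(keep)) {
      band <- band[keep]
      x <- pts[keep, 1]
      lo <- tapply(x, band, min)
      hi <- tapply(x, band, max)
      ix <- as.integer(names(lo))
      lim <- machine$max_leaf_position
      left[ix] <- pmax(-lim, lo - margin_mm)
      right[ix] <- pmin(lim, hi + margin_mm)
      open[ix] <- TRUE
    }
  }
  aperture(silhouette$gantry_angle, left, right, open, machine)
}

#' Open area of an aperture
#'
#' @param a an [aperture()].
#' @return Sum over open pairs of `(right - left) * band_height`, mm^2.
#' @export
aperture_open_area <- function(a) {
  h <- diff(a$machine$leaf_pair_boundaries)
  sum(((a$right - a$left) * h)[a$open])
}
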