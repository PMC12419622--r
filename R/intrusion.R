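#' Intrusion area of one leaf pair
#'
#' The part of a reference opening blocked by the actual leaves, per band:
#' `((rR - rL) - overlap) * band_height`, where `overlap` is the length of
#' the intersection of the reference interval `(rL, rR)` and the actual open
#' interval `(aL, aR)` (zero when the actual pair is closed). Leaves
#' retracted beyond the reference contribute nothing — intrusion-only
#' accounting, no credit and no penalty for over-opening.
#'
#' All arguments are vectorized over leaf pairs.
#'
#' @param ref_left,ref_right reference open interval, mm, `ref_left <= ref_right`.
#' @param act_left,act_right actual open interval, mm.
#' @param act_open logical; `FALSE` marks a closed actual pair.
#' @param band_height leaf band height, mm.
#' @return Intrusion area in mm^2 (vector).
#' @examples
#' leaf_pair_intrusion(-10, 10, -5, 10, TRUE, 5)  # 25 mm^2
#' @export
leaf_pair_intrusion <- function(ref_left, ref_right, act_left, act_right,
                                act_open = TRUE, band_height) {
  if (any(ref_left > ref_right + 1e-9)) {
    arc_domain_error("leaf_pair_intrusion: reference interval is inverted")
  }
  if (any(act_open & (act_left > act_right + 1e-9))) {
    arc_domain_error("leaf_pair_intrusion: actual interval is inverted")
  }
  ov <- pmax(0, pmin(ref_right, act_right) - pmax(ref_left, act_left))
  ov[!act_open] <- 0
  ((ref_right - ref_left) - ov) * band_height
}

#' Ratio of area difference between a plan and its zero-margin reference
#'
#' For every control point of the plan, the zero-margin reference aperture is
#' fitted to the target's BEV silhouette at that control point's actual
#' gantry angle; the intrusion of the plan's actual leaves into that
#' reference is accumulated with [leaf_pair_intrusion()] over all pairs whose
#' reference is open (pairs with a closed reference are excluded from both
#' numerator and denominator). The score is
#' `100 * sum(intrusion area) / sum(reference open area)`: 0 percent means
#' the plan never encroaches on the target silhouette, 100 percent means the
#' target is fully blocked everywhere.
#'
#' Control points are weighted equally by default, matching a segment-wise
#' reading of the metric; `mu_weighted = TRUE` weights each control point by
#' the monitor units of its following segment (start-of-segment convention,
#' final control point weight 0).
#'
#' @param plan an [arc_plan()].
#' @param target a [structure_volume()] sharing the plan's isocenter frame.
#' @param machine machine model; defaults to the plan's.
#' @param projection `"divergent"` or `"parallel"`, see [project_points_bev()].
#' @param mu_weighted weight control points by segment MU instead of equally.
#' @return An `area_difference_result` with fields `ratio_percent`,
#'   `total_intrusion_mm2`, `total_reference_mm2`, `mu_weighted` and
#'   `per_control_point` (data frame: index, gantry_angle, intrusion and
#'   reference areas, n_open_reference_pairs). If the reference aperture is
#'   closed at every control point (target never in view) an
#'   undefined-metric error is raised.
#' @export
area_difference_ratio <- function(plan, target, machine = plan$machine,
                                  projection = c("divergent", "parallel"),
                                  mu_weighted = FALSE) {
  projection <- match.arg(projection)
  if (!any(target$mask)) arc_input_error("area_difference_ratio: target structure is empty")
  surf <- mask_coords(surface_mask(target$mask), target$grid)
  n <- n_control_points(plan)
  h <- diff(machine$leaf_pair_boundaries)
  intr <- numeric(n); ref_area <- numeric(n); n_open <- integer(n)
  for (i in seq_len(n)) {
    sil <- project_points_bev(surf, plan$gantry_angle[i], machine, projection)
    ref <- fit_conformal_aperture(sil, machine, 0)
    op <- ref$open
    ref_area[i] <- aperture_open_area(ref)
    n_open[i] <- sum(op)
    if (any(op)) {
      intr[i] <- sum(leaf_pair_intrusion(ref$left[op], ref$right[op],
                                         plan$bank_a[i, op], plan$bank_b[i, op],
                                         TRUE, h[op]))
    }
  }
  w <- if (mu_weighted) c(segment_mu(plan), 0) else rep(1, n)
  tot_ref <- sum(w * ref_area)
  if (tot_ref <= 1e-12) {
    arc_undefined_metric("area_difference_ratio: target is never in view (reference aperture closed at every control point)")
  }
  tot_int <- sum(w * intr)
  structure(list(
    ratio_percent = 100 * tot_int / tot_ref,
    total_intrusion_mm2 = tot_int,
    total_reference_mm2 = tot_ref,
    mu_weighted = mu_weighted,
    projection = projection,
    per_control_point = data.frame(
      index = seq_len(n),
      gantry_angle = plan$gantry_angle,
      intrusion_mm2 = intr,
      reference_mm2 = ref_area,
      n_open_reference_pairs = n_open)
  ), class = "area_difference_result")
}

#' @export
print.area_difference_result <- function(x, ...) {
  cat(sprintf("<area_difference_result> ratio %.3f%% (%s%s projection)\n",
              x$ratio_percent, if (x$mu_weighted) "MU-weighted, " else "",
              x$projection))
  cat(sprintf("  intrusion %.1f mm^2 over reference %.1f mm^2 across %d control points\n",
              x$total_intrusion_mm2, x$total_reference_mm2,
              nrow(x$per_control_point)))
  invisible(x)
}
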