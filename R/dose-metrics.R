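#' 3D dose grid
#'
#' @param grid a [grid_spec()].
#' @param dose numeric array of doses in Gy, non-negative, with
#'   `dim(dose) == grid$shape`.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(grid, dose) {
  if (!inherits(grid, "grid_spec")) arc_input_error("dose_grid: grid must be a grid_spec")
  if (!is.numeric(dose) || !identical(dim(dose), as.integer(grid$shape))) {
    arc_input_error("dose_grid: dose must be a numeric array matching grid shape")
  }
  if (any(dose < 0)) arc_input_error("dose_grid: doses must be non-negative")
  structure(list(grid = grid, dose = dose), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d, max %.3f Gy\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], max(x$dose)))
  invisible(x)
}

#' Resample a dose grid onto another grid by trilinear interpolation
#'
#' Voxel centres of `target_grid` are interpolated in the source dose array;
#' positions outside the source voxel-centre extent get zero dose.
#'
#' @param d a [dose_grid()].
#' @param target_grid a [grid_spec()].
#' @return A [dose_grid()] on `target_grid`.
#' @export
resample_dose <- function(d, target_grid) {
  if (grids_identical(d$grid, target_grid)) return(d)
  ax <- grid_axes(target_grid)
  shp <- target_grid$shape
  # fractional (0-based) source indices per target axis coordinate
  fx <- (ax$x - d$grid$origin[1]) / d$grid$spacing[1]
  fy <- (ax$y - d$grid$origin[2]) / d$grid$spacing[2]
  fz <- (ax$z - d$grid$origin[3]) / d$grid$spacing[3]
  nvox <- prod(shp)
  FX <- rep(fx, times = shp[2] * shp[3])
  FY <- rep(rep(fy, each = shp[1]), times = shp[3])
  FZ <- rep(fz, each = shp[1] * shp[2])
  sshp <- d$grid$shape
  inb <- FX >= 0 & FX <= sshp[1] - 1 & FY >= 0 & FY <= sshp[2] - 1 &
    FZ >= 0 & FZ <= sshp[3] - 1
  out <- numeric(nvox)
  if (any(inb)) {
    fx0 <- pmin(floor(FX[inb]), sshp[1] - 2); fx0 <- pmax(fx0, 0)
    fy0 <- pmin(floor(FY[inb]), sshp[2] - 2); fy0 <- pmax(fy0, 0)
    fz0 <- pmin(floor(FZ[inb]), sshp[3] - 2); fz0 <- pmax(fz0, 0)
    tx <- FX[inb] - fx0; ty <- FY[inb] - fy0; tz <- FZ[inb] - fz0
    at <- function(i, j, k) d$dose[1 + i + sshp[1] * (j + sshp[2] * k)]
    out[inb] <-
      at(fx0,     fy0,     fz0)     * (1 - tx) * (1 - ty) * (1 - tz) +
      at(fx0 + 1, fy0,     fz0)     * tx       * (1 - ty) * (1 - tz) +
      at(fx0,     fy0 + 1, fz0)     * (1 - tx) * ty       * (1 - tz) +
      at(fx0 + 1, fy0 + 1, fz0)     * tx       * ty       * (1 - tz) +
      at(fx0,     fy0,     fz0 + 1) * (1 - tx) * (1 - ty) * tz +
      at(fx0 + 1, fy0,     fz0 + 1) * tx       * (1 - ty) * tz +
      at(fx0,     fy0 + 1, fz0 + 1) * (1 - tx) * ty       * tz +
      at(fx0 + 1, fy0 + 1, fz0 + 1) * tx       * ty       * tz
  }
  dose_grid(target_grid, array(out, shp))
}

# Put dose on the structure's grid (resampling if needed) and return the array.
align_dose <- function(d, s) {
  if (!inherits(d, "dose_grid")) arc_input_error("expected a dose_grid")
  if (!inherits(s, "structure_volume")) arc_input_error("expected a structure_volume")
  resample_dose(d, s$grid)$dose
}

#' Conformation number (coverage times selectivity)
#'
#' `CN = (VT,ref / VT) * (VT,ref / Vref)` where `VT` is the target volume,
#' `Vref` the total volume receiving at least the reference dose and `VT,ref`
#' the target volume receiving at least the reference dose. The threshold is
#' closed (`>=`). `Vref` is taken over the whole grid unless a `body` mask is
#' supplied.
#'
#' @param dose a [dose_grid()].
#' @param target a non-empty [structure_volume()].
#' @param ref_dose_gy reference (prescription) dose in Gy, > 0.
#' @param body optional [structure_volume()] restricting `Vref`.
#' @return List with `cn`, `v_t`, `v_ref`, `v_t_ref` (cc).
#' @export
conformation_number <- function(dose, target, ref_dose_gy, body = NULL) {
  if (ref_dose_gy <= 0) arc_input_error("conformation_number: ref_dose_gy must be > 0")
  if (!any(target$mask)) arc_input_error("conformation_number: target is empty")
  dd <- align_dose(dose, target)
  vv <- grid_voxel_cc(target$grid)
  hot <- dd >= ref_dose_gy
  if (!is.null(body)) hot <- hot & body$mask
  v_t <- sum(target$mask) * vv
  v_ref <- sum(hot) * vv
  v_t_ref <- sum(hot & target$mask) * vv
  if (v_ref == 0) arc_undefined_metric("conformation_number: no voxel reaches the reference dose")
  list(cn = (v_t_ref / v_t) * (v_t_ref / v_ref),
       v_t = v_t, v_ref = v_ref, v_t_ref = v_t_ref)
}

#' Conformality index (prescription volume over target volume)
#'
#' @inheritParams conformation_number
#' @return `Vref / VT` as a single number.
#' @export
conformality_index <- function(dose, target, ref_dose_gy, body = NULL) {
  if (!any(target$mask)) arc_input_error("conformality_index: target is empty")
  dd <- align_dose(dose, target)
  hot <- dd >= ref_dose_gy
  if (!is.null(body)) hot <- hot & body$mask
  sum(hot) / sum(target$mask)
}

#' Homogeneity index, raw and IDL-normalized
#'
#' `HI = Dmax / Rx`. When prescribing to an isodose line below 100 percent
#' the maximum is hot by construction, so the normalized variant
#' `HI * idl / 100` equals 1 exactly when the maximum dose matches the value
#' the IDL prescription implies.
#'
#' @param dose_max_gy maximum dose in Gy.
#' @param prescription_gy prescription dose in Gy, > 0.
#' @param idl_percent prescription isodose line in percent, `(0, 100]`.
#' @return List with `hi` and `hi_normalized`.
#' @examples
#' homogeneity_index(90, 45, 50)  # hi = 2, hi_normalized = 1
#' @export
homogeneity_index <- function(dose_max_gy, prescription_gy, idl_percent = 100) {
  if (prescription_gy <= 0) arc_input_error("homogeneity_index: prescription_gy must be > 0")
  if (idl_percent <= 0 || idl_percent > 100) {
    arc_input_error("homogeneity_index: idl_percent must be in (0, 100]")
  }
  hi <- dose_max_gy / prescription_gy
  list(hi = hi, hi_normalized = hi * idl_percent / 100)
}

#' Maximum-dose percentage implied by an isodose-line prescription
#'
#' Prescribing so that the `idl` percent isodose surface carries the
#' prescription dose implies a maximum of `100 / (idl/100)` percent of the
#' prescription, rounded to the nearest integer percent: 50 -> 200,
#' 60 -> 167, 70 -> 143, 80 -> 125, 90 -> 111.
#'
#' @param idl_percent isodose line in percent, `(0, 100]`.
#' @return Integer percent of the prescription dose.
#' @export
idl_to_max_percent <- function(idl_percent) {
  if (any(idl_percent <= 0) || any(idl_percent > 100)) {
    arc_input_error("idl_to_max_percent: idl_percent must be in (0, 100]")
  }
  as.integer(round(100^2 / idl_percent))
}

#' R50% gradient metric
#'
#' Ratio of the volume receiving at least half the prescription dose to the
#' PTV volume (closed threshold). Values near 1 indicate a steep dose
#' fall-off; SBRT protocols flag large values as deviations.
#'
#' @param dose a [dose_grid()].
#' @param ptv a non-empty [structure_volume()].
#' @param prescription_gy prescription dose in Gy.
#' @return The volume ratio.
#' @export
r50 <- function(dose, ptv, prescription_gy) {
  if (!any(ptv$mask)) arc_input_error("r50: PTV is empty")
  dd <- align_dose(dose, ptv)
  sum(dd >= 0.5 * prescription_gy) / sum(ptv$mask)
}

#' Squared / plain Euclidean distance to a structure
#'
#' Distance from every voxel centre to the nearest voxel centre of the
#' structure (0 inside it), computed with a separable exact distance
#' transform honouring anisotropic spacing.
#'
#' @param s a non-empty [structure_volume()].
#' @return Numeric array of distances in mm on the structure's grid.
#' @export
distance_to_structure <- function(s) {
  if (!any(s$mask)) arc_input_error("distance_to_structure: structure is empty")
  d2 <- edt_sq_cpp(as.vector(s$mask), as.integer(s$grid$shape), s$grid$spacing)
  array(sqrt(d2), s$grid$shape)
}

#' D2cm gradient metric
#'
#' Maximum dose at 2 cm or more from the PTV in any direction, as a
#' percentage of the prescription dose. The distance is the Euclidean
#' distance transform from the PTV; the threshold is closed (voxels at
#' exactly 20 mm count). The grid must extend at least 2 cm beyond the PTV's
#' bounding box on every side, otherwise an explicit error is raised rather
#' than reporting a clipped maximum.
#'
#' @inheritParams r50
#' @return Percent of the prescription dose.
#' @export
d2cm <- function(dose, ptv, prescription_gy) {
  if (!any(ptv$mask)) arc_input_error("d2cm: PTV is empty")
  idx <- which(ptv$mask, arr.ind = TRUE)
  ext <- grid_extent(ptv$grid)
  ax_names <- c("x", "y", "z")
  for (a in 1:3) {
    lo <- ptv$grid$origin[a] + (min(idx[, a]) - 1) * ptv$grid$spacing[a]
    hi <- ptv$grid$origin[a] + (max(idx[, a]) - 1) * ptv$grid$spacing[a]
    if (lo - ext["min", a] < 20 - 1e-9 || ext["max", a] - hi < 20 - 1e-9) {
      arc_input_error(sprintf(
        "d2cm: grid does not extend 2 cm beyond the PTV along axis %s; evaluate on a larger grid",
        ax_names[a]))
    }
  }
  dd <- align_dose(dose, ptv)
  dist <- distance_to_structure(ptv)
  sel <- dist >= 20 - 1e-9
  100 * max(dd[sel]) / prescription_gy
}

#' Dose-volume-histogram metrics
#'
#' `D_xcc` is the largest dose d such that at least x cc of the structure
#' receives at least d, computed by sorting the structure's voxel doses in
#' descending order and linearly interpolating the cumulative volume at the
#' x-cc cut (partial-volume interpolation, so sub-voxel volumes like 0.03 cc
#' are meaningful). `V_d` is the percentage of the structure volume receiving
#' at least d Gy (closed threshold).
#'
#' @param dose a [dose_grid()].
#' @param structure a non-empty [structure_volume()].
#' @param d_cc numeric vector of volumes x (cc) for `D_xcc` queries; each
#'   must not exceed the structure volume (error otherwise).
#' @param v_gy numeric vector of dose levels d (Gy) for `V_d` queries.
#' @return Data frame with columns `metric` (e.g. `"D10cc"`, `"V11.4"`),
#'   `value` and `unit`.
#' @export
dvh_metrics <- function(dose, structure, d_cc = numeric(), v_gy = numeric()) {
  if (!any(structure$mask)) arc_input_error("dvh_metrics: structure is empty")
  dd <- align_dose(dose, structure)
  doses <- dd[structure$mask]
  vv <- grid_voxel_cc(structure$grid)
  total <- length(doses) * vv
  out <- data.frame(metric = character(), value = numeric(), unit = character())
  if (length(d_cc) > 0) {
    bad <- d_cc > total + 1e-12
    if (any(bad)) {
      arc_domain_error(sprintf(
        "dvh_metrics: D_xcc query x = %g cc exceeds the structure volume (%.4g cc)",
        d_cc[which(bad)[1]], total))
    }
    ds <- sort(doses, decreasing = TRUE)
    cum <- seq_along(ds) * vv
    vals <- vapply(d_cc, function(x) {
      if (x <= cum[1]) ds[1] else approx(cum, ds, xout = x, ties = "ordered")$y
    }, numeric(1))
    out <- rbind(out, data.frame(metric = sprintf("D%gcc", d_cc),
                                 value = vals, unit = "Gy"))
  }
  if (length(v_gy) > 0) {
    vals <- vapply(v_gy, function(d) 100 * mean(doses >= d), numeric(1))
    out <- rbind(out, data.frame(metric = sprintf("V%g", v_gy),
                                 value = vals, unit = "%"))
  }
  out
}

#' Cumulative DVH curve
#'
#' @inheritParams dvh_metrics
#' @param n_bins number of dose bins between 0 and the structure maximum.
#' @return Data frame with `dose_gy` and `volume_percent` (volume receiving
#'   at least that dose).
#' @export
dvh_curve <- function(dose, structure, n_bins = 200) {
  if (!any(structure$mask)) arc_input_error("dvh_curve: structure is empty")
  dd <- align_dose(dose, structure)
  doses <- dd[structure$mask]
  levels <- seq(0, max(doses), length.out = n_bins + 1)
  data.frame(dose_gy = levels,
             volume_percent = vapply(levels, function(d) 100 * mean(doses >= d),
                                     numeric(1)))
}

#' Gradient-metric protocol flags
#'
#' Compares R50% and D2cm against configurable minor-deviation thresholds
#' (defaults match an interpolated lung-SBRT protocol table for an ~12 cc
#' PTV: 5.8 and 58.0). The thresholds are configuration constants; the
#' protocol interpolation itself is out of scope.
#'
#' @param r50_value,d2cm_value computed metric values.
#' @param r50_threshold,d2cm_threshold minor-deviation thresholds.
#' @return List with per-metric `"pass"` / `"minor-deviation"` flags.
#' @export
gradient_flags <- function(r50_value, d2cm_value,
                           r50_threshold = 5.8, d2cm_threshold = 58.0) {
  list(r50 = if (r50_value <= r50_threshold) "pass" else "minor-deviation",
       d2cm = if (d2cm_value <= d2cm_threshold) "pass" else "minor-deviation",
       r50_threshold = r50_threshold, d2cm_threshold = d2cm_threshold)
}

#' Full dosimetric index panel
#'
#' Computes the conformation number, conformality index, homogeneity index
#' (raw and IDL-normalized), R50%, D2cm, protocol flags and optional per-OAR
#' DVH queries on one dose grid.
#'
#' @param dose a [dose_grid()].
#' @param target the PTV as a [structure_volume()].
#' @param prescription a [prescription_spec()].
#' @param body optional body mask restricting `Vref`.
#' @param oars named list of [structure_volume()] organs at risk.
#' @param oar_queries named list: for each OAR name, a list with `d_cc`
#'   and/or `v_gy` vectors; defaults to `D10cc`/`D0.03cc` style queries only
#'   if provided. Per-query failures (e.g. x exceeding the OAR volume) are
#'   recorded as error entries rather than aborting the panel.
#' @param r50_threshold,d2cm_threshold see [gradient_flags()].
#' @return An `index_report` list.
#' @export
plan_indices <- function(dose, target, prescription, body = NULL,
                         oars = list(), oar_queries = list(),
                         r50_threshold = 5.8, d2cm_threshold = 58.0) {
  rx <- rx_total_gy(prescription)
  cn <- conformation_number(dose, target, rx, body)
  ci <- conformality_index(dose, target, rx, body)
  dmax <- max(dose$dose)
  hi <- homogeneity_index(dmax, rx, prescription$idl_percent)
  r50_v <- r50(dose, target, rx)
  d2_v <- tryCatch(d2cm(dose, target, rx), arcmetrics_input_error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NA_real_
  })
  flags <- if (is.na(d2_v)) NULL else gradient_flags(r50_v, d2_v, r50_threshold, d2cm_threshold)
  oar_results <- list()
  for (nm in names(oars)) {
    q <- oar_queries[[nm]] %||% list()
    # one row per query; a failing query (e.g. D_xcc beyond the OAR volume)
    # becomes an error entry instead of aborting the whole panel
    rows <- list()
    one <- function(d_cc = numeric(), v_gy = numeric()) {
      tryCatch(cbind(dvh_metrics(dose, oars[[nm]], d_cc = d_cc, v_gy = v_gy),
                     error = NA_character_),
               arcmetrics_error = function(e) {
                 data.frame(metric = if (length(d_cc)) sprintf("D%gcc", d_cc)
                            else sprintf("V%g", v_gy),
                            value = NA_real_, unit = if (length(d_cc)) "Gy" else "%",
                            error = conditionMessage(e))
               })
    }
    for (x in q$d_cc %||% numeric()) rows[[length(rows) + 1L]] <- one(d_cc = x)
    for (v in q$v_gy %||% numeric()) rows[[length(rows) + 1L]] <- one(v_gy = v)
    oar_results[[nm]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(metric = character(), value = numeric(), unit = character(),
                 error = character())
  }
  structure(list(
    cn = cn$cn, cn_components = cn[c("v_t", "v_ref", "v_t_ref")],
    ci = ci,
    hi = hi$hi, hi_normalized = hi$hi_normalized,
    dose_max_gy = dmax,
    prescription_gy = rx,
    idl_percent = prescription$idl_percent,
    r50 = r50_v, d2cm_percent = d2_v,
    flags = flags,
    oars = oar_results
  ), class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat("<index_report>\n")
  cat(sprintf("  CN %.4f  (VT %.3f cc, Vref %.3f cc, VT,ref %.3f cc)\n",
              x$cn, x$cn_components$v_t, x$cn_components$v_ref, x$cn_components$v_t_ref))
  cat(sprintf("  CI %.4f   HI %.4f (normalized %.4f)\n", x$ci, x$hi, x$hi_normalized))
  cat(sprintf("  R50%% %.3f   D2cm %.2f%% of prescription\n", x$r50, x$d2cm_percent))
  if (!is.null(x$flags)) {
    cat(sprintf("  flags: R50%% %s (<= %.1f), D2cm %s (<= %.1f)\n",
                x$flags$r50, x$flags$r50_threshold, x$flags$d2cm, x$flags$d2cm_threshold))
  }
  for (nm in names(x$oars)) {
    o <- x$oars[[nm]]
    txt <- ifelse(is.na(o$error),
                  sprintf("%s = %.3f %s", o$metric, o$value, o$unit),
                  sprintf("%s = <%s>", o$metric, o$error))
    cat(sprintf("  %s: %s\n", nm, paste(txt, collapse = ", ")))
  }
  invisible(x)
}
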