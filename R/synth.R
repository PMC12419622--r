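#' Synthetic phantom specification and construction
#'
#' Builds the stated target geometry of the evaluation phantom: a small
#' spherical GTV (default 0.51 cc), an ITV by anisotropic margin expansion
#' (default 1 cm superior, 0.3 cm elsewhere, emulating breathing motion
#' predominantly along the cranio-caudal axis) and a PTV by a 0.5 cm
#' isotropic setup margin. The default grid is 1 mm isotropic — finer than a
#' typical 2 mm planning CT — to stabilize metrics on sub-cc volumes, and
#' extends more than 2 cm beyond the PTV so gradient metrics are computable.
#'
#' @param gtv_volume_cc GTV volume in cc.
#' @param gtv_center GTV centre (isocenter frame), mm.
#' @param itv_margin [margin_spec()] for GTV -> ITV.
#' @param ptv_margin [margin_spec()] for ITV -> PTV.
#' @param grid a [grid_spec()]; see [default_phantom_grid()].
#' @return `phantom_spec()` returns the specification; `generate_phantom()`
#'   returns a list with `GTV`, `ITV`, `PTV` [structure_volume()]s on one
#'   grid.
#' @export
phantom_spec <- function(gtv_volume_cc = 0.51,
                         gtv_center = c(0, 0, 0),
                         itv_margin = margin_spec(sup = 10, inf = 3, left = 3,
                                                  right = 3, ant = 3, post = 3),
                         ptv_margin = margin_spec_iso(5),
                         grid = default_phantom_grid()) {
  structure(list(gtv_volume_cc = gtv_volume_cc, gtv_center = gtv_center,
                 itv_margin = itv_margin, ptv_margin = ptv_margin, grid = grid),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param spacing_mm isotropic voxel spacing of the default phantom grid.
#' @export
default_phantom_grid <- function(spacing_mm = 1) {
  # x, y span ~[-40, 40]; z ~[-40, 60] (extra superior room for the ITV
  # margin). The grid is offset a quarter millimetre from the isocenter so
  # the GTV sphere is not lattice-aligned: a sphere whose surface passes
  # through voxel centres is a degenerate case for voxel-centre membership
  # (volume errors of ~5%), and real anatomy never aligns with the grid.
  shape <- c(round(80 / spacing_mm), round(80 / spacing_mm), round(100 / spacing_mm)) + 1L
  grid_spec(origin = c(-39.75, -39.75, -39.75), spacing = rep(spacing_mm, 3),
            shape = shape)
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  gtv <- make_sphere_structure(spec$gtv_center, spec$gtv_volume_cc, spec$grid, "GTV")
  itv <- expand_margin(gtv, spec$itv_margin, "ITV")
  ptv <- expand_margin(itv, spec$ptv_margin, "PTV")
  list(GTV = gtv, ITV = itv, PTV = ptv)
}

# ---- synthetic arc plans ---------------------------------------------------

#' Intrusion models for synthetic plans
#'
#' Controlled departures of the synthetic plan's leaves from its conformal
#' aperture, so the area-difference metric has known answers:
#' `intrusion_none()` leaves the conformal aperture untouched;
#' `intrusion_fixed()` pushes leaf tips inward by a constant depth;
#' `intrusion_sinusoidal()` modulates the depth along the arc,
#' `depth_i = amplitude * (1 + sin(2 pi (i - 1) / period)) / 2`, emulating
#' the periodic in-and-out leaf travel of a modulated arc;
#' `intrusion_speed_limited()` caps leaf travel per degree of gantry
#' rotation, emulating a leaf-speed-limited delivery (a planning-system
#' minimum of 0.01 cm/degree corresponds to `max_travel_mm_per_deg = 0.1`).
#'
#' @param depth_mm,amplitude_mm intrusion depth / peak depth, mm, >= 0.
#' @param banks which bank(s) intrude: `"both"`, `"a"` or `"b"`.
#' @param period_cp sinusoid period in control points.
#' @param max_travel_mm_per_deg leaf travel limit, mm per degree.
#' @return An `intrusion_model` list.
#' @export
intrusion_none <- function() {
  structure(list(model = "none"), class = "intrusion_model")
}

#' @rdname intrusion_none
#' @export
intrusion_fixed <- function(depth_mm, banks = c("both", "a", "b")) {
  if (depth_mm < 0) arc_input_error("intrusion_fixed: depth_mm must be >= 0")
  structure(list(model = "fixed_depth", depth_mm = depth_mm,
                 banks = match.arg(banks)),
            class = "intrusion_model")
}

#' @rdname intrusion_none
#' @export
intrusion_sinusoidal <- function(amplitude_mm, period_cp = 20,
                                 banks = c("both", "a", "b")) {
  if (amplitude_mm < 0) arc_input_error("intrusion_sinusoidal: amplitude_mm must be >= 0")
  if (period_cp <= 0) arc_input_error("intrusion_sinusoidal: period_cp must be > 0")
  structure(list(model = "sinusoidal", amplitude_mm = amplitude_mm,
                 period_cp = period_cp, banks = match.arg(banks)),
            class = "intrusion_model")
}

#' @rdname intrusion_none
#' @export
intrusion_speed_limited <- function(max_travel_mm_per_deg) {
  if (max_travel_mm_per_deg <= 0) {
    arc_input_error("intrusion_speed_limited: max_travel_mm_per_deg must be > 0")
  }
  structure(list(model = "speed_limited",
                 max_travel_mm_per_deg = max_travel_mm_per_deg),
            class = "intrusion_model")
}

#' Synthetic arc plan specification
#'
#' @param n_control_points number of control points (default 121, a full arc
#'   at 3-degree spacing).
#' @param arc_span_deg arc span in degrees.
#' @param arc_start_deg gantry angle of the first control point.
#' @param margin_mm conformal aperture margin of the base plan, mm.
#' @param intrusion an intrusion model, see [intrusion_none()].
#' @param mu_profile `"constant"` for uniform per-segment meterset, or a
#'   numeric vector of relative per-segment weights
#'   (length `n_control_points - 1`).
#' @param total_mu total monitor units.
#' @param prescription a [prescription_spec()].
#' @param seed integer seed for any stochastic component (kept explicit so
#'   generation never touches global RNG state).
#' @return A `synth_plan_spec` object.
#' @export
synth_plan_spec <- function(n_control_points = 121L, arc_span_deg = 360,
                            arc_start_deg = 0, margin_mm = 0,
                            intrusion = intrusion_none(),
                            mu_profile = "constant", total_mu = 3000,
                            prescription = prescription_spec(15, 3, 80),
                            seed = 1L) {
  if (n_control_points < 2L) arc_input_error("synth_plan_spec: need >= 2 control points")
  if (margin_mm < 0) arc_input_error("synth_plan_spec: margin_mm must be >= 0")
  if (!inherits(intrusion, "intrusion_model")) {
    arc_input_error("synth_plan_spec: intrusion must be an intrusion_model")
  }
  if (is.numeric(mu_profile) && length(mu_profile) != n_control_points - 1L) {
    arc_input_error("synth_plan_spec: numeric mu_profile must have n_control_points - 1 entries")
  }
  structure(list(n_control_points = as.integer(n_control_points),
                 arc_span_deg = arc_span_deg, arc_start_deg = arc_start_deg,
                 margin_mm = margin_mm, intrusion = intrusion,
                 mu_profile = mu_profile, total_mu = total_mu,
                 prescription = prescription, seed = as.integer(seed)),
            class = "synth_plan_spec")
}

# clamp intrusion so banks never cross; crossing pairs meet at the midpoint
apply_depths <- function(left, right, open, depth_a, depth_b) {
  l <- left; r <- right
  l[open] <- left[open] + depth_a[open]
  r[open] <- right[open] - depth_b[open]
  cross <- open & (l > r)
  mid <- (l + r) / 2
  l[cross] <- mid[cross]
  r[cross] <- mid[cross]
  list(left = l, right = r)
}

#' Generate a synthetic conformal arc plan
#'
#' Fits the conformal aperture (at `spec$margin_mm`) to the target at every
#' control-point gantry angle, then perturbs it with the spec's intrusion
#' model. The result is a fully valid [arc_plan()] whose deviation from the
#' zero-margin reference is known by construction, which is what makes the
#' area-difference metric testable against closed forms.
#'
#' @param target a non-empty [structure_volume()].
#' @param machine a [machine_model()].
#' @param spec a [synth_plan_spec()].
#' @param projection projection mode for the aperture fit.
#' @return An [arc_plan()]. If the intrusion closes every pair at some
#'   control point a warning (not an error) is emitted.
#' @export
generate_conformal_plan <- function(target, machine, spec = synth_plan_spec(),
                                    projection = c("divergent", "parallel")) {
  projection <- match.arg(projection)
  if (!any(target$mask)) arc_input_error("generate_conformal_plan: target is empty")
  n <- spec$n_control_points
  np <- machine$n_pairs
  angles <- spec$arc_start_deg + spec$arc_span_deg * (seq_len(n) - 1) / (n - 1)
  surf <- mask_coords(surface_mask(target$mask), target$grid)
  bank_a <- matrix(0, n, np); bank_b <- matrix(0, n, np)
  imod <- spec$intrusion
  prev_a <- NULL; prev_b <- NULL; prev_ang <- NULL
  for (i in seq_len(n)) {
    sil <- project_points_bev(surf, angles[i], machine, projection)
    ap <- fit_conformal_aperture(sil, machine, spec$margin_mm)
    if (imod$model %in% c("fixed_depth", "sinusoidal")) {
      depth <- if (imod$model == "fixed_depth") imod$depth_mm else {
        imod$amplitude_mm * (1 + sin(2 * pi * (i - 1) / imod$period_cp)) / 2
      }
      da <- rep(if (imod$banks %in% c("both", "a")) depth else 0, np)
      db <- rep(if (imod$banks %in% c("both", "b")) depth else 0, np)
      adj <- apply_depths(ap$left, ap$right, ap$open, da, db)
      ap$left <- adj$left; ap$right <- adj$right
      if (any(ap$open) && all(adj$left[ap$open] >= adj$right[ap$open] - 1e-12)) {
        warning(sprintf("intrusion closed all open leaf pairs at control point %d", i),
                call. = FALSE)
      }
    } else if (imod$model == "speed_limited" && i > 1L) {
      dstep <- abs(angles[i] - angles[i - 1])
      dstep <- min(dstep, 360 - dstep %% 360)
      lim <- imod$max_travel_mm_per_deg * dstep
      ap$left <- prev_a + pmin(pmax(ap$left - prev_a, -lim), lim)
      ap$right <- prev_b + pmin(pmax(ap$right - prev_b, -lim), lim)
      cross <- ap$left > ap$right
      mid <- (ap$left + ap$right) / 2
      ap$left[cross] <- mid[cross]; ap$right[cross] <- mid[cross]
    }
    prev_a <- ap$left; prev_b <- ap$right
    bank_a[i, ] <- ap$left
    bank_b[i, ] <- ap$right
  }
  w <- if (identical(spec$mu_profile, "constant")) {
    (seq_len(n) - 1) / (n - 1)
  } else {
    seg <- as.numeric(spec$mu_profile)
    if (any(seg < 0) || sum(seg) <= 0) {
      arc_input_error("generate_conformal_plan: mu_profile weights must be non-negative with positive sum")
    }
    cumsum(c(0, seg)) / sum(seg)
  }
  arc_plan(machine, angles, bank_a, bank_b, w, spec$total_mu, spec$prescription)
}

#' Delivery-style presets for synthetic plans
#'
#' Maps the five arc delivery styles compared in the evaluation workflow onto
#' synthetic plan specifications: `"vmat"` = heavily modulated leaves
#' (sinusoidal intrusion, 3 mm amplitude over a 20-control-point period);
#' `"limu"` = MU-limited VMAT that hugs the target (1 mm margin, no
#' intrusion); `"lsl"` = leaf-speed-limited VMAT (0.1 mm/degree cap, the
#' planning-system minimum of 0.01 cm/degree); `"dcat"` = dynamic conformal
#' arc with a 3 mm dosimetric margin and a varying dose rate; `"cdcat"` =
#' the same aperture with a constant dose rate.
#'
#' @param style one of `"vmat"`, `"limu"`, `"lsl"`, `"dcat"`, `"cdcat"`.
#' @param n_control_points,total_mu,prescription,seed forwarded to
#'   [synth_plan_spec()].
#' @return A [synth_plan_spec()].
#' @export
synth_plan_preset <- function(style = c("vmat", "limu", "lsl", "dcat", "cdcat"),
                              n_control_points = 121L, total_mu = 3000,
                              prescription = prescription_spec(15, 3, 80),
                              seed = 1L) {
  style <- match.arg(style)
  n <- as.integer(n_control_points)
  base <- function(...) synth_plan_spec(n_control_points = n, total_mu = total_mu,
                                        prescription = prescription, seed = seed, ...)
  switch(style,
    vmat = base(margin_mm = 0, intrusion = intrusion_sinusoidal(3, 20)),
    limu = base(margin_mm = 1, intrusion = intrusion_none()),
    lsl = base(margin_mm = 0, intrusion = intrusion_speed_limited(0.1)),
    dcat = base(margin_mm = 3, intrusion = intrusion_none(),
                mu_profile = 1 + 0.5 * sin(2 * pi * seq_len(n - 1L) / (n - 1L))),
    cdcat = base(margin_mm = 3, intrusion = intrusion_none())
  )
}

# ---- synthetic dose --------------------------------------------------------

#' Synthetic dose model specification
#'
#' An analytically tractable stand-in for a dose engine: a uniform plateau
#' inside the PTV and a monotone radial fall-off outside,
#' `dose(d) = plateau * exp(-log(2) * (d / scale)^exponent)` where `d` is the
#' Euclidean distance to the PTV surface — so the dose halves every `scale`
#' mm at `exponent = 1`, and every isodose surface is a known distance shell
#' around the PTV. This is deliberately not a transport calculation; its only
#' contract is closed-form testability of the dose metrics.
#'
#' @param plateau_gy plateau dose in Gy; defaults to the IDL-implied maximum
#'   `rx_total * 100 / idl`.
#' @param falloff_scale_mm distance halving scale, mm, > 0.
#' @param falloff_exponent fall-off shape exponent, > 0.
#' @param prescription a [prescription_spec()].
#' @param noise_sd relative Gaussian noise (0 disables).
#' @param seed seed for the noise.
#' @return A `synth_dose_spec` object.
#' @export
synth_dose_spec <- function(plateau_gy = NULL, falloff_scale_mm = 8,
                            falloff_exponent = 1,
                            prescription = prescription_spec(15, 3, 80),
                            noise_sd = 0, seed = 1L) {
  if (falloff_scale_mm < 0 || falloff_exponent <= 0) {
    arc_input_error("synth_dose_spec: fall-off must be strictly decreasing (scale >= 0, exponent > 0)")
  }
  if (is.null(plateau_gy)) {
    plateau_gy <- rx_total_gy(prescription) * 100 / prescription$idl_percent
  }
  if (plateau_gy <= 0) arc_input_error("synth_dose_spec: plateau must be positive")
  structure(list(plateau_gy = plateau_gy, falloff_scale_mm = falloff_scale_mm,
                 falloff_exponent = falloff_exponent, prescription = prescription,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_dose_spec")
}

#' Generate a synthetic dose grid around a PTV
#'
#' Evaluates the [synth_dose_spec()] model on the PTV's grid and, if needed,
#' rescales the whole distribution so that at least 95 percent of the PTV
#' receives the prescription dose (the planning coverage rule). Deterministic
#' for a fixed spec and seed.
#'
#' @param ptv a non-empty [structure_volume()].
#' @param spec a [synth_dose_spec()].
#' @return A [dose_grid()] on the PTV's grid.
#' @export
generate_synthetic_dose <- function(ptv, spec = synth_dose_spec()) {
  if (!any(ptv$mask)) arc_input_error("generate_synthetic_dose: PTV is empty")
  dist <- distance_to_structure(ptv)
  dose <- if (spec$falloff_scale_mm == 0) {
    # limit case: dose confined to the PTV
    spec$plateau_gy * (dist == 0)
  } else {
    spec$plateau_gy *
      exp(-log(2) * (dist / spec$falloff_scale_mm)^spec$falloff_exponent)
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, rnorm(length(dose), 0, spec$noise_sd))
    dose <- pmax(dose * (1 + array(noise, dim(dose))), 0)
  }
  rx <- rx_total_gy(spec$prescription)
  q05 <- quantile(dose[ptv$mask], probs = 0.05, type = 1, names = FALSE)
  if (q05 < rx) {
    dose <- dose * rx / q05
  }
  dose_grid(ptv$grid, dose)
}
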