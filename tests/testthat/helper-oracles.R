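# Shared fixtures and independent oracles. Oracles deliberately use a
# different computation path (pixel counting, explicit loops) than the
# implementation they check.

# memoised expensive fixtures -------------------------------------------------
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

default_phantom <- function() cached("phantom", generate_phantom())

# small sphere target on its own grid, for cheap plan tests
small_target <- function(r_mm = 8, center = c(0, 0, 0), spacing = 1, pad_mm = 6) {
  cached(sprintf("target_%g_%g_%g_%g", r_mm, center[3], spacing, pad_mm), {
    n <- as.integer(round(2 * (r_mm + pad_mm) / spacing)) + 1L
    half <- (n - 1) / 2 * spacing
    g <- grid_spec(origin = center - half + 0.13, spacing = rep(spacing, 3),
                   shape = rep(n, 3L))
    make_sphere_structure(center, 4 / 3 * pi * r_mm^3 / 1000, g, "target")
  })
}

small_machine <- function() machine_model(leaf_pair_boundaries = seq(-30, 30, by = 5))

# pixel-rasterization oracle for aperture areas -------------------------------
# Counts 0.1 mm pixels inside the reference opening (and, for intrusion, not
# inside the actual opening). Pixel centre membership, closed on the left.
raster_pair_area <- function(ref_l, ref_r, act_l = NULL, act_r = NULL,
                             band_h, res = 0.1) {
  if (ref_r <= ref_l) return(0)
  xs <- seq(ref_l - 1, ref_r + 1, by = res) + res / 2
  inside_ref <- xs >= ref_l & xs <= ref_r
  blocked <- if (is.null(act_l)) inside_ref else inside_ref & !(xs >= act_l & xs <= act_r)
  sum(blocked) * res * band_h
}

raster_ratio_oracle <- function(plan, target, res = 0.1,
                                projection = "divergent") {
  m <- plan$machine
  b <- m$leaf_pair_boundaries
  h <- diff(b)
  tot_int <- 0; tot_ref <- 0
  for (i in seq_len(length(plan$gantry_angle))) {
    sil <- project_to_bev(target, plan$gantry_angle[i], m, projection)
    ref <- fit_conformal_aperture(sil, m, 0)
    for (p in which(ref$open)) {
      tot_ref <- tot_ref + raster_pair_area(ref$left[p], ref$right[p],
                                            band_h = h[p], res = res)
      tot_int <- tot_int + raster_pair_area(ref$left[p], ref$right[p],
                                            plan$bank_a[i, p], plan$bank_b[i, p],
                                            band_h = h[p], res = res)
    }
  }
  100 * tot_int / tot_ref
}

# brute-force DVH oracle -------------------------------------------------------
# Largest dose d with >= x cc at >= d, by explicit scan over the sorted
# cumulative curve (no approx()).
oracle_dxcc <- function(doses, voxel_cc, x) {
  ds <- sort(doses, decreasing = TRUE)
  cum <- seq_along(ds) * voxel_cc
  if (x <= cum[1]) return(ds[1])
  i <- max(which(cum < x))
  ds[i] + (ds[i + 1] - ds[i]) * (x - cum[i]) / (cum[i + 1] - cum[i])
}

oracle_vd <- function(doses, d) 100 * sum(doses >= d) / length(doses)

# brute-force distance oracle --------------------------------------------------
# min distance from every voxel centre to the structure's voxel centres,
# accumulated with pmin over structure voxels (no distance transform).
oracle_distance <- function(s) {
  ax <- arcmetrics:::grid_axes(s$grid)
  shp <- s$grid$shape
  X <- rep(ax$x, times = shp[2] * shp[3])
  Y <- rep(rep(ax$y, each = shp[1]), times = shp[3])
  Z <- rep(ax$z, each = shp[1] * shp[2])
  src <- arcmetrics:::mask_coords(s$mask, s$grid)
  best <- rep(Inf, length(X))
  for (k in seq_len(nrow(src))) {
    best <- pmin(best, (X - src[k, 1])^2 + (Y - src[k, 2])^2 + (Z - src[k, 3])^2)
  }
  array(sqrt(best), shp)
}

# random plans -----------------------------------------------------------------
# Perturbs the conformal plan of `target` with random per-pair, per-control
# point shifts (both intruding and retracting) and occasional closed pairs.
random_perturbed_plan <- function(target, machine, n_cp = 6, seed = 1) {
  base <- generate_conformal_plan(target, machine,
                                  synth_plan_spec(n_control_points = n_cp,
                                                  total_mu = 1000))
  set.seed(seed)
  n <- length(base$gantry_angle)
  np <- machine$n_pairs
  a <- base$bank_a + matrix(runif(n * np, -4, 4), n, np)
  b <- base$bank_b + matrix(runif(n * np, -4, 4), n, np)
  lo <- pmin(a, b); hi <- pmax(a, b)
  closed <- matrix(runif(n * np) < 0.1, n, np)
  mid <- (lo + hi) / 2
  lo[closed] <- mid[closed]; hi[closed] <- mid[closed]
  arc_plan(machine, base$gantry_angle, lo, hi, base$cum_weight, base$total_mu)
}

random_small_plan <- function(seed, n_cp = 4, n_pairs = 6) {
  set.seed(seed)
  m <- machine_model(leaf_pair_boundaries = seq(0, 5 * n_pairs, by = 5))
  a <- matrix(runif(n_cp * n_pairs, -50, 0), n_cp, n_pairs)
  b <- a + matrix(runif(n_cp * n_pairs, 0, 60), n_cp, n_pairs)
  w <- sort(runif(n_cp)); w <- (w - w[1]) / (w[n_cp] - w[1])
  arc_plan(m, runif(n_cp, 0, 360), a, b, w, runif(1, 50, 5000),
           prescription_spec(15, 3, 80))
}
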