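block_structure <- function(nx = 20, extra = 0) {
  g <- grid_spec(origin = c(0, 0, 0), spacing = c(1, 1, 1), shape = c(nx, nx, nx))
  mask <- array(FALSE, c(nx, nx, nx))
  mask[6:15, 6:15, 6:15] <- TRUE  # 1000 voxels = 1 cc
  structure_volume("block", g, mask)
}

test_that("conformation number closed forms", {
  s <- block_structure()
  dose <- array(0, s$grid$shape)
  dose[s$mask] <- 10
  d <- dose_grid(s$grid, dose)
  r <- conformation_number(d, s, 10)
  expect_equal(r$cn, 1)
  expect_equal(r$v_t_ref, 1.0)
  # prescription volume exactly twice the target, full coverage -> CN 0.5
  dose2 <- dose
  dose2[1:20, 1:10, 16:20] <- 10  # disjoint extra 1000 voxels
  stopifnot(sum(dose2 >= 10) == 2000)
  r2 <- conformation_number(dose_grid(s$grid, dose2), s, 10)
  expect_equal(r2$cn, 0.5)
  expect_equal(conformality_index(dose_grid(s$grid, dose2), s, 10), 2.0)
  expect_equal(conformality_index(d, s, 10), 1.0)
  expect_error(conformation_number(dose_grid(s$grid, dose * 0), s, 10),
               class = "arcmetrics_undefined_metric")
})

test_that("CN and CI on a radial dose match brute-force voxel counting", {
  ph <- small_target(r_mm = 8)
  d <- generate_synthetic_dose(ph, synth_dose_spec(prescription = prescription_spec(15, 3, 80)))
  rx <- 45
  r <- conformation_number(d, ph, rx)
  # independent oracle: explicit logical sums on the arrays
  vv <- prod(ph$grid$spacing) / 1000
  expect_equal(r$v_ref, sum(d$dose >= rx) * vv)
  expect_equal(r$v_t_ref, sum(d$dose >= rx & ph$mask) * vv)
  expect_equal(r$cn, (r$v_t_ref / r$v_t) * (r$v_t_ref / r$v_ref))
  expect_equal(conformality_index(d, ph, rx), r$v_ref / r$v_t)
  expect_gte(r$cn, 0); expect_lte(r$cn, 1)
  # CN = coverage x selectivity exactly
  expect_equal(r$cn, (r$v_t_ref / r$v_t) * (r$v_t_ref / r$v_ref))
})

test_that("homogeneity index and IDL normalization", {
  expect_equal(homogeneity_index(90, 45, 50), list(hi = 2, hi_normalized = 1))
  expect_equal(homogeneity_index(45, 45, 100), list(hi = 1, hi_normalized = 1))
  h <- homogeneity_index(1.67 * 45, 45, 60)
  expect_equal(h$hi, 1.67)
  expect_equal(h$hi_normalized, 1.002)
})

test_that("IDL to maximum-dose conversion reproduces the printed series", {
  expect_identical(idl_to_max_percent(c(50, 60, 70, 80, 90)),
                   c(200L, 167L, 143L, 125L, 111L))
  expect_identical(idl_to_max_percent(100), 100L)
  expect_error(idl_to_max_percent(0), class = "arcmetrics_input_error")
  expect_error(idl_to_max_percent(101), class = "arcmetrics_input_error")
})

test_that("r50 uses a closed threshold and the PTV volume", {
  s <- block_structure()
  dose <- array(0, s$grid$shape)
  dose[s$mask] <- 22.5            # exactly half of 45: counts (>=)
  d <- dose_grid(s$grid, dose)
  expect_equal(r50(d, s, 45), 1.0)
  dose[s$mask] <- 22.499999
  expect_equal(r50(dose_grid(s$grid, dose), s, 45), 0)
})

test_that("r50 on the analytic dose model matches its closed form", {
  # the 50% shell sits ~10.6 mm outside the PTV, so the grid needs room for
  # it, and a half-millimetre grid keeps the voxel-centre distance bias small
  ph <- small_target(r_mm = 8, spacing = 0.5, pad_mm = 13)
  spec <- synth_dose_spec(prescription = prescription_spec(15, 3, 80))
  d <- generate_synthetic_dose(ph, spec)
  # dose(d) = plateau * exp(-ln2 d / s); the 50% isodose sits at distance
  # d50 = s * log2(plateau / (Rx/2)) from the (voxelized) PTV surface
  d50 <- spec$falloff_scale_mm * log2(spec$plateau_gy / 22.5)
  r_eq <- (3 * ph$volume_cc * 1000 / (4 * pi))^(1 / 3)  # equivalent sphere radius
  want <- ((r_eq + d50) / r_eq)^3
  expect_lt(abs(r50(d, ph, 45) - want) / want, 0.03)
})

test_that("distance transform equals the brute-force distance oracle", {
  set.seed(7)
  for (i in 1:3) {
    g <- grid_spec(origin = c(0, 0, 0), spacing = c(1, 1.5, 2), shape = c(12, 10, 9))
    mask <- array(runif(prod(g$shape)) < 0.05, g$shape)
    if (!any(mask)) mask[5, 5, 5] <- TRUE
    s <- structure_volume("rnd", g, mask)
    expect_equal(distance_to_structure(s), oracle_distance(s), tolerance = 1e-9)
  }
})

test_that("d2cm matches brute-force distances on a small grid", {
  # 40^3 voxels at 1.5 mm spacing so the tiny sphere keeps 2 cm of clearance
  g <- grid_spec(origin = c(-29.25, -29.25, -29.25), spacing = c(1.5, 1.5, 1.5),
                 shape = c(40, 40, 40))
  s <- make_sphere_structure(c(0.25, 0.25, 0.25), 0.05, g)  # r ~ 2.3 mm
  set.seed(11)
  dose <- array(runif(prod(g$shape), 0, 30), g$shape)
  d <- dose_grid(g, dose)
  dist <- oracle_distance(s)
  want <- 100 * max(dose[dist >= 20 - 1e-9]) / 45
  expect_equal(d2cm(d, s, 45), want, tolerance = 1e-12)
})

test_that("d2cm equals the model dose at 2 cm for a monotone radial falloff", {
  ph <- default_phantom()$PTV  # its grid has >= 2 cm of clearance on all sides
  spec <- synth_dose_spec(prescription = prescription_spec(15, 3, 80))
  d <- generate_synthetic_dose(ph, spec)
  want <- 100 * spec$plateau_gy * exp(-log(2) * 20 / spec$falloff_scale_mm) / 45
  expect_lt(abs(d2cm(d, ph, 45) - want) / want, 0.02)
  # zero dose outside the PTV -> 0%
  d0 <- generate_synthetic_dose(ph, synth_dose_spec(falloff_scale_mm = 0,
                                                    prescription = prescription_spec(15, 3, 80)))
  expect_equal(d2cm(d0, ph, 45), 0)
})

test_that("d2cm refuses grids without 2 cm of clearance", {
  s <- small_target(r_mm = 8)  # 6 mm of clearance only
  dose <- dose_grid(s$grid, array(1, s$grid$shape))
  expect_error(d2cm(dose, s, 45), "2 cm", class = "arcmetrics_input_error")
})

test_that("DVH metrics: uniform and two-level closed forms", {
  s <- block_structure()
  dose <- array(0, s$grid$shape)
  dose[s$mask] <- 10
  d <- dose_grid(s$grid, dose)
  out <- dvh_metrics(d, s, d_cc = c(0.03, 0.5, 1.0), v_gy = c(9.9, 10, 10.1))
  expect_equal(out$value[1:3], c(10, 10, 10))
  expect_equal(out$value[4:6], c(100, 100, 0))
  # two-level structure: 2 cc total, half at 20 Gy
  g <- s$grid
  mask <- array(FALSE, g$shape); mask[1:20, 1:10, 1:10] <- TRUE
  s2 <- structure_volume("two", g, mask)
  dose2 <- array(0, g$shape); dose2[1:10, 1:10, 1:10] <- 20
  d2 <- dose_grid(g, dose2)
  out2 <- dvh_metrics(d2, s2, d_cc = 1, v_gy = 11.4)
  expect_equal(out2$value, c(20, 50))
  expect_error(dvh_metrics(d2, s2, d_cc = 3), class = "arcmetrics_domain_error")
})

test_that("DVH metrics match the sort-based oracle on random fields", {
  set.seed(99)
  s <- block_structure()
  vv <- prod(s$grid$spacing) / 1000
  for (i in 1:5) {
    dose <- array(runif(prod(s$grid$shape), 0, 60), s$grid$shape)
    d <- dose_grid(s$grid, dose)
    doses <- dose[s$mask]
    xs <- c(0.03, 0.2, runif(3, 0.01, 0.99))
    vs <- c(11.4, runif(3, 0, 60))
    out <- dvh_metrics(d, s, d_cc = xs, v_gy = vs)
    for (j in seq_along(xs)) {
      expect_equal(out$value[j], oracle_dxcc(doses, vv, xs[j]), tolerance = 1e-9)
    }
    for (j in seq_along(vs)) {
      expect_equal(out$value[length(xs) + j], oracle_vd(doses, vs[j]), tolerance = 1e-9)
    }
    # monotonicity: D_xcc non-increasing in x, V_d non-increasing in d
    xs_s <- sort(xs); vs_s <- sort(vs)
    dx <- dvh_metrics(d, s, d_cc = xs_s)$value
    vd <- dvh_metrics(d, s, v_gy = vs_s)$value
    expect_true(all(diff(dx) <= 1e-12))
    expect_true(all(diff(vd) <= 1e-12))
  }
})

test_that("dose grids resample onto mask grids trilinearly", {
  # linear field is reproduced exactly by trilinear interpolation
  g1 <- grid_spec(origin = c(0, 0, 0), spacing = c(2, 2, 2), shape = c(11, 11, 11))
  ax <- arcmetrics:::grid_axes(g1)
  lin <- function(x, y, z) 0.1 * x + 0.2 * y + 0.05 * z
  dose1 <- outer(outer(0.1 * ax$x, 0.2 * ax$y, "+"), 0.05 * ax$z, "+")
  d1 <- dose_grid(g1, dose1)
  g2 <- grid_spec(origin = c(1, 1, 1), spacing = c(1, 1, 1), shape = c(17, 17, 17))
  d2 <- resample_dose(d1, g2)
  ax2 <- arcmetrics:::grid_axes(g2)
  want <- outer(outer(0.1 * ax2$x, 0.2 * ax2$y, "+"), 0.05 * ax2$z, "+")
  expect_equal(d2$dose, want, tolerance = 1e-12)
  # identity on the same grid
  expect_identical(resample_dose(d1, g1)$dose, dose1)
})

test_that("RT-DOSE round-trips through DICOM at scaling precision", {
  ph <- small_target(r_mm = 8)
  d <- generate_synthetic_dose(ph)
  path <- tempfile(fileext = ".dcm")
  write_rtdose(d, path)
  back <- read_rtdose(path)
  expect_equal(back$grid$origin, d$grid$origin)
  expect_equal(back$grid$spacing, d$grid$spacing)
  expect_equal(back$dose, d$dose, tolerance = 1e-8)
  unlink(path)
})

test_that("dose text format round-trips", {
  ph <- small_target(r_mm = 8)
  d <- generate_synthetic_dose(ph)
  path <- tempfile(fileext = ".dgrid")
  write_dose_text(d, path)
  back <- read_dose_text(path)
  expect_equal(back$dose, d$dose, tolerance = 1e-8)
  unlink(path)
})

test_that("gradient flags compare against protocol thresholds", {
  f <- gradient_flags(5.79, 58.0)
  expect_identical(f$r50, "pass")
  expect_identical(f$d2cm, "pass")
  f2 <- gradient_flags(5.81, 58.01)
  expect_identical(f2$r50, "minor-deviation")
  expect_identical(f2$d2cm, "minor-deviation")
})

test_that("plan_indices assembles the full panel with per-query OAR errors", {
  ph <- default_phantom()
  d <- generate_synthetic_dose(ph$PTV)
  rx <- prescription_spec(15, 3, 80)
  oar <- make_sphere_structure(c(0.25, 0.25, -25), 0.3, ph$PTV$grid, "tiny_oar")
  rpt <- plan_indices(d, ph$PTV, rx, oars = list(tiny = oar),
                      oar_queries = list(tiny = list(d_cc = c(10, 0.03), v_gy = 11.4)))
  for (f in c("cn", "ci", "hi", "hi_normalized", "r50", "d2cm_percent")) {
    expect_true(is.finite(rpt[[f]]))
  }
  expect_equal(rpt$hi_normalized, rpt$hi * 0.8)
  o <- rpt$oars$tiny
  expect_identical(o$metric, c("D10cc", "D0.03cc", "V11.4"))
  expect_false(is.na(o$error[1]))   # 10 cc exceeds a 0.3 cc structure
  expect_true(is.na(o$error[2]))
  expect_true(is.na(o$error[3]))
})
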