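test_that("sphere radius closed form matches independent arithmetic", {
  # independent oracle: direct arithmetic on V = (4/3) pi r^3
  expect_equal(sphere_radius_mm(0.51), (3 * 0.51 * 1000 / (4 * pi))^(1 / 3))
  expect_equal(round(sphere_radius_mm(0.51), 3), 4.957, tolerance = 1e-3)
  expect_equal(sphere_radius_mm(4 * pi / 3), 10)  # unit-sphere scaling
})

test_that("voxelized sphere volumes are within 2% of closed form at 1 mm", {
  g <- default_phantom_grid()
  for (v in c(0.51, 2, 4.19, 10)) {
    s <- make_sphere_structure(c(0, 0, 0), v, g)
    expect_lt(abs(s$volume_cc - v) / v, 0.02)
  }
  gtv <- make_sphere_structure(c(0, 0, 0), 0.51, g)
  expect_gte(gtv$volume_cc, 0.50)
  expect_lte(gtv$volume_cc, 0.52)
})

test_that("sphere outside the grid errors naming the violating axis", {
  g <- grid_spec(origin = c(-10, -10, -10), spacing = c(1, 1, 1), shape = c(21, 21, 21))
  expect_error(make_sphere_structure(c(0, 0, 8), 0.51, g), "axis z",
               class = "arcmetrics_geometry_error")
  expect_error(make_sphere_structure(c(-9, 0, 0), 0.51, g), "axis x",
               class = "arcmetrics_geometry_error")
  expect_silent(make_sphere_structure(c(0, 0, 0), 0.51, g))
})

test_that("zero-margin expansion is the identity", {
  s <- make_sphere_structure(c(0, 0, 0), 0.51, default_phantom_grid())
  e <- expand_margin(s, margin_spec())
  expect_identical(e$mask, s$mask)
})

test_that("isotropic expansion of a sphere brackets the closed-form volume", {
  # a binary mask pins the surface only to half a voxel, so centre-to-centre
  # dilation carries an O(h/2) radial bias; the rigorous check is the
  # half-voxel bracket around (4/3) pi (r + m)^3, tightening with refinement
  r_exp <- sphere_radius_mm(0.51) + 5   # 9.956 mm
  vol_cc <- function(radius) 4 / 3 * pi * radius^3 / 1000
  errs <- vapply(c(1, 0.5), function(h) {
    g <- default_phantom_grid(h)
    s <- make_sphere_structure(c(0, 0, 0), 0.51, g)
    e <- expand_margin(s, margin_spec_iso(5))
    expect_true(all(e$mask[s$mask]))                   # superset
    expect_gte(e$volume_cc, vol_cc(r_exp - h / 2) * 0.995)
    expect_lte(e$volume_cc, vol_cc(r_exp + h / 2) * 1.005)
    abs(e$volume_cc - vol_cc(r_exp))
  }, numeric(1))
  expect_lt(errs[2], errs[1])   # refinement shrinks the bias
})

test_that("anisotropic expansion only grows the stated directions", {
  g <- grid_spec(origin = c(-15.75, -15.75, -15.75), spacing = c(1, 1, 1),
                 shape = c(32, 32, 32))
  s <- make_sphere_structure(c(0, 0, 0), 0.51, g)
  e <- expand_margin(s, margin_spec(sup = 10))
  idx_s <- which(s$mask, arr.ind = TRUE)
  idx_e <- which(e$mask, arr.ind = TRUE)
  # x/y extents unchanged, inferior extent unchanged, superior extent +10 voxels
  expect_equal(range(idx_e[, 1]), range(idx_s[, 1]))
  expect_equal(range(idx_e[, 2]), range(idx_s[, 2]))
  expect_equal(min(idx_e[, 3]), min(idx_s[, 3]))
  expect_equal(max(idx_e[, 3]), max(idx_s[, 3]) + 10L)
})

test_that("expansion that would clip at the grid boundary errors", {
  g <- grid_spec(origin = c(-8, -8, -8), spacing = c(1, 1, 1), shape = c(17, 17, 17))
  s <- make_sphere_structure(c(0, 0, 0), 0.51, g)
  expect_error(expand_margin(s, margin_spec_iso(5)),
               class = "arcmetrics_geometry_error")
})

test_that("GTV, ITV and PTV are nested and near the reference volumes", {
  ph <- default_phantom()
  expect_true(all(ph$ITV$mask[ph$GTV$mask]))
  expect_true(all(ph$PTV$mask[ph$ITV$mask]))
  expect_gte(ph$GTV$volume_cc, 0.50)
  expect_lte(ph$GTV$volume_cc, 0.52)
  # informational comparison to the planning-system reference volumes; the
  # expansion kernel convention differs, so only a loose band is meaningful
  expect_lt(abs(ph$ITV$volume_cc - 3.14) / 3.14, 0.35)
  expect_lt(abs(ph$PTV$volume_cc - 11.91) / 11.91, 0.35)
})

test_that("grid refinement converges from the degenerate aligned start", {
  # sphere centre on a voxel centre: the worst case for centre-inside
  # membership; halving the spacing must reduce the volume error
  vol_err <- function(h) {
    n <- as.integer(round(16 / h)) + 1L
    g <- grid_spec(origin = rep(-8, 3), spacing = rep(h, 3), shape = rep(n, 3L))
    s <- make_sphere_structure(c(0, 0, 0), 0.51, g)
    abs(s$volume_cc - 0.51)
  }
  errs <- vapply(c(1, 0.5, 0.25), vol_err, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("structure_volume_cc counts voxels times voxel volume", {
  g <- grid_spec(origin = c(0, 0, 0), spacing = c(1, 1, 1), shape = c(10, 10, 10))
  empty <- structure_volume("empty", g, array(FALSE, c(10, 10, 10)))
  expect_equal(structure_volume_cc(empty), 0)
  full <- structure_volume("block", g, array(TRUE, c(10, 10, 10)))
  expect_equal(structure_volume_cc(full), 1.0)
  g2 <- grid_spec(origin = c(0, 0, 0), spacing = c(2, 2, 2), shape = c(5, 5, 5))
  expect_equal(structure_volume_cc(structure_volume("b", g2, array(TRUE, c(5, 5, 5)))),
               1.0)
})

test_that("margin and grid constructors validate their inputs", {
  expect_error(margin_spec(sup = -1), class = "arcmetrics_input_error")
  expect_error(grid_spec(spacing = c(1, 0, 1), shape = c(2, 2, 2)),
               class = "arcmetrics_input_error")
  expect_error(grid_spec(shape = c(2, -1, 2)), class = "arcmetrics_input_error")
})

test_that("structure masks round-trip through the text format", {
  ph <- default_phantom()
  for (ext in c(".svol", ".svol.gz")) {
    path <- tempfile(fileext = ext)
    write_structure_text(ph$ITV, path)
    back <- read_structure_text(path)
    expect_identical(back$mask, ph$ITV$mask)
    expect_equal(back$grid$origin, ph$ITV$grid$origin)
    expect_identical(back$name, "ITV")
    unlink(path)
  }
})

test_that("structure text reader rejects unknown versions", {
  path <- tempfile()
  writeLines(c("SVOL 99", "name x"), path)
  expect_error(read_structure_text(path), class = "arcmetrics_format_error")
  unlink(path)
})

test_that("contours_to_mask fills planar polygons with even-odd rule", {
  g <- grid_spec(origin = c(-10.5, -10.5, 0), spacing = c(1, 1, 2), shape = c(22, 22, 3))
  square <- function(half, z) {
    cbind(c(-half, half, half, -half), c(-half, -half, half, half), z)
  }
  s <- contours_to_mask(list(square(8, 2), square(8, 4)), g, "sq")
  # 16x16 mm square on two slices, 1 mm pixels, 2 mm slice thickness
  expect_equal(sum(s$mask), 2 * 16 * 16)
  # a nested square on the same slice toggles off (a hole)
  s2 <- contours_to_mask(list(square(8, 2), square(4, 2)), g, "ring")
  expect_equal(sum(s2$mask), 16 * 16 - 8 * 8)
})

test_that("RT-STRUCT contours round-trip and rasterize", {
  square <- cbind(c(-8, 8, 8, -8), c(-8, -8, 8, 8), 2)
  path <- tempfile(fileext = ".dcm")
  write_rtstruct(list(list(name = "cube", contours = list(square))), path)
  back <- read_rtstruct(path)
  expect_identical(back[[1]]$name, "cube")
  expect_equal(back[[1]]$contours[[1]], square, ignore_attr = TRUE)
  unlink(path)
})
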