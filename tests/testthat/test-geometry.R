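# Derived-structure recipes and geometric metrics against closed forms.

test_that("margin expansion matches the expanded-sphere closed form", {
  sph <- cs_sphere(radius = 20, slice_spacing = 2)
  ptv <- expand_margin(sph, margin_spec(7, 7, 7, 7, 7, 7))
  expect_equal(structure_volume(ptv), 4 / 3 * pi * 27^3 / 1000,
               tolerance = 0.02)
  # superset of the input up to raster tolerance
  expect_gt(structure_volume(ptv), structure_volume(sph))
  zr <- range(stack_z(ptv))
  expect_equal(zr, c(-24, 24))  # 7 mm superior/inferior in whole 2 mm slices
})

test_that("anisotropic margins act along the correct patient axes", {
  sph <- cs_sphere(radius = 20, slice_spacing = 2)
  ptv <- expand_margin(sph, margin_spec(anterior = 7, posterior = 5,
                                        left = 7, right = 7,
                                        superior = 7, inferior = 7))
  bb <- spacerdose:::.stacks_bbox(list(ptv))
  expect_equal(bb$ymax - 20, 5, tolerance = 0.35)   # posterior (+y) by 5
  expect_equal(-20 - bb$ymin, 7, tolerance = 0.35)  # anterior (-y) by 7
  expect_equal(bb$xmax - 20, 7, tolerance = 0.35)
})

test_that("zero margins leave the structure unchanged and empty input errors", {
  sph <- cs_sphere(radius = 20, slice_spacing = 2)
  id <- expand_margin(sph, margin_spec(0, 0, 0, 0, 0, 0))
  expect_equal(structure_volume(id), structure_volume(sph), tolerance = 1e-12)
  empty <- contour_stack("empty", list(), 2)
  expect_error(expand_margin(empty), "empty")
})

test_that("raster-vs-analytic error shrinks as the resolution is refined", {
  sph <- cs_sphere(radius = 12, slice_spacing = 2)
  true_v <- 4 / 3 * pi * 17^3 / 1000
  err <- vapply(c(2, 0.75), function(r) {
    v <- structure_volume(expand_margin(
      sph, margin_spec(5, 5, 5, 5, 5, 5),
      structure_recipe(raster_resolution = r)))
    abs(v - true_v) / true_v
  }, numeric(1))
  expect_lt(err[2], err[1] + 1e-9)
  expect_lt(err[2], 0.03)
})

test_that("wall generation matches the spherical-shell closed form", {
  sph <- cs_sphere(radius = 20, slice_spacing = 2)
  w <- suppressMessages(make_wall(sph))
  expect_equal(structure_volume(w), 4 / 3 * pi * (20^3 - 17^3) / 1000,
               tolerance = 0.03)
  # wall is a subset of the organ
  expect_lt(structure_volume(w), structure_volume(sph))
  expect_equal(overlap_volume(w, sph), structure_volume(w), tolerance = 0.03)
})

test_that("cylinder wall cross-section matches the annulus closed form", {
  cyl <- cs_cylinder(radius = 15, z_range = c(-50, 50), slice_spacing = 2)
  w <- suppressMessages(make_wall(cyl))
  mid <- which(abs(stack_z(w)) < 1e-6)
  a <- spacerdose:::.slice_area(w$slices[[mid]]$polys)
  expect_equal(a, pi * (15^2 - 12^2), tolerance = 0.03)
})

test_that("zero wall thickness gives an empty wall", {
  sph <- cs_sphere(radius = 20, slice_spacing = 2)
  w <- make_wall(sph, structure_recipe(wall_thickness = 0))
  expect_equal(structure_volume(w), 0)
})

test_that("organs thinner than the wall keep the whole slice", {
  thin <- cs_cylinder(radius = 2.5, z_range = c(-10, 10), slice_spacing = 2)
  expect_message(w <- make_wall(thin), "thinner")
  expect_equal(structure_volume(w), structure_volume(thin), tolerance = 0.05)
})

test_that("height limiting snaps to the slice grid and is idempotent", {
  wall <- cs_cylinder(radius = 10, z_range = c(0, 200), slice_spacing = 2.5)
  ptv <- cs_cylinder(radius = 10, z_range = c(80, 120), slice_spacing = 2.5)
  out <- height_limit(wall, ptv)
  expect_equal(range(stack_z(out)), c(62.5, 137.5))
  again <- height_limit(out, ptv)
  expect_identical(stack_z(again), stack_z(out))
  # PTV covering the wall: no-op
  big <- cs_cylinder(radius = 10, z_range = c(-50, 250), slice_spacing = 2.5)
  expect_identical(stack_z(height_limit(wall, big)), stack_z(wall))
  # zero extent: exactly the PTV z range
  out0 <- height_limit(wall, ptv, structure_recipe(height_limit_extent = 0))
  expect_equal(range(stack_z(out0)), c(80, 120))
  # disjoint z ranges
  low <- cs_cylinder(radius = 10, z_range = c(-100, -50), slice_spacing = 2.5)
  expect_warning(e <- height_limit(low, ptv), "disjoint")
  expect_equal(length(e$slices), 0L)
})

test_that("slice-summed volume matches analytic solids", {
  cube <- cs_cuboid(c(0, 10), c(0, 10), c(1, 11), slice_spacing = 2)
  expect_equal(structure_volume(cube), 1.000)   # 10 mm cube, exact
  sph <- cs_sphere(radius = 26.7, slice_spacing = 2)
  expect_equal(structure_volume(sph), 4 / 3 * pi * 26.7^3 / 1000,
               tolerance = 0.02)
  expect_equal(structure_volume(contour_stack("none", list(), 2)), 0)
})

test_that("overlap volume matches the sphere-sphere lens closed form", {
  s1 <- cs_sphere(c(0, 0, 0), 20, 2)
  s2 <- cs_sphere(c(0, 30, 0), 20, 2)
  lens <- pi * (4 * 20 + 30) * (2 * 20 - 30)^2 / 12 / 1000
  expect_equal(overlap_volume(s1, s2), lens, tolerance = 0.03)
  # commutative
  expect_equal(overlap_volume(s1, s2), overlap_volume(s2, s1),
               tolerance = 1e-9)
  # containment: overlap with itself equals its own volume
  expect_equal(overlap_volume(s1, s1), structure_volume(s1), tolerance = 0.02)
  # disjoint
  s3 <- cs_sphere(c(0, 100, 0), 20, 2)
  expect_equal(overlap_volume(s1, s3), 0)
})

test_that("slice Hausdorff distance matches analytic and brute-force values", {
  expect_equal(slice_hausdorff(circle_poly(r = 10), circle_poly(r = 25)), 1.5,
               tolerance = 1e-3)
  sq <- square_poly()
  expect_equal(slice_hausdorff(sq, sq), 0)
  off <- sq + matrix(c(3, 4), 4, 2, byrow = TRUE)
  expect_equal(slice_hausdorff(sq, off), 0.5, tolerance = 1e-3)
  expect_error(slice_hausdorff(rbind(c(0, 0), c(1, 1)), sq), "degenerate")
})

test_that("slice Hausdorff equals dense brute force on random polygon pairs", {
  set.seed(11)
  for (k in 1:20) {
    p <- random_star_poly(); q <- random_star_poly()
    expect_equal(slice_hausdorff(p, q) * 10, bf_hausdorff_mm(p, q),
                 tolerance = 0.2 / max(1, bf_hausdorff_mm(p, q)))
  }
})

test_that("mean slice Hausdorff averages matched slices only", {
  a <- cs_cylinder(c(0, 0), 10, c(0, 18), slice_spacing = 2)
  b <- cs_cylinder(c(21.8, 0), 10, c(0, 18), slice_spacing = 2)
  # parallel equal cylinders: every slice equals the axis separation
  expect_equal(mean_slice_hausdorff(a, b), 2.18, tolerance = 1e-3)
  # identical stacks: zero
  expect_equal(mean_slice_hausdorff(a, a), 0)
  # single shared slice
  short <- cs_cylinder(c(21.8, 0), 10, c(-0.5, 0.5), slice_spacing = 2)
  expect_equal(mean_slice_hausdorff(a, short), 2.18, tolerance = 1e-3)
  # no common slices
  far <- cs_cylinder(c(0, 0), 10, c(100, 110), slice_spacing = 2)
  expect_error(mean_slice_hausdorff(a, far), "common")
})
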