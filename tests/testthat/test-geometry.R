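test_that("default geometry has the documented layer structure", {
  geom <- fx_geom()
  expect_equal(geom$outer_radius, 0.36 / (2 * pi))
  expect_equal(geom$skin_thickness, 0.001)
  expect_equal(geom$muscle_thickness, 0.01)
  # a point 0.5 mm under the surface is skin; 3 mm under is fat (0.6 cm case)
  R <- geom$outer_radius
  expect_identical(classify_point(geom, c(0, R - 0.0005)), "skin")
  expect_identical(classify_point(geom, c(0, R - 0.003)), "fat")
})

test_that("zero fat thickness yields an empty fat region", {
  geom <- fx_geom(fat = 0)
  R <- geom$outer_radius
  # 1.5 mm under the surface classifies as muscle when there is no fat
  expect_identical(classify_point(geom, c(0, R - 0.0015)), "muscle")
  mesh <- fx_mesh(fat = 0, h = 0.003)
  expect_false(any(mesh$element_region == "fat"))
})

test_that("point classification resolves nested structures innermost-first", {
  geom <- fx_geom()
  expect_identical(classify_point(geom, geom$nodule$center), "nodule")
  expect_identical(classify_point(geom, c(0, 2 * geom$outer_radius)),
                   "outside")
  expect_identical(classify_point(geom, geom$trachea$center), "trachea")
  # deep posterior point, below the trachea: plain muscle
  expect_identical(classify_point(geom, c(0, -0.045)), "muscle")
})

test_that("nodule size presets reproduce the printed areas", {
  areas <- vapply(c("small", "medium", "large"), function(sz) {
    ax <- nodule_semi_axes(sz)
    1e4 * pi * ax[1] * ax[2]
  }, numeric(1))
  expect_equal(unname(areas), c(2.64, 8.71, 17.76), tolerance = 1e-3)
})

test_that("Monte-Carlo area of the nodule label matches pi*a*b within 1%", {
  geom <- fx_geom()
  set.seed(7)
  n <- 4e5
  box <- 0.05
  pts <- cbind(runif(n, -box, box), runif(n, -box, box))
  frac <- mean(classify_point(geom, pts) == "nodule")
  mc_area <- frac * (2 * box)^2
  expect_equal(mc_area, pi * geom$nodule$a * geom$nodule$b, tolerance = 0.01)
})

test_that("probe points sit where the analyses expect them", {
  geom <- fx_geom()
  pp <- probe_points(geom)
  R <- geom$outer_radius
  # both skin probes lie on the outer circle to 1e-9 m
  expect_lt(abs(sqrt(sum(pp$front_of_nodule^2)) - R), 1e-9)
  expect_lt(abs(sqrt(sum(pp$contralateral^2)) - R), 1e-9)
  # contralateral is the exact sagittal reflection of the front probe
  expect_identical(pp$contralateral, c(-pp$front_of_nodule[1],
                                       pp$front_of_nodule[2]))
  # front probe arc coordinate is about -3 cm (nodule side is negative)
  expect_equal(pp$front_arc, -0.03, tolerance = 0.01)
  expect_lt(pp$front_arc, 0)
  # the lobe mirror is the reflection of the nodule centre
  expect_identical(pp$lobe_mirror, c(-pp$nodule_center[1],
                                     pp$nodule_center[2]))
})

test_that("mirroring the geometry swaps the nodule side consistently", {
  geom <- fx_geom()
  mg <- mirror_geometry(geom)
  ppo <- probe_points(geom)
  ppm <- probe_points(mg)
  expect_equal(ppm$front_of_nodule, ppo$contralateral)
  expect_equal(ppm$nodule_center, ppo$lobe_mirror)
  expect_identical(classify_point(mg, ppo$lobe_mirror), "nodule")
})

test_that("geometry errors name the violated containment", {
  # a nodule larger than the lobe cannot be contained
  expect_error(neck_geometry(nodule_semi_axes = c(0.04, 0.021)),
               "nodule is not contained inside the left lobe")
  # a custom nodule deep enough to reach the trachea region is refused
  expect_error(neck_geometry(fat_thickness = 0.012,
                             lobe_semi_axes = c(0.034, 0.0215)),
               "lobe")
})

test_that("geometry serializes to JSON and back without loss", {
  geom <- fx_geom(fat = 0.003)
  path <- withr::local_tempfile(fileext = ".json")
  geometry_to_json(geom, path)
  back <- geometry_from_json(path)
  expect_equal(back$outer_radius, geom$outer_radius)
  expect_equal(back$nodule$center, geom$nodule$center)
  expect_equal(back$lobes$right$axis, geom$lobes$right$axis)
  expect_equal(back$trachea$radius, geom$trachea$radius)
  # restored geometry classifies identically
  set.seed(11)
  pts <- cbind(runif(200, -0.05, 0.05), runif(200, -0.05, 0.05))
  expect_identical(classify_point(back, pts), classify_point(geom, pts))
})
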