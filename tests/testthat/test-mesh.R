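test_that("mesh conserves area and resolves all tissue interfaces", {
  geom <- fx_geom()
  mesh <- fx_mesh(h = 0.002)
  q <- mesh_quality(mesh)
  target <- pi * geom$outer_radius^2 - pi * geom$trachea$radius^2
  expect_lt(abs(q$total_area - target) / target, 0.001)
  expect_identical(q$interface_violations, 0L)
  # every element carries a tissue tag
  expect_true(all(mesh$element_region %in%
                    c("skin", "fat", "muscle", "thyroid", "nodule")))
  # all signed areas positive (counter-clockwise orientation)
  expect_true(all(thyrotherm:::tri_signed_areas(mesh$nodes,
                                                mesh$elements) > 0))
})

test_that("element quality holds exhaustively across the case grid", {
  for (fat in c(0, 0.006, 0.012)) {
    mesh <- fx_mesh(fat = fat, h = 0.002)
    expect_gte(mesh$min_angle, 20)
  }
  expect_gte(fx_mesh(h = 0.004)$min_angle, 20)
})

test_that("boundary edges lie on their circles and are tagged once", {
  geom <- fx_geom()
  mesh <- fx_mesh(h = 0.002)
  be <- mesh$boundary_edges
  expect_setequal(unique(be$tag), c("GAMMA1", "GAMMA2", "GAMMA3"))
  nds <- unique(c(be$a, be$b))
  for (tag in c("GAMMA1", "GAMMA3")) {
    sel <- unique(c(be$a[be$tag == tag], be$b[be$tag == tag]))
    r <- sqrt(rowSums(mesh$nodes[sel, , drop = FALSE]^2))
    expect_lt(max(abs(r - geom$outer_radius)), 1e-6)
  }
  sel2 <- unique(c(be$a[be$tag == "GAMMA2"], be$b[be$tag == "GAMMA2"]))
  d <- sqrt((mesh$nodes[sel2, 1] - geom$trachea$center[1])^2 +
            (mesh$nodes[sel2, 2] - geom$trachea$center[2])^2)
  expect_lt(max(abs(d - geom$trachea$radius)), 1e-6)
  # no boundary edge appears twice
  key <- paste(pmin(be$a, be$b), pmax(be$a, be$b))
  expect_false(any(duplicated(key)))
  # anterior/posterior split: GAMMA1 midpoints anterior, GAMMA3 posterior
  mid1 <- (mesh$nodes[be$a[be$tag == "GAMMA1"], 2] +
             mesh$nodes[be$b[be$tag == "GAMMA1"], 2]) / 2
  expect_true(all(mid1 > 0))
})

test_that("refinement changes the steady probe reading below 0.02 degC", {
  geom <- fx_geom()
  reg <- tissue_registry("per_minute_gland")
  probe <- probe_points(geom)$front_of_nodule
  t_coarse <- evaluate_field(solve_steady(fx_mesh(h = 0.003), reg,
                                          boundary_spec()), probe)
  t_fine <- evaluate_field(solve_steady(fx_mesh(h = 0.0015), reg,
                                        boundary_spec()), probe)
  expect_lt(abs(t_fine - t_coarse), 0.02)
})

test_that("convergence report shows shrinking deltas and guards its input", {
  geom <- fx_geom()
  rep <- convergence_report(geom, c(0.004, 0.003, 0.002))
  expect_equal(nrow(rep), 3L)
  expect_true(is.na(rep$delta[1]))
  expect_lt(abs(rep$delta[3]), abs(rep$delta[2]) + 0.02)
  expect_error(convergence_report(geom, 0.004), "length")
  expect_error(convergence_report(geom, c(0.002, 0.004)), "descending")
})

test_that("mesh exports write readable node/element tables and VTU", {
  mesh <- fx_mesh(h = 0.004)
  stem <- file.path(withr::local_tempdir(), "mesh")
  write_mesh(mesh, stem)
  nodes <- utils::read.csv(paste0(stem, "_nodes.csv"))
  elems <- utils::read.csv(paste0(stem, "_elements.csv"))
  expect_equal(nrow(nodes), nrow(mesh$nodes))
  expect_equal(nrow(elems), nrow(mesh$elements))
  expect_identical(elems$region, mesh$element_region)
  vtu <- write_mesh_vtu(mesh, stem, values = rep(37, nrow(mesh$nodes)))
  x <- xml2::read_xml(vtu)
  expect_identical(xml2::xml_name(x), "VTKFile")
})
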