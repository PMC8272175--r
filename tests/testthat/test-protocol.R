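test_that("protocol phases chain continuously and sample on schedule", {
  res <- fx_mini_protocol()
  # first cooling sample is the steady field itself
  expect_identical(res$cooling_fields[[1L]]$values, res$steady_field$values)
  # reheating starts from the last cooling field (no jump at the junction)
  last_cool <- res$cooling_fields[[length(res$cooling_fields)]]
  expect_lt(max(abs(res$reheating_fields[[1L]]$values - last_cool$values)),
            1e-9)
  # timeline strictly increasing within each phase
  tc <- vapply(res$cooling_fields, `[[`, numeric(1), "time")
  expect_true(all(diff(tc) > 0))
})

test_that("full-length protocol produces the camera-schedule series", {
  res <- fx_protocol(fat = 0)
  # reheating yields 20 sampled fields after t = 0, one every 15 s
  expect_equal(length(res$reheating_fields) - 1L, 20L)
  sf <- extract_point_series(res, probe_points(res$geom)$front_of_nodule)
  # (300 + 300)/15 + 1 samples, uniform 15 s spacing, no junction duplicate
  expect_equal(length(sf$values), 41L)
  expect_equal(unique(diff(sf$times)), 15)
  # cooling is monotone non-increasing at the probe
  cool <- sf$values[1:21]
  expect_true(all(diff(cool) <= 1e-9))
  # five minutes of reheating does not recover the initial temperature
  expect_lt(sf$values[41], sf$values[1])
})

test_that("constant fields give a constant extracted series", {
  res <- fx_mini_protocol()
  flat <- res
  for (i in seq_along(flat$cooling_fields)) {
    flat$cooling_fields[[i]]$values[] <- 31.5
  }
  for (i in seq_along(flat$reheating_fields)) {
    flat$reheating_fields[[i]]$values[] <- 31.5
  }
  s <- extract_point_series(flat, probe_points(res$geom)$front_of_nodule)
  expect_equal(unique(s$values), 31.5)
  expect_error(extract_point_series(res, c(1, 1)), "outside")
})

test_that("skin profile is symmetric when the nodule is thyroid tissue", {
  geom <- fx_geom()
  mesh <- generate_mesh(geom, 0.002, symmetric = TRUE)
  fld <- solve_steady(mesh, tissue_registry("per_minute_gland"),
                      boundary_spec())
  prof <- extract_skin_profile(fld, geom)
  mirrored <- prof[rev(seq_len(nrow(prof))), ]
  expect_lt(max(abs(prof$T - mirrored$T)), 1e-6)
})

test_that("skin profile stays within physical bounds and spans the arc", {
  fld <- fx_steady()
  prof <- extract_skin_profile(fld, fx_geom())
  expect_true(all(prof$T > 25 & prof$T < max(fld$values)))
  expect_equal(max(prof$arc_cm), -min(prof$arc_cm), tolerance = 0.01)
  expect_gt(max(prof$arc_cm), 8.9)
  # the warm spot sits on the nodule side (negative arc)
  expect_lt(prof$arc_cm[which.max(prof$T)], 0)
})

test_that("line profile annotations agree with point classification", {
  geom <- fx_geom()
  fld <- fx_steady()
  lp <- extract_line_profile(fld, geom, side = "nodule")
  th <- geom$nodule_angle
  u <- c(-sin(th), cos(th))
  pts <- cbind((geom$outer_radius - lp$depth) * u[1],
               (geom$outer_radius - lp$depth) * u[2])
  expect_identical(lp$tissue, classify_point(geom, pts))
  # crosses the expected stack in order: skin, fat, muscle, thyroid, nodule
  expect_identical(unique(lp$tissue)[1:5],
                   c("skin", "fat", "muscle", "thyroid", "nodule"))
  # first sample equals the field at the skin probe
  expect_equal(lp$T[1], evaluate_field(fld, probe_points(geom)$front_of_nodule))
  # mirror line crosses the healthy lobe
  lpm <- extract_line_profile(fld, geom, side = "mirror")
  expect_true(any(lpm$tissue == "thyroid"))
  expect_identical(lpm$tissue[1], "skin")
})

test_that("sweep tabulates every case and survives per-case failure", {
  cfg <- protocol_config(cooling = list(h = 50, Tair = 25, duration = 30),
                         reheating = list(h = 10, Tair = 25, duration = 30),
                         dt = 3)
  cases <- list(case_spec(fat_thickness = 0, nodule_size = "large",
                          h_target = 0.004),
                case_spec(fat_thickness = 0.006, nodule_size = "large",
                          h_target = 0.004))
  out_csv <- withr::local_tempfile(fileext = ".csv")
  tab <- run_sweep(cases, cfg, out_csv = out_csv)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$error == ""))
  expect_true(all(is.finite(tab$delta_TCL)))
  # thicker fat insulates: smaller contralateral contrast
  expect_gt(tab$delta_TCL[1], tab$delta_TCL[2])
  expect_true(file.exists(out_csv))
  # a failing case is recorded, the sweep continues
  bad <- case_spec(fat_thickness = 0, nodule_size = c(0.05, 0.03),
                   h_target = 0.004)
  tab2 <- run_sweep(list(bad, cases[[1]]), cfg)
  expect_true(nzchar(tab2$error[1]))
  expect_true(is.na(tab2$delta_TCL[1]))
  expect_false(is.na(tab2$delta_TCL[2]))
})

test_that("the factorial grid enumerates 12 geometry cases", {
  grid <- geometry_case_grid(h_target = 0.004)
  expect_length(grid, 12L)
  labs <- vapply(grid, `[[`, character(1), "label")
  expect_false(any(duplicated(labs)))
})

test_that("mean-skin-threshold stop ends cooling early when reached", {
  cfg <- protocol_config(cooling = list(h = 400, Tair = 10, duration = 300),
                         reheating = list(h = 10, Tair = 25, duration = 30),
                         dt = 3, cooling_stop = "mean_skin_threshold",
                         skin_threshold = 30)
  res <- run_protocol(case_spec(fat_thickness = 0, h_target = 0.004), cfg)
  g1 <- thyrotherm:::gamma1_nodes(res$mesh)
  last <- res$cooling_fields[[length(res$cooling_fields)]]
  expect_lte(mean(last$values[g1]), 30)
  expect_lt(last$time, 300)
})
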