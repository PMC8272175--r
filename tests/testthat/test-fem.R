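test_that("solver matches the closed-form 1D bioheat slab", {
  L <- 0.02
  mesh <- strip_mesh(L, 0.01, 0.0005, tissue = "muscle")
  reg <- tissue_registry()
  bc <- boundary_spec(h = 10, Tair = 25, Tp = 37)
  fld <- solve_steady(mesh, reg, bc)
  xs <- seq(0, L, by = 0.0005)
  num <- evaluate_field(fld, cbind(xs, 0.005))
  ana <- slab_analytic(xs, L, reg["muscle", "k"], reg["muscle", "wb"],
                       reg["muscle", "rho_b"], reg["muscle", "c_b"],
                       37, reg["muscle", "Qm"], 37, 10, 25)
  expect_lt(max(abs(num - ana)), 0.01)
})

test_that("pure conduction with uniform Dirichlet data is exactly constant", {
  mesh <- fx_mesh(h = 0.004)
  reg <- tissue_registry()
  reg$Qm[] <- 0
  reg$wb[] <- 0
  # convective arc disabled: only the prescribed 37 degC boundary remains
  fld <- solve_steady(mesh, reg, boundary_spec(h = 0, Tair = 25, Tp = 37))
  expect_lt(max(abs(fld$values - 37)), 1e-9)
})

test_that("steady conduction solutions obey the discrete maximum principle", {
  mesh <- fx_mesh(h = 0.002)
  reg <- tissue_registry()
  reg$Qm[] <- 0
  reg$wb[] <- 0
  fld <- solve_steady(mesh, reg, boundary_spec(h = 10, Tair = 25, Tp = 37))
  expect_gte(min(fld$values), 25 - 1e-9)
  expect_lte(max(fld$values), 37 + 1e-9)
})

test_that("perfused interior temperatures respect the source bound", {
  fld <- fx_steady()
  reg <- tissue_registry("per_minute_gland")
  cap <- max(37, max(37 + reg$Qm / (reg$wb * reg$rho_b * reg$c_b)))
  expect_lte(max(fld$values), cap + 1e-6)
})

test_that("a system with no temperature-fixing term is rejected", {
  mesh <- strip_mesh(0.01, 0.01, 0.002)
  mesh$boundary_edges$tag <- "GAMMA2"  # everything insulated
  reg <- tissue_registry()
  reg$wb[] <- 0
  expect_error(solve_steady(mesh, reg, boundary_spec(h = 0)), "singular")
})

test_that("P1 interpolation is exact for linear fields and nodal at nodes", {
  mesh <- fx_mesh(h = 0.004)
  a <- 13.7; b <- -41.2; c0 <- 31
  fld <- temperature_field(mesh, a * mesh$nodes[, 1] + b * mesh$nodes[, 2] +
                             c0)
  set.seed(3)
  idx <- sample(nrow(mesh$elements), 60)
  l <- matrix(stats::runif(180), ncol = 3)
  l <- l / rowSums(l)
  pts <- sapply(1:2, function(d) {
    rowSums(sapply(1:3, function(k) l[, k] *
                     mesh$nodes[mesh$elements[cbind(idx, k)], d]))
  })
  expect_equal(evaluate_field(fld, pts),
               a * pts[, 1] + b * pts[, 2] + c0, tolerance = 1e-9)
  # a mesh node returns its own nodal value
  nd <- mesh$nodes[17, , drop = FALSE]
  expect_equal(evaluate_field(fld, nd), fld$values[17])
  expect_error(evaluate_field(fld, c(1, 1)), "outside")
})

test_that("equilibrium is preserved exactly by the time integrator", {
  mesh <- strip_mesh(0.02, 0.01, 0.002)
  mesh$boundary_edges$tag <- "GAMMA2"  # fully insulated
  reg <- tissue_registry()
  reg$Qm[] <- 0
  reg$wb[] <- 0
  T0 <- temperature_field(mesh, rep(37, nrow(mesh$nodes)))
  out <- solve_transient(mesh, reg, boundary_spec(h = 0), T0,
                         duration = 60, dt = 5, sample_every = 15)
  expect_equal(length(out), 5L)
  expect_identical(out[[1L]]$values, T0$values)
  for (f in out) expect_lt(max(abs(f$values - 37)), 1e-9)
})

test_that("transient integration converges to the steady solution", {
  mesh <- fx_mesh(h = 0.004)
  reg <- tissue_registry("per_minute_gland")
  bc <- boundary_spec()
  steady <- solve_steady(mesh, reg, bc)
  # start from the end of a fan-cooling phase and relax under natural
  # convection: the protocol-relevant return to equilibrium
  cooled <- solve_transient(mesh, reg, boundary_spec(h = 50), steady,
                            duration = 300, dt = 5, sample_every = 300)
  out <- solve_transient(mesh, reg, bc, cooled[[2L]], duration = 3600,
                         dt = 15, sample_every = 3600)
  expect_lt(max(abs(out[[length(out)]]$values - steady$values)), 0.05)
})

test_that("time step and sampling misconfiguration is caught", {
  mesh <- strip_mesh(0.01, 0.01, 0.002)
  reg <- tissue_registry()
  T0 <- temperature_field(mesh, rep(37, nrow(mesh$nodes)))
  bc <- boundary_spec()
  expect_error(solve_transient(mesh, reg, bc, T0, 60, dt = -1), "dt")
  expect_error(solve_transient(mesh, reg, bc, T0, 60, dt = 4,
                               sample_every = 15), "multiple")
  expect_error(solve_transient(mesh, reg, bc, T0, 70, dt = 1,
                               sample_every = 15), "multiple")
})
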