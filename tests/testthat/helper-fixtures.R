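# Shared fixtures, memoized so expensive meshes/solves are built once per
# test session. Test meshes default to 2 mm elements: steady probe readings
# there sit within a few thousandths of a degree of the 1 mm study meshes
# (see the self-convergence checks), far inside every tolerance asserted.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_geom <- function(fat = 0.006, size = "large") {
  memo(sprintf("geom_%g_%s", fat, size),
       neck_geometry(fat_thickness = fat, nodule_semi_axes = size))
}

fx_mesh <- function(fat = 0.006, size = "large", h = 0.002) {
  memo(sprintf("mesh_%g_%s_%g", fat, size, h),
       generate_mesh(fx_geom(fat, size), h))
}

fx_steady <- function(fat = 0.006, size = "large", h = 0.002,
                      preset = "per_minute_gland") {
  memo(sprintf("steady_%g_%s_%g_%s", fat, size, h, preset),
       solve_steady(fx_mesh(fat, size, h), tissue_registry(preset),
                    boundary_spec()))
}

fx_protocol <- function(fat, size = "large", h = 0.002) {
  memo(sprintf("protocol_%g_%s_%g", fat, size, h),
       run_protocol(case_spec(fat_thickness = fat, nodule_size = size,
                              h_target = h),
                    protocol_config(),
                    mesh = fx_mesh(fat, size, h)))
}

# short protocol for structural checks (30 s phases, coarse mesh)
fx_mini_protocol <- function(fat = 0, size = "large") {
  memo(sprintf("mini_%g_%s", fat, size),
       run_protocol(case_spec(fat_thickness = fat, nodule_size = size,
                              h_target = 0.004),
                    protocol_config(cooling = list(h = 50, Tair = 25,
                                                   duration = 30),
                                    reheating = list(h = 10, Tair = 25,
                                                     duration = 30),
                                    dt = 3)))
}

# closed-form steady 1D bioheat slab: prescribed Tp at x = 0, convective
# (h, Tair) at x = L, uniform properties; independent oracle for the solver
slab_analytic <- function(x, L, k, w, rho_b, c_b, Tb, Qm, Tp, h, Tair) {
  W <- w * rho_b * c_b
  m <- sqrt(W / k)
  Tinf <- Tb + Qm / W
  C1 <- Tp - Tinf
  C2 <- (-k * m * C1 * sinh(m * L) - h * (Tinf + C1 * cosh(m * L) - Tair)) /
    (k * m * cosh(m * L) + h * sinh(m * L))
  Tinf + C1 * cosh(m * x) + C2 * sinh(m * x)
}
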