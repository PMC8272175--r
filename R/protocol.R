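# Simulation of the dynamic infrared thermography (DITI) examination:
# steady equilibrium with the room, forced fan cooling, natural reheating,
# with thermogram-rate sampling of the fields.

#' DITI protocol configuration
#'
#' @param cooling List \code{h} (W/(m^2 K)), \code{Tair} (degC),
#'   \code{duration} (s) for the forced-cooling phase. The fan is modelled
#'   purely as an increased convection coefficient at room air temperature.
#' @param reheating Same fields for the natural-reheating phase.
#' @param sample_every Field sampling interval, s (the camera frame period).
#' @param dt Time-integration step, s.
#' @param cooling_stop \code{"fixed_duration"} or
#'   \code{"mean_skin_threshold"}: the protocol's alternative stop rule,
#'   ending cooling as soon as the mean anterior skin temperature drops to
#'   \code{skin_threshold} (or at \code{duration}, whichever is first).
#' @param skin_threshold Mean skin temperature stop level, degC.
#' @param Tp Prescribed posterior/core temperature, degC.
#' @return Object of class \code{protocol_config}.
#' @export
protocol_config <- function(cooling = list(h = 50, Tair = 25, duration = 300),
                            reheating = list(h = 10, Tair = 25, duration = 300),
                            sample_every = 15, dt = 1,
                            cooling_stop = c("fixed_duration",
                                             "mean_skin_threshold"),
                            skin_threshold = 30, Tp = 37) {
  cooling_stop <- match.arg(cooling_stop)
  stopifnot(cooling$h >= 0, reheating$h >= 0)
  for (dur in c(cooling$duration, reheating$duration)) {
    if (abs(dur / sample_every - round(dur / sample_every)) > 1e-9) {
      stop("configuration error: phase durations must be multiples of ",
           "sample_every")
    }
  }
  structure(list(cooling = cooling, reheating = reheating,
                 sample_every = sample_every, dt = dt,
                 cooling_stop = cooling_stop,
                 skin_threshold = skin_threshold, Tp = Tp),
            class = "protocol_config")
}

gamma1_nodes <- function(mesh) {
  be <- mesh$boundary_edges
  sort(unique(c(be$a[be$tag == "GAMMA1"], be$b[be$tag == "GAMMA1"])))
}

#' Run the full DITI protocol for one case
#'
#' Solves the steady problem (natural convection), uses it as the initial
#' condition for the forced-cooling transient, chains the last cooling field
#' into the natural-reheating transient, and retains all sampled fields.
#'
#' @param case A \code{\link{case_spec}}.
#' @param cfg A \code{\link{protocol_config}}.
#' @param registry Optional \code{\link{tissue_registry}}; derived from the
#'   case (preset + nodule combo) when omitted.
#' @param mesh Optional pre-built mesh for the case's geometry.
#' @return Object of class \code{protocol_result} with fields
#'   \code{steady_field}, \code{cooling_fields}, \code{reheating_fields},
#'   \code{case}, \code{geom}, \code{mesh}, \code{config}.
#' @examples
#' \donttest{
#' res <- run_protocol(case_spec(h_target = 0.003), protocol_config())
#' print(res)
#' }
#' @export
run_protocol <- function(case, cfg = protocol_config(), registry = NULL,
                         mesh = NULL) {
  stopifnot(inherits(case, "case_spec"), inherits(cfg, "protocol_config"))
  if (is.null(registry)) {
    registry <- set_nodule_combo(tissue_registry(case$preset),
                                 Qm = case$Qm, wb = case$wb)
  }
  stage <- "geometry"
  result <- tryCatch({
    geom <- neck_geometry(fat_thickness = case$fat_thickness,
                          nodule_semi_axes = case$nodule_semi_axes)
    stage <- "meshing"
    if (is.null(mesh)) mesh <- generate_mesh(geom, case$h_target)
    stage <- "steady"
    bc_nat <- boundary_spec(h = cfg$reheating$h, Tair = cfg$reheating$Tair,
                            Tp = cfg$Tp)
    steady <- solve_steady(mesh, registry, bc_nat)
    stage <- "cooling"
    bc_cool <- boundary_spec(h = cfg$cooling$h, Tair = cfg$cooling$Tair,
                             Tp = cfg$Tp)
    cooling <- if (cfg$cooling_stop == "fixed_duration") {
      solve_transient(mesh, registry, bc_cool, steady,
                      duration = cfg$cooling$duration, dt = cfg$dt,
                      sample_every = cfg$sample_every)
    } else {
      g1 <- gamma1_nodes(mesh)
      fields <- list(steady)
      current <- steady
      t <- 0
      while (t < cfg$cooling$duration) {
        step <- solve_transient(mesh, registry, bc_cool, current,
                                duration = cfg$sample_every, dt = cfg$dt,
                                sample_every = cfg$sample_every)
        current <- step[[2L]]
        t <- t + cfg$sample_every
        current$time <- t
        fields[[length(fields) + 1L]] <- current
        if (mean(current$values[g1]) <= cfg$skin_threshold) break
      }
      fields
    }
    stage <- "reheating"
    bc_heat <- boundary_spec(h = cfg$reheating$h, Tair = cfg$reheating$Tair,
                             Tp = cfg$Tp)
    reheating <- solve_transient(mesh, registry, bc_heat,
                                 cooling[[length(cooling)]],
                                 duration = cfg$reheating$duration,
                                 dt = cfg$dt,
                                 sample_every = cfg$sample_every)
    structure(list(steady_field = steady, cooling_fields = cooling,
                   reheating_fields = reheating, case = case, geom = geom,
                   mesh = mesh, registry = registry, config = cfg),
              class = "protocol_result")
  }, error = function(e) {
    stop(sprintf("protocol stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' @export
print.protocol_result <- function(x, ...) {
  pp <- probe_points(x$geom)
  s0 <- evaluate_field(x$steady_field, pp$front_of_nodule)
  sc <- evaluate_field(x$cooling_fields[[length(x$cooling_fields)]],
                       pp$front_of_nodule)
  sr <- evaluate_field(x$reheating_fields[[length(x$reheating_fields)]],
                       pp$front_of_nodule)
  cat("DITI protocol result:", x$case$label, "\n")
  cat(sprintf("  front-of-nodule skin: %.2f degC (steady) -> %.2f (end of cooling) -> %.2f (end of reheating)\n",
              s0, sc, sr))
  cat(sprintf("  %d cooling + %d reheating sampled fields (every %g s)\n",
              length(x$cooling_fields), length(x$reheating_fields) - 1L,
              x$config$sample_every))
  invisible(x)
}

#' Extract the probe temperature series from a protocol result
#'
#' Concatenates the cooling and reheating samples at a fixed point; the
#' junction field (end of cooling = start of reheating) appears once, as the
#' last cooling sample.
#'
#' @param result A \code{\link{run_protocol}} result.
#' @param probe Length-2 point, m (e.g. from \code{\link{probe_points}}).
#' @param label Series label.
#' @return A \code{\link{temperature_series}}.
#' @export
extract_point_series <- function(result, probe,
                                 label = result$case$label) {
  fields <- c(result$cooling_fields, result$reheating_fields[-1L])
  cool_end <- result$cooling_fields[[length(result$cooling_fields)]]$time
  times <- vapply(result$cooling_fields, function(f) f$time, numeric(1))
  times <- c(times,
             cool_end + vapply(result$reheating_fields[-1L],
                               function(f) f$time, numeric(1)))
  vals <- vapply(fields, function(f) evaluate_field(f, probe), numeric(1))
  temperature_series(times, vals, label = label)
}

#' Skin-surface temperature profile along the anterior arc
#'
#' Samples a field along the convective skin boundary at 1 mm arc spacing.
#' Arc coordinate 0 is the anterior sagittal point; negative values are on
#' the nodule (patient's left) side.
#'
#' @param field A \code{temperature_field} on a neck mesh.
#' @param geom The \code{\link{neck_geometry}} (defaults to the mesh's).
#' @param spacing Arc sampling step, m.
#' @return Data frame with \code{arc_cm} and \code{T}.
#' @export
extract_skin_profile <- function(field, geom = field$mesh$geom,
                                 spacing = 0.001) {
  R <- geom$outer_radius
  smax <- R * (pi / 2 - 1e-3)
  # symmetric arc grid: s = 0 is on it and -s is sampled whenever s is
  s <- seq(-smax, smax, length.out = 2L * ceiling(smax / spacing) + 1L)
  pts <- cbind(R * sin(s / R), R * cos(s / R))
  data.frame(arc_cm = 100 * s, T = evaluate_field(field, pts))
}

#' Temperature profile along a line from the skin to the trachea
#'
#' Samples the field along the radial ray through the nodule centre (or its
#' mirror across the sagittal axis), from the skin surface to the tracheal
#' wall, annotating each sample with its tissue region.
#'
#' @param field A \code{temperature_field} on a neck mesh.
#' @param geom The \code{\link{neck_geometry}}.
#' @param side \code{"nodule"} (through the nodule) or \code{"mirror"}.
#' @param spacing Depth sampling step, m.
#' @return Data frame with \code{depth} (m below the surface), \code{T}
#'   (degC) and \code{tissue}.
#' @export
extract_line_profile <- function(field, geom = field$mesh$geom,
                                 side = c("nodule", "mirror"),
                                 spacing = 0.00025) {
  side <- match.arg(side)
  th <- geom$nodule_angle
  u <- c(-sin(th), cos(th))
  if (side == "mirror") u <- c(-u[1], u[2])
  R <- geom$outer_radius
  # depth at which the ray (R - d) * u meets the trachea circle
  ct <- geom$trachea$center
  rt <- geom$trachea$radius
  b <- sum(u * ct)
  disc <- b^2 - sum(ct^2) + rt^2
  d_max <- if (disc >= 0) R - (b + sqrt(disc)) else R
  d_max <- min(d_max, R)
  d <- seq(0, d_max - 1e-6, by = spacing)
  pts <- cbind((R - d) * u[1], (R - d) * u[2])
  data.frame(depth = d, T = evaluate_field(field, pts),
             tissue = classify_point(geom, pts))
}

#' Factorial sweep over simulation cases
#'
#' Runs the full protocol for each case and tabulates the summary metrics:
#' steady contralateral skin difference (delta_TCL), steady fat-layer drop
#' (delta_TF) and the front-of-nodule series limits (steady start, end of
#' cooling, end of reheating). Per-case failures are recorded in the
#' \code{error} column and the sweep continues.
#'
#' @param cases List of \code{\link{case_spec}}s.
#' @param cfg A \code{\link{protocol_config}}.
#' @param out_csv Optional path to persist the table.
#' @return Data frame, one row per case, in input order.
#' @export
run_sweep <- function(cases, cfg = protocol_config(), out_csv = NULL) {
  stopifnot(length(cases) >= 1L)
  rows <- lapply(cases, function(cs) {
    base <- data.frame(label = cs$label, fat_cm = 100 * cs$fat_thickness,
                       nodule = cs$nodule_size,
                       nodule_area_cm2 = 1e4 * pi * prod(cs$nodule_semi_axes),
                       Qm = cs$Qm, wb = cs$wb, preset = cs$preset,
                       stringsAsFactors = FALSE)
    res <- tryCatch(run_protocol(cs, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      return(cbind(base, delta_TCL = NA_real_, delta_TF = NA_real_,
                   T_start = NA_real_, T_cooling_end = NA_real_,
                   T_end = NA_real_, error = conditionMessage(res)))
    }
    m <- summarize_protocol(res)
    cbind(base, delta_TCL = m$delta_TCL, delta_TF = m$delta_TF,
          T_start = m$start, T_cooling_end = m$cooling_min, T_end = m$end,
          error = "")
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Default factorial case grid of the geometry study
#'
#' Four fat thicknesses (0, 0.3, 0.6, 1.2 cm) crossed with the three nodule
#' size presets, with malignant-like nodule parameters.
#'
#' @param h_target Mesh size for every case, m.
#' @param preset Perfusion preset.
#' @return List of 12 \code{\link{case_spec}}s.
#' @export
geometry_case_grid <- function(h_target = 0.001,
                               preset = "per_minute_gland") {
  grid <- expand.grid(fat = c(0, 0.003, 0.006, 0.012),
                      size = c("small", "medium", "large"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    case_spec(fat_thickness = grid$fat[i], nodule_size = grid$size[i],
              h_target = h_target, preset = preset)
  })
}
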