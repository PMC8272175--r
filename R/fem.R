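# Linear (P1) finite elements for Pennes' bioheat equation.
#
# Steady form:    0 = div(k grad T) + wb*rho_b*c_b*(Tb - T) + Qm
# Transient form: rho*c dT/dt = div(k grad T) + wb*rho_b*c_b*(Tb - T) + Qm
#
# Boundary conditions: convective (Robin) exchange h*(Tair - T) on GAMMA1,
# zero flux on GAMMA2 (natural), prescribed temperature Tp on GAMMA3
# (imposed strongly by elimination, keeping the reduced system symmetric
# positive definite so one sparse Cholesky factor serves a whole transient
# phase).

#' Boundary condition specification
#'
#' @param h Convection coefficient on the skin arc, W/(m^2 K). 10 is the
#'   natural-convection value used at equilibrium and during reheating; 50
#'   emulates the examination fan during cooling.
#' @param Tair Ambient air temperature, degC.
#' @param Tp Prescribed (core) temperature on the posterior arc, degC.
#' @return Object of class \code{boundary_spec}.
#' @export
boundary_spec <- function(h = 10, Tair = 25, Tp = 37) {
  stopifnot(h >= 0)
  structure(list(gamma1 = list(h = h, Tair = Tair),
                 gamma2 = "zero-flux",
                 gamma3 = list(Tp = Tp)),
            class = "boundary_spec")
}

# assemble stiffness, perfusion/mass matrices and volume load
assemble_volume <- function(mesh, registry) {
  P <- mesh$nodes
  tri <- mesh$elements
  reg <- registry[mesh$element_region, , drop = FALSE]
  x1 <- P[tri[, 1], 1]; y1 <- P[tri[, 1], 2]
  x2 <- P[tri[, 2], 1]; y2 <- P[tri[, 2], 2]
  x3 <- P[tri[, 3], 1]; y3 <- P[tri[, 3], 2]
  A <- ((x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)) / 2
  if (any(A <= 0)) stop("solver error: non-positive element area")
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / (2 * A)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / (2 * A)

  n <- nrow(P)
  ii <- jj <- kk <- pp <- mm <- vector("list", 9L)
  perf <- reg$wb * reg$rho_b * reg$c_b
  rhoc <- reg$rho * reg$c
  idx <- 0L
  for (i in 1:3) {
    for (j in 1:3) {
      idx <- idx + 1L
      ii[[idx]] <- tri[, i]
      jj[[idx]] <- tri[, j]
      kk[[idx]] <- reg$k * A * (b[, i] * b[, j] + cc[, i] * cc[, j])
      mfac <- if (i == j) 1 / 6 else 1 / 12  # consistent mass
      pp[[idx]] <- perf * A * mfac
      mm[[idx]] <- rhoc * A * mfac
    }
  }
  i_all <- unlist(ii); j_all <- unlist(jj)
  K <- Matrix::sparseMatrix(i = i_all, j = j_all, x = unlist(kk),
                            dims = c(n, n))
  Pf <- Matrix::sparseMatrix(i = i_all, j = j_all, x = unlist(pp),
                             dims = c(n, n))
  M <- Matrix::sparseMatrix(i = i_all, j = j_all, x = unlist(mm),
                            dims = c(n, n))
  src <- (reg$Qm + perf * reg$Tb) * A / 3
  F <- as.numeric(Matrix::sparseMatrix(
    i = as.vector(tri), j = rep(1L, 3L * nrow(tri)),
    x = rep(src, 3L), dims = c(n, 1L)))
  list(K = K, P = Pf, M = M, F = F)
}

# Robin (convective) boundary terms on GAMMA1 edges
assemble_robin <- function(mesh, bc) {
  n <- nrow(mesh$nodes)
  be <- mesh$boundary_edges
  g1 <- be[be$tag == "GAMMA1", , drop = FALSE]
  if (nrow(g1) == 0L || bc$gamma1$h == 0) {
    return(list(R = Matrix::sparseMatrix(i = integer(), j = integer(),
                                         x = numeric(), dims = c(n, n)),
                Fr = numeric(n)))
  }
  pa <- mesh$nodes[g1$a, , drop = FALSE]
  pb <- mesh$nodes[g1$b, , drop = FALSE]
  L <- sqrt(rowSums((pa - pb)^2))
  h <- bc$gamma1$h
  i_all <- c(g1$a, g1$b, g1$a, g1$b)
  j_all <- c(g1$a, g1$b, g1$b, g1$a)
  x_all <- c(h * L / 3, h * L / 3, h * L / 6, h * L / 6)
  R <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all, dims = c(n, n))
  Fr <- as.numeric(Matrix::sparseMatrix(
    i = c(g1$a, g1$b), j = rep(1L, 2L * nrow(g1)),
    x = rep(h * bc$gamma1$Tair * L / 2, 2L), dims = c(n, 1L)))
  list(R = R, Fr = Fr)
}

dirichlet_nodes <- function(mesh) {
  be <- mesh$boundary_edges
  sort(unique(c(be$a[be$tag == "GAMMA3"], be$b[be$tag == "GAMMA3"])))
}

#' Solve the steady-state bioheat problem
#'
#' @param mesh A \code{\link{generate_mesh}} or \code{\link{strip_mesh}} mesh.
#' @param registry A \code{\link{tissue_registry}}.
#' @param bc A \code{\link{boundary_spec}}.
#' @return A \code{temperature_field}: nodal temperatures (degC) on the mesh.
#' @examples
#' \donttest{
#' mesh <- generate_mesh(neck_geometry(), h_target = 0.003)
#' fld <- solve_steady(mesh, tissue_registry("per_minute_gland"))
#' evaluate_field(fld, probe_points(mesh$geom)$nodule_center)
#' }
#' @export
solve_steady <- function(mesh, registry, bc = boundary_spec()) {
  vol <- assemble_volume(mesh, registry)
  rob <- assemble_robin(mesh, bc)
  A <- vol$K + vol$P + rob$R
  rhs <- vol$F + rob$Fr
  n <- nrow(mesh$nodes)
  dnod <- dirichlet_nodes(mesh)
  if (length(dnod) == 0L && bc$gamma1$h == 0 &&
      all(Matrix::rowSums(vol$P) == 0)) {
    stop("solver error: no Dirichlet, Robin or perfusion term anywhere; ",
         "the steady system is singular")
  }
  T <- numeric(n)
  if (length(dnod)) {
    free <- setdiff(seq_len(n), dnod)
    Td <- rep(bc$gamma3$Tp, length(dnod))
    Aff <- Matrix::forceSymmetric(A[free, free, drop = FALSE])
    bf <- rhs[free] - as.numeric(A[free, dnod, drop = FALSE] %*% Td)
    T[dnod] <- Td
    T[free] <- as.numeric(Matrix::solve(Aff, bf))
  } else {
    T <- as.numeric(Matrix::solve(Matrix::forceSymmetric(A), rhs))
  }
  res <- as.numeric(A %*% T) - rhs
  if (length(dnod)) res[dnod] <- 0
  scale <- max(sqrt(sum(rhs^2)), sqrt(sum(T^2)), 1)
  rel <- sqrt(sum(res^2)) / scale
  if (rel > 1e-10) {
    stop(sprintf("solver error: relative residual %.3g exceeds 1e-10", rel))
  }
  temperature_field(mesh, T, time = NULL)
}

#' Solve the transient bioheat problem
#'
#' Implicit theta-scheme time integration (backward Euler by default) from a
#' given initial field, returning sampled fields at t = 0, sample_every, ...,
#' duration. The first returned field is the initial condition itself.
#'
#' @param mesh,registry,bc As in \code{\link{solve_steady}}.
#' @param T0 Initial \code{temperature_field} on the same mesh.
#' @param duration Total simulated time, s.
#' @param dt Time step, s.
#' @param sample_every Sampling interval, s; must be an integer multiple of
#'   \code{dt}, and \code{duration} a multiple of \code{sample_every}.
#' @param theta Implicitness parameter in (0, 1]; 1 is backward Euler.
#' @return List of \code{temperature_field}s with \code{time} tags.
#' @export
solve_transient <- function(mesh, registry, bc, T0, duration, dt = 1,
                            sample_every = 15, theta = 1) {
  stopifnot(inherits(T0, "temperature_field"))
  if (dt <= 0) stop("configuration error: dt must be positive")
  if (abs(sample_every / dt - round(sample_every / dt)) > 1e-9) {
    stop("configuration error: sample_every must be a multiple of dt")
  }
  if (abs(duration / sample_every - round(duration / sample_every)) > 1e-9) {
    stop("configuration error: duration must be a multiple of sample_every")
  }
  if (!identical(nrow(T0$mesh$nodes), nrow(mesh$nodes))) {
    stop("configuration error: T0 is not defined on the given mesh")
  }
  vol <- assemble_volume(mesh, registry)
  rob <- assemble_robin(mesh, bc)
  A <- vol$K + vol$P + rob$R
  Fv <- vol$F + rob$Fr
  n <- nrow(mesh$nodes)
  dnod <- dirichlet_nodes(mesh)
  free <- setdiff(seq_len(n), dnod)
  Td <- rep(bc$gamma3$Tp, length(dnod))

  LHS <- vol$M / dt + theta * A
  RHSm <- vol$M / dt - (1 - theta) * A
  LHSff <- Matrix::forceSymmetric(LHS[free, free, drop = FALSE])
  LHSfd <- LHS[free, dnod, drop = FALSE]
  RHSff <- RHSm[free, , drop = FALSE]
  ch <- Matrix::Cholesky(LHSff, LDL = FALSE)

  nstep <- as.integer(round(duration / dt))
  per_sample <- as.integer(round(sample_every / dt))
  T <- T0$values
  if (length(dnod)) T[dnod] <- Td
  out <- vector("list", nstep %/% per_sample + 1L)
  out[[1L]] <- temperature_field(mesh, T, time = 0)
  k <- 1L
  lhs_d <- if (length(dnod)) as.numeric(LHSfd %*% Td) else 0
  for (s in seq_len(nstep)) {
    b <- as.numeric(RHSff %*% T) + Fv[free] - lhs_d
    T[free] <- as.numeric(Matrix::solve(ch, b, system = "A"))
    if (length(dnod)) T[dnod] <- Td
    if (s %% per_sample == 0L) {
      k <- k + 1L
      out[[k]] <- temperature_field(mesh, T, time = s * dt)
    }
  }
  out
}

#' Nodal temperature field on a mesh
#'
#' @param mesh The mesh the values live on.
#' @param values Nodal temperatures, degC.
#' @param time Optional time tag, s (absent/NULL for steady fields).
#' @return Object of class \code{temperature_field}.
#' @export
temperature_field <- function(mesh, values, time = NULL) {
  stopifnot(length(values) == nrow(mesh$nodes), all(is.finite(values)))
  structure(list(mesh = mesh, values = as.numeric(values), time = time),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("Temperature field%s: %d nodes, range %.3f .. %.3f degC\n",
              if (!is.null(x$time)) sprintf(" (t = %g s)", x$time) else
                " (steady)",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# grid-bucket point locator, cached on the mesh's environment
mesh_locator <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache) && !is.null(cache$locator)) return(cache$locator)
  P <- mesh$nodes
  tri <- mesh$elements
  cell <- max(2.5 * mesh$h_target,
              sqrt(4 * max(tri_signed_areas(P, tri))))
  x0 <- min(P[, 1]); y0 <- min(P[, 2])
  nxc <- max(1L, as.integer(ceiling((max(P[, 1]) - x0) / cell)))
  nyc <- max(1L, as.integer(ceiling((max(P[, 2]) - y0) / cell)))
  tx1 <- pmin(P[tri[, 1], 1], P[tri[, 2], 1], P[tri[, 3], 1])
  tx2 <- pmax(P[tri[, 1], 1], P[tri[, 2], 1], P[tri[, 3], 1])
  ty1 <- pmin(P[tri[, 1], 2], P[tri[, 2], 2], P[tri[, 3], 2])
  ty2 <- pmax(P[tri[, 1], 2], P[tri[, 2], 2], P[tri[, 3], 2])
  cx1 <- pmax(1L, pmin(nxc, as.integer(floor((tx1 - x0) / cell)) + 1L))
  cx2 <- pmax(1L, pmin(nxc, as.integer(floor((tx2 - x0) / cell)) + 1L))
  cy1 <- pmax(1L, pmin(nyc, as.integer(floor((ty1 - y0) / cell)) + 1L))
  cy2 <- pmax(1L, pmin(nyc, as.integer(floor((ty2 - y0) / cell)) + 1L))
  buckets <- vector("list", nxc * nyc)
  for (t in seq_len(nrow(tri))) {
    for (cx in cx1[t]:cx2[t]) {
      for (cy in cy1[t]:cy2[t]) {
        id <- (cy - 1L) * nxc + cx
        buckets[[id]] <- c(buckets[[id]], t)
      }
    }
  }
  loc <- list(cell = cell, x0 = x0, y0 = y0, nxc = nxc, nyc = nyc,
              buckets = buckets)
  if (!is.null(cache)) cache$locator <- loc
  loc
}

# barycentric coordinates of points within given triangles
barycentric <- function(P, tri, t_id, pts) {
  p1 <- P[tri[t_id, 1], , drop = FALSE]
  p2 <- P[tri[t_id, 2], , drop = FALSE]
  p3 <- P[tri[t_id, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  l1 <- ((p2[, 1] - pts[, 1]) * (p3[, 2] - pts[, 2]) -
           (p2[, 2] - pts[, 2]) * (p3[, 1] - pts[, 1])) / det
  l2 <- ((p3[, 1] - pts[, 1]) * (p1[, 2] - pts[, 2]) -
           (p3[, 2] - pts[, 2]) * (p1[, 1] - pts[, 1])) / det
  cbind(l1, l2, 1 - l1 - l2)
}

#' Evaluate a temperature field at arbitrary points
#'
#' Piecewise-linear (barycentric) interpolation within the containing
#' triangle. Points on the curved outer boundary, which the mesh represents
#' by chords, are accepted within a small chordal tolerance and clamped onto
#' the nearest element; genuinely exterior points raise an error.
#'
#' @param field A \code{temperature_field}.
#' @param p Length-2 point or n x 2 matrix, m.
#' @return Numeric vector of temperatures, degC.
#' @export
evaluate_field <- function(field, p) {
  mesh <- field$mesh
  pts <- matrix(p, ncol = 2)
  loc <- mesh_locator(mesh)
  tri <- mesh$elements
  P <- mesh$nodes
  cx <- pmax(1L, pmin(loc$nxc,
                      as.integer(floor((pts[, 1] - loc$x0) / loc$cell)) + 1L))
  cy <- pmax(1L, pmin(loc$nyc,
                      as.integer(floor((pts[, 2] - loc$y0) / loc$cell)) + 1L))
  out <- numeric(nrow(pts))
  slack <- 0.05  # barycentric tolerance for chord-approximated boundaries
  for (q in seq_len(nrow(pts))) {
    best_t <- NA_integer_
    best_l <- NULL
    best_min <- -Inf
    for (dx in 0:2) {
      for (dyy in 0:2) {
        ccx <- cx[q] + c(0, -1, 1)[dx + 1]
        ccy <- cy[q] + c(0, -1, 1)[dyy + 1]
        if (ccx < 1 || ccx > loc$nxc || ccy < 1 || ccy > loc$nyc) next
        cand <- loc$buckets[[(ccy - 1L) * loc$nxc + ccx]]
        if (is.null(cand)) next
        lam <- barycentric(P, tri, cand, pts[rep(q, length(cand)), ,
                                             drop = FALSE])
        mn <- pmin(lam[, 1], lam[, 2], lam[, 3])
        i <- which.max(mn)
        if (mn[i] > best_min) {
          best_min <- mn[i]
          best_t <- cand[i]
          best_l <- lam[i, ]
        }
      }
      if (best_min >= 0) break
    }
    if (is.na(best_t) || best_min < -slack) {
      stop(sprintf("evaluation error: point (%.5f, %.5f) is outside the meshed domain",
                   pts[q, 1], pts[q, 2]))
    }
    l <- pmax(best_l, 0)
    l <- l / sum(l)
    out[q] <- sum(field$values[tri[best_t, ]] * l)
  }
  out
}

#' Export a field as node-value CSV or gridded raster CSV
#'
#' \code{write_field_csv} writes one row per mesh node (x, y, T).
#' \code{write_field_raster} samples the field on a regular grid (NA outside
#' the domain) for image-style visualization.
#'
#' @param field A \code{temperature_field}.
#' @param path Output path.
#' @param nx,ny Raster resolution.
#' @return \code{path}, invisibly.
#' @export
write_field_csv <- function(field, path) {
  utils::write.csv(data.frame(x = field$mesh$nodes[, 1],
                              y = field$mesh$nodes[, 2],
                              T = field$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
write_field_raster <- function(field, path, nx = 200, ny = 200) {
  P <- field$mesh$nodes
  xs <- seq(min(P[, 1]), max(P[, 1]), length.out = nx)
  ys <- seq(min(P[, 2]), max(P[, 2]), length.out = ny)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  vals <- rep(NA_real_, nrow(grid))
  geom <- field$mesh$geom
  inside <- if (!is.null(geom)) {
    !(classify_point(geom, grid) %in% c("outside", "trachea"))
  } else rep(TRUE, nrow(grid))
  ok <- which(inside)
  for (i in ok) {
    vals[i] <- tryCatch(evaluate_field(field, grid[i, , drop = FALSE]),
                        error = function(e) NA_real_)
  }
  m <- matrix(vals, nrow = ny, byrow = TRUE)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
plot.temperature_field <- function(x, n = 200, ...) {
  P <- x$mesh$nodes
  xs <- seq(min(P[, 1]), max(P[, 1]), length.out = n)
  ys <- seq(min(P[, 2]), max(P[, 2]), length.out = n)
  z <- matrix(NA_real_, n, n)
  geom <- x$mesh$geom
  for (j in seq_len(n)) {
    pts <- cbind(xs, ys[j])
    ok <- if (!is.null(geom)) {
      !(classify_point(geom, pts) %in% c("outside", "trachea"))
    } else rep(TRUE, n)
    for (i in which(ok)) {
      z[i, j] <- tryCatch(evaluate_field(x, pts[i, , drop = FALSE]),
                          error = function(e) NA_real_)
    }
  }
  graphics::image(xs, ys, z, asp = 1, xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
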