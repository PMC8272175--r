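# Unstructured conforming triangulation of the neck cross-section.
#
# Strategy: all tissue interface curves (layer circles, trachea, lobe and
# nodule ellipses) are sampled at a spacing no coarser than the target edge
# length; interior filler points are laid on a hexagonal lattice and culled
# near the curves; the Delaunay triangulation of the combined cloud then
# conforms to the interfaces. Elements are tagged by centroid classification,
# triangles falling outside the neck or inside the tracheal hole are dropped,
# and free (filler) nodes are Laplacian-smoothed for element quality.

even_ceil <- function(x) 2L * as.integer(ceiling(x / 2))

circle_points <- function(center, r, spacing) {
  n <- max(16L, even_ceil(2 * pi * r / spacing))
  a <- 2 * pi * (seq_len(n) - 1L) / n
  list(pts = cbind(center[1] + r * cos(a), center[2] + r * sin(a)),
       spacing = 2 * pi * r / n)
}

ellipse_points <- function(e, spacing) {
  # near-uniform arclength sampling
  fine <- ellipse_boundary(e, 2048L)
  seg <- sqrt(rowSums((fine - fine[c(2:nrow(fine), 1), ])^2))
  L <- sum(seg)
  n <- max(16L, as.integer(ceiling(L / spacing)))
  s <- cumsum(c(0, seg[-length(seg)]))
  want <- L * (seq_len(n) - 1L) / n
  idx <- findInterval(want, s)
  list(pts = fine[idx, , drop = FALSE], spacing = L / n)
}

# squared-distance cull of `cand` against reference points with radii `rad`
cull_near <- function(cand, ref, rad) {
  if (is.null(ref) || nrow(ref) == 0L || nrow(cand) == 0L) {
    return(rep(TRUE, if (is.null(cand)) 0L else nrow(cand)))
  }
  keep <- rep(TRUE, nrow(cand))
  chunk <- 2000L
  for (i0 in seq(1L, nrow(ref), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(ref))
    d2 <- outer(cand[, 1], ref[ii, 1], "-")^2 +
          outer(cand[, 2], ref[ii, 2], "-")^2
    hit <- d2 <= matrix(rad[ii]^2, nrow(cand), length(ii), byrow = TRUE)
    keep <- keep & !rowSums(hit)
  }
  keep
}

#' Generate a conforming triangular mesh of a neck geometry
#'
#' Produces an unstructured triangulation whose element edges resolve all
#' tissue interfaces, with per-element region tags and boundary edges tagged
#' \code{GAMMA1} (anterior skin arc, convective), \code{GAMMA2} (trachea
#' wall, insulated) or \code{GAMMA3} (posterior arc, prescribed temperature).
#'
#' @param geom A \code{\link{neck_geometry}}.
#' @param h_target Target element edge length, m.
#' @param smooth_iter Laplacian smoothing sweeps applied to interior nodes.
#' @param symmetric If \code{TRUE}, build an exactly mirror-symmetric mesh:
#'   the left half-plane is meshed (with nodes pinned on the sagittal axis)
#'   and reflected. The nodule interface is omitted — the nodule is treated
#'   as thyroid tissue — because only then is the continuous geometry itself
#'   mirror-symmetric. Intended for symmetry validation of the solver.
#' @return An object of class \code{bioheat_mesh} with fields \code{nodes}
#'   (n x 2, m), \code{elements} (m x 3 node indices, counter-clockwise),
#'   \code{element_region} (tissue label per element), \code{boundary_edges}
#'   (data frame \code{a}, \code{b}, \code{tag}), \code{h_target},
#'   \code{geom}, and quality metadata.
#' @examples
#' \donttest{
#' mesh <- generate_mesh(neck_geometry(), h_target = 0.003)
#' summary(mesh)
#' }
#' @export
generate_mesh <- function(geom, h_target = 0.001, smooth_iter = 4L,
                          symmetric = FALSE) {
  stopifnot(inherits(geom, "neck_geometry"), h_target > 0)
  R <- geom$outer_radius
  h <- h_target
  skin_inner <- R - geom$skin_thickness
  fat_inner <- skin_inner - geom$fat_thickness

  pts_list <- list()
  spc_list <- list()
  add <- function(p) {
    # drop new points that collide with already-kept ones
    keep <- cull_near(p$pts, do.call(rbind, pts_list),
                      0.45 * unlist(spc_list))
    pts_list[[length(pts_list) + 1L]] <<- p$pts[keep, , drop = FALSE]
    spc_list[[length(spc_list) + 1L]] <<- rep(p$spacing, sum(keep))
  }

  thin_cap <- 2.2 * geom$skin_thickness
  add(circle_points(c(0, 0), R, min(h, thin_cap)))
  add(circle_points(c(0, 0), skin_inner, min(h, thin_cap)))
  if (geom$fat_thickness > 0) {
    add(circle_points(c(0, 0), fat_inner,
                      min(h, 2.2 * geom$fat_thickness)))
  }
  add(circle_points(geom$trachea$center, geom$trachea$radius, h))

  ell_spacing <- min(h, 0.0025)
  if (!symmetric) {
    add(ellipse_points(geom$nodule, ell_spacing))
  }
  for (nm in c("left", "right")) {
    lp <- ellipse_points(geom$lobes[[nm]], ell_spacing)
    other <- if (nm == "left") geom$lobes$right else geom$lobes$left
    drop <- ellipse_level(other, lp$pts) < 1 - 1e-9
    if (!symmetric) {
      drop <- drop | ellipse_level(geom$nodule, lp$pts) < 1 - 1e-9
    }
    lp$pts <- lp$pts[!drop, , drop = FALSE]
    add(lp)
  }
  if (symmetric) {
    # sagittal-axis points: the half-mesh boundary that will be reflected
    tc <- geom$trachea$center[2]
    tr <- geom$trachea$radius
    seg <- function(y0, y1) {
      n <- max(2L, as.integer(ceiling((y1 - y0) / h)) + 1L)
      cbind(0, seq(y0, y1, length.out = n))
    }
    axis_pts <- rbind(seg(-R + 0.55 * h, tc - tr - 0.3 * h),
                      seg(tc + tr + 0.3 * h, R - 0.55 * h))
    add(list(pts = axis_pts, spacing = h))
  }

  curve_pts <- do.call(rbind, pts_list)
  curve_spc <- unlist(spc_list)

  # free intermediate rings inside a fat layer thicker than the target edge
  # length: the hexagonal lattice alone leaves badly-shaped transition bands
  # between the differently-spaced layer rings
  ring_filler <- NULL
  if (geom$fat_thickness > 0) {
    nr <- ceiling(geom$fat_thickness / h)
    if (nr >= 2L) {
      step <- geom$fat_thickness / nr
      for (k in seq_len(nr - 1L)) {
        cp <- circle_points(c(0, 0), skin_inner - k * step,
                            min(h, 2.5 * step))
        ring_filler <- rbind(ring_filler, cp$pts)
      }
      ring_filler <- ring_filler[cull_near(ring_filler, curve_pts,
                                           0.55 * curve_spc), , drop = FALSE]
    }
  }

  # hexagonal filler lattice over the disc
  dy <- h * sqrt(3) / 2
  ys <- seq(-R, R, by = dy)
  filler <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) h / 2 else 0
    xs <- seq(-R - off, R, by = h) + off
    cbind(xs, ys[i])
  }))
  r2 <- rowSums(filler^2)
  dtr <- sqrt((filler[, 1] - geom$trachea$center[1])^2 +
              (filler[, 2] - geom$trachea$center[2])^2)
  filler <- filler[r2 < (R - 0.4 * h)^2 &
                     dtr > geom$trachea$radius + 0.4 * h, , drop = FALSE]
  filler <- filler[cull_near(filler, curve_pts,
                             pmax(0.62 * curve_spc, 0.5 * h)), , drop = FALSE]
  if (!is.null(ring_filler)) {
    filler <- filler[cull_near(filler, ring_filler,
                               rep(0.7 * h, nrow(ring_filler))), ,
                     drop = FALSE]
    filler <- rbind(ring_filler, filler)
  }

  if (symmetric) {
    on_axis <- abs(curve_pts[, 1]) < 0.3 * h
    curve_pts[on_axis, 1] <- 0
    keep_c <- curve_pts[, 1] <= 0
    curve_pts <- curve_pts[keep_c, , drop = FALSE]
    on_axis <- on_axis[keep_c]
    filler <- filler[filler[, 1] < -0.45 * h, , drop = FALSE]
  }
  nodes <- rbind(curve_pts, filler)
  n_curve <- nrow(curve_pts)

  # deterministic symbolic jitter to break cocircular degeneracies
  jit <- 1e-6 * h
  ang <- sin(1e4 * seq_len(nrow(nodes)) + 0.7)
  nodes_j <- nodes + jit * cbind(cos(73 * ang), sin(151 * ang))
  if (symmetric) {
    # axis nodes stay exactly on the axis (jitter along it only)
    nodes_j[which(on_axis), 1] <- 0
  }

  tri <- .delaunay_cpp(nodes_j)

  # orient CCW, drop slivers and triangles outside the domain
  a1 <- nodes_j[tri[, 1], ]; a2 <- nodes_j[tri[, 2], ]; a3 <- nodes_j[tri[, 3], ]
  s2 <- (a2[, 1] - a1[, 1]) * (a3[, 2] - a1[, 2]) -
        (a2[, 2] - a1[, 2]) * (a3[, 1] - a1[, 1])
  flip <- s2 < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  area <- abs(s2) / 2
  cent <- (a1 + a2 + a3) / 3
  lab <- classify_point(geom, cent)
  keep <- area > 1e-4 * h^2 & !(lab %in% c("outside", "trachea"))
  if (symmetric) keep <- keep & cent[, 1] < 0
  tri <- tri[keep, , drop = FALSE]
  lab <- lab[keep]

  # drop unused nodes, re-index
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(nodes_j)); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3)
  nodes_j <- nodes_j[used, , drop = FALSE]
  free <- used > n_curve  # filler nodes are free to move

  mesh <- structure(list(nodes = nodes_j, elements = tri,
                         element_region = lab, h_target = h,
                         n_curve = sum(!free), free_node = free,
                         geom = geom, cache = new.env(parent = emptyenv())),
                    class = "bioheat_mesh")
  mesh <- smooth_mesh(mesh, smooth_iter)
  if (symmetric) mesh <- reflect_half_mesh(mesh)
  mesh$boundary_edges <- tag_boundary_edges(mesh)
  q <- mesh_quality(mesh)
  mesh$min_angle <- q$min_angle
  mesh
}

# reflect a left-half mesh across the sagittal axis into a whole-domain
# mesh that is exactly mirror-symmetric (axis nodes shared)
reflect_half_mesh <- function(mesh) {
  P <- mesh$nodes
  tri <- mesh$elements
  on_axis <- P[, 1] == 0
  nn <- nrow(P)
  map <- integer(nn)           # node -> index of its mirror
  map[on_axis] <- which(on_axis)
  map[!on_axis] <- nn + seq_len(sum(!on_axis))
  P2 <- P[!on_axis, , drop = FALSE]
  P2[, 1] <- -P2[, 1]
  tri2 <- cbind(map[tri[, 1]], map[tri[, 3]], map[tri[, 2]])  # re-orient
  lab2 <- mesh$element_region
  lab2[lab2 == "nodule"] <- "thyroid"
  lab_m <- lab2  # all remaining labels are mirror-invariant
  mesh$nodes <- rbind(P, P2)
  mesh$elements <- rbind(tri, tri2)
  mesh$element_region <- c(lab2, lab_m)
  mesh$free_node <- c(mesh$free_node, mesh$free_node[!on_axis])
  mesh$n_curve <- sum(!mesh$free_node)
  mesh$cache <- new.env(parent = emptyenv())
  mesh
}

# Laplacian smoothing of free nodes with inverted-element rollback
smooth_mesh <- function(mesh, iters) {
  if (iters <= 0L) return(mesh)
  tri <- mesh$elements
  nn <- nrow(mesh$nodes)
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  ed <- rbind(ed, ed[, 2:1])
  adj <- Matrix::sparseMatrix(i = ed[, 1], j = ed[, 2], x = 1,
                              dims = c(nn, nn))
  adj@x[] <- 1  # dedupe duplicated edges
  deg <- Matrix::rowSums(adj)
  free <- mesh$free_node
  P <- mesh$nodes
  for (it in seq_len(iters)) {
    Pnew <- as.matrix(adj %*% P) / deg
    Pnew[!free, ] <- P[!free, ]
    s <- tri_signed_areas(Pnew, tri)
    if (any(s <= 0)) {
      bad <- unique(as.vector(tri[s <= 0, ]))
      Pnew[bad, ] <- P[bad, ]
      s <- tri_signed_areas(Pnew, tri)
      if (any(s <= 0)) break  # keep previous coordinates
    }
    P <- Pnew
  }
  mesh$nodes <- P
  mesh
}

tri_signed_areas <- function(P, tri) {
  a1 <- P[tri[, 1], , drop = FALSE]
  a2 <- P[tri[, 2], , drop = FALSE]
  a3 <- P[tri[, 3], , drop = FALSE]
  ((a2[, 1] - a1[, 1]) * (a3[, 2] - a1[, 2]) -
     (a2[, 2] - a1[, 2]) * (a3[, 1] - a1[, 1])) / 2
}

tag_boundary_edges <- function(mesh) {
  tri <- mesh$elements
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  bed <- ed[key %in% bkey, , drop = FALSE]
  geom <- mesh$geom
  P <- mesh$nodes
  mid <- (P[bed[, 1], , drop = FALSE] + P[bed[, 2], , drop = FALSE]) / 2
  r <- sqrt(rowSums(mid^2))
  dtr <- sqrt((mid[, 1] - geom$trachea$center[1])^2 +
              (mid[, 2] - geom$trachea$center[2])^2)
  tol <- 0.55 * mesh$h_target
  tag <- rep(NA_character_, nrow(bed))
  on_outer <- abs(r - geom$outer_radius) < tol
  tag[on_outer & mid[, 2] > 0] <- "GAMMA1"
  tag[on_outer & mid[, 2] <= 0] <- "GAMMA3"
  tag[abs(dtr - geom$trachea$radius) < tol] <- "GAMMA2"
  if (anyNA(tag)) {
    stop("meshing error: ", sum(is.na(tag)), " untagged boundary edges")
  }
  data.frame(a = bed[, 1], b = bed[, 2], tag = tag,
             stringsAsFactors = FALSE)
}

#' Mesh quality and consistency metrics
#'
#' @param mesh A \code{\link{generate_mesh}} result.
#' @return List with \code{min_angle} (degrees), \code{angles} summary,
#'   \code{n_nodes}, \code{n_elements}, \code{total_area} (m^2) and
#'   \code{interface_violations} (edges separating two tissue regions whose
#'   endpoints are not interface-curve nodes).
#' @export
mesh_quality <- function(mesh) {
  P <- mesh$nodes
  tri <- mesh$elements
  ang <- tri_angles(P, tri)
  # interface conformity: region-separating interior edges must join
  # curve-sampled nodes (indices <= n_curve by construction)
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  eid <- rep(seq_len(nrow(tri)), 3L)
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  o <- order(key)
  key <- key[o]; eid <- eid[o]; ed <- ed[o, , drop = FALSE]
  dup <- key[-1] == key[-length(key)]
  i1 <- which(c(dup, FALSE)); i2 <- i1 + 1L
  reg <- mesh$element_region
  differ <- reg[eid[i1]] != reg[eid[i2]]
  is_curve <- !mesh$free_node
  bad <- differ & !(is_curve[ed[i1, 1]] & is_curve[ed[i1, 2]])
  list(min_angle = min(ang), angles = summary(as.vector(ang)),
       n_nodes = nrow(P), n_elements = nrow(tri),
       total_area = sum(tri_signed_areas(P, tri)),
       interface_violations = sum(bad))
}

tri_angles <- function(P, tri) {
  a <- P[tri[, 1], , drop = FALSE]
  b <- P[tri[, 2], , drop = FALSE]
  c <- P[tri[, 3], , drop = FALSE]
  l1 <- sqrt(rowSums((b - c)^2))  # opposite a
  l2 <- sqrt(rowSums((a - c)^2))
  l3 <- sqrt(rowSums((a - b)^2))
  ang <- cbind(acos(pmin(1, pmax(-1, (l2^2 + l3^2 - l1^2) / (2 * l2 * l3)))),
               acos(pmin(1, pmax(-1, (l1^2 + l3^2 - l2^2) / (2 * l1 * l3)))),
               acos(pmin(1, pmax(-1, (l1^2 + l2^2 - l3^2) / (2 * l1 * l2)))))
  ang * 180 / pi
}

#' @export
print.bioheat_mesh <- function(x, ...) {
  cat(sprintf(
    "Triangular mesh: %d nodes, %d elements (h_target %.2f mm, min angle %.1f deg)\n",
    nrow(x$nodes), nrow(x$elements), 1000 * x$h_target, x$min_angle))
  cat("  regions:", paste(sprintf("%s %d", names(table(x$element_region)),
                                  table(x$element_region)), collapse = ", "),
      "\n")
  cat("  boundary edges:",
      paste(sprintf("%s %d", names(table(x$boundary_edges$tag)),
                    table(x$boundary_edges$tag)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bioheat_mesh <- function(object, ...) {
  q <- mesh_quality(object)
  print(object)
  cat(sprintf("  total area %.6f m^2, interface violations %d\n",
              q$total_area, q$interface_violations))
  invisible(q)
}

#' @export
plot.bioheat_mesh <- function(x, ...) {
  cols <- c(skin = "#f2c9a0", fat = "#f7e9a0", muscle = "#d98f8f",
            thyroid = "#a0c8f2", nodule = "#d06060")
  P <- x$nodes
  graphics::plot(NA, xlim = range(P[, 1]), ylim = range(P[, 2]), asp = 1,
                 xlab = "x (m)", ylab = "y (m)", main = "Mesh regions", ...)
  for (rg in names(cols)) {
    idx <- which(x$element_region == rg)
    if (!length(idx)) next
    for (i in idx) {
      graphics::polygon(P[x$elements[i, ], 1], P[x$elements[i, ], 2],
                        col = cols[rg], border = NA)
    }
  }
  invisible(x)
}

#' Rectangular strip mesh (validation geometry)
#'
#' Structured right-triangle mesh of a single-tissue rectangle, used to
#' validate the solver against the closed-form one-dimensional bioheat slab
#' solution. Boundary tags: \code{GAMMA3} (prescribed temperature) at x = 0,
#' \code{GAMMA1} (convective) at x = L, insulated (\code{GAMMA2}) lateral
#' sides.
#'
#' @param length_x Slab thickness, m (the 1D direction).
#' @param width_y Lateral extent, m.
#' @param h Element size, m.
#' @param tissue Region label for all elements.
#' @return A \code{bioheat_mesh} (with a \code{NULL} geometry reference).
#' @export
strip_mesh <- function(length_x, width_y, h, tissue = "muscle") {
  nx <- max(2L, as.integer(round(length_x / h)) + 1L)
  ny <- max(2L, as.integer(round(width_y / h)) + 1L)
  xs <- seq(0, length_x, length.out = nx)
  ys <- seq(0, width_y, length.out = ny)
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  id <- function(i, j) (j - 1L) * nx + i
  tri <- matrix(0L, 2L * (nx - 1L) * (ny - 1L), 3L)
  k <- 0L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      tri[k + 1L, ] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
      tri[k + 2L, ] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
      k <- k + 2L
    }
  }
  be <- rbind(
    data.frame(a = id(1L, seq_len(ny - 1L)), b = id(1L, seq_len(ny - 1L) + 1L),
               tag = "GAMMA3"),
    data.frame(a = id(nx, seq_len(ny - 1L)), b = id(nx, seq_len(ny - 1L) + 1L),
               tag = "GAMMA1"),
    data.frame(a = id(seq_len(nx - 1L), 1L), b = id(seq_len(nx - 1L) + 1L, 1L),
               tag = "GAMMA2"),
    data.frame(a = id(seq_len(nx - 1L), ny), b = id(seq_len(nx - 1L) + 1L, ny),
               tag = "GAMMA2"))
  structure(list(nodes = nodes, elements = tri,
                 element_region = rep(tissue, nrow(tri)),
                 boundary_edges = be, h_target = h,
                 n_curve = nrow(nodes),
                 free_node = rep(FALSE, nrow(nodes)), geom = NULL,
                 cache = new.env(parent = emptyenv()), min_angle = 45),
            class = "bioheat_mesh")
}

#' Mesh self-convergence report at a probe point
#'
#' Solves the steady problem on a sequence of meshes of decreasing target
#' edge length and reports the front-of-nodule skin temperature and its
#' change between consecutive refinements; shrinking deltas indicate mesh
#' convergence.
#'
#' @param geom A \code{\link{neck_geometry}}.
#' @param h_list Mesh sizes, m, sorted descending, at least two.
#' @param registry Tissue registry (default per-minute gland preset).
#' @param bc Boundary specification (default \code{\link{boundary_spec}()}).
#' @return Data frame with columns \code{h}, \code{probe_T}, \code{delta}.
#' @export
convergence_report <- function(geom, h_list,
                               registry = tissue_registry("per_minute_gland"),
                               bc = boundary_spec()) {
  stopifnot(length(h_list) >= 2L)
  if (is.unsorted(rev(h_list))) {
    stop("h_list must be sorted in descending order")
  }
  probe <- probe_points(geom)$front_of_nodule
  temps <- vapply(h_list, function(h) {
    mesh <- tryCatch(generate_mesh(geom, h),
                     error = function(e) stop("at h = ", h, ": ",
                                              conditionMessage(e)))
    fld <- solve_steady(mesh, registry, bc)
    evaluate_field(fld, probe)
  }, numeric(1))
  data.frame(h = h_list, probe_T = temps,
             delta = c(NA, diff(temps)))
}

#' Export a mesh as plain-text node/element tables or VTU
#'
#' \code{write_mesh} writes \code{<stem>_nodes.csv} (x, y) and
#' \code{<stem>_elements.csv} (n1, n2, n3, region). \code{write_mesh_vtu}
#' writes an unstructured-grid XML file for visualization tools.
#'
#' @param mesh A \code{bioheat_mesh}.
#' @param stem Output path stem (\code{write_mesh}) or file path
#'   (\code{write_mesh_vtu}).
#' @param values Optional per-node scalar (e.g. temperature) for the VTU.
#' @return Paths written, invisibly.
#' @export
write_mesh <- function(mesh, stem) {
  np <- paste0(stem, "_nodes.csv")
  ep <- paste0(stem, "_elements.csv")
  utils::write.csv(data.frame(x = mesh$nodes[, 1], y = mesh$nodes[, 2]),
                   np, row.names = FALSE)
  utils::write.csv(data.frame(n1 = mesh$elements[, 1],
                              n2 = mesh$elements[, 2],
                              n3 = mesh$elements[, 3],
                              region = mesh$element_region),
                   ep, row.names = FALSE)
  invisible(c(np, ep))
}

#' @rdname write_mesh
#' @export
write_mesh_vtu <- function(mesh, stem, values = NULL) {
  path <- if (grepl("\\.vtu$", stem)) stem else paste0(stem, ".vtu")
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', m, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(paste(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]),
          collapse = " "))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(t(mesh$elements - 1L), collapse = " "))
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(3L * seq_len(m), collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(5L, m), collapse = " "))
  w('</DataArray></Cells>')
  if (!is.null(values)) {
    w('<PointData Scalars="T"><DataArray type="Float64" Name="T" format="ascii">')
    w(paste(sprintf("%.9g", values), collapse = " "))
    w('</DataArray></PointData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
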