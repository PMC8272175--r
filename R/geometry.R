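# Parametric 2D neck cross-section.
#
# Coordinates: origin at the centre of the (circular) neck section, the
# sagittal axis is x = 0, anterior is +y. The patient's left -- the nodule
# side -- is x < 0, and arc coordinates along the skin are negative on that
# side. Layers are concentric annuli: skin (1 mm), fat (variable), muscle
# (1 cm). The thyroid lobes and the nodule are ellipses whose major axes are
# tangential (perpendicular to the radial through their centres); the trachea
# is a circular hole with an insulated wall.

#' Build the parametric neck geometry
#'
#' Constructs the simplified neck cross-section: concentric skin, fat and
#' muscle layers inside a circle of perimeter 36 cm, two mirrored elliptic
#' thyroid lobes, an elliptic nodule inside the left lobe, and a circular
#' tracheal hole on the sagittal axis. The nodule centre lies on the radial
#' ray 30 degrees to the patient's left of the anterior midline, so the skin
#' point in front of the nodule sits at arc coordinate -3.0 cm. The nodule is
#' concentric with its host lobe, whose position is anchored so the large
#' nodule's outer radial edge lies directly beneath the tissue stack, at
#' depth skin + fat + muscle below the surface: a thicker subcutaneous fat
#' layer pushes the gland correspondingly deeper, and smaller nodule presets
#' sit deeper within the (fixed-size) lobe.
#'
#' @param fat_thickness Fat layer thickness, m (0 gives an empty fat region).
#' @param nodule_semi_axes Length-2 numeric, nodule semi-axes in m
#'   (tangential, radial), or a preset label for \code{\link{nodule_semi_axes}}.
#' @param outer_radius Neck radius, m. Default 0.36/(2*pi) (36 cm perimeter).
#' @param skin_thickness,muscle_thickness Layer thicknesses, m.
#' @param nodule_angle Polar angle of the nodule-centre radial, radians left
#'   of the anterior midline.
#' @param lobe_semi_axes Thyroid lobe semi-axes (tangential, radial), m. The
#'   default wraps the large nodule preset with a 1.5 mm shell.
#' @param lobe_outer_depth Depth of the lobe's outer radial edge, m.
#' @param trachea_center,trachea_radius Trachea circle (centre y on the
#'   sagittal axis), m.
#' @return An object of class \code{neck_geometry}.
#' @examples
#' geom <- neck_geometry(fat_thickness = 0.006)
#' classify_point(geom, rbind(geom$nodule$center, c(0, 0)))
#' @export
neck_geometry <- function(fat_thickness = 0.006,
                          nodule_semi_axes = "large",
                          outer_radius = 0.36 / (2 * pi),
                          skin_thickness = 0.001,
                          muscle_thickness = 0.01,
                          nodule_angle = pi / 6,
                          lobe_semi_axes = c(0.0314, 0.0180) + 0.0015,
                          lobe_outer_depth = skin_thickness + fat_thickness +
                            muscle_thickness - 0.0015,
                          trachea_center = c(0, -0.021),
                          trachea_radius = 0.012) {
  stopifnot(fat_thickness >= 0, outer_radius > 0, skin_thickness > 0,
            muscle_thickness > 0, trachea_radius > 0)
  if (is.character(nodule_semi_axes)) {
    nodule_semi_axes <- nodule_semi_axes(nodule_semi_axes)
  }
  stopifnot(length(nodule_semi_axes) == 2L, all(nodule_semi_axes > 0))

  R <- outer_radius
  th <- nodule_angle
  u <- c(-sin(th), cos(th))          # radial unit vector, nodule side
  tg <- c(-cos(th), -sin(th))        # tangential unit vector (major axis)

  lob_b <- lobe_semi_axes[2]
  lobe_center <- (R - lobe_outer_depth - lob_b) * u
  lobe_left <- list(center = lobe_center, a = lobe_semi_axes[1], b = lob_b,
                    axis = tg)
  # nodule concentric with its host lobe; smaller presets sit deeper
  nodule <- list(center = lobe_center, a = nodule_semi_axes[1],
                 b = nodule_semi_axes[2], axis = tg)
  lobe_right <- mirror_ellipse(lobe_left)

  geom <- structure(list(
    outer_radius = R,
    skin_thickness = skin_thickness,
    fat_thickness = fat_thickness,
    muscle_thickness = muscle_thickness,
    nodule_angle = th,
    nodule = nodule,
    lobes = list(left = lobe_left, right = lobe_right),
    trachea = list(center = c(trachea_center[1], trachea_center[2]),
                   radius = trachea_radius)
  ), class = "neck_geometry")

  validate_neck_geometry(geom)
  geom
}

mirror_ellipse <- function(e) {
  list(center = c(-e$center[1], e$center[2]), a = e$a, b = e$b,
       axis = c(-e$axis[1], e$axis[2]))
}

# signed "ellipse coordinate": <= 1 inside. p may be a matrix (n x 2).
ellipse_level <- function(e, p) {
  p <- matrix(p, ncol = 2)
  dx <- p[, 1] - e$center[1]
  dy <- p[, 2] - e$center[2]
  ex <- e$axis
  en <- c(-ex[2], ex[1])
  xp <- dx * ex[1] + dy * ex[2]
  yp <- dx * en[1] + dy * en[2]
  (xp / e$a)^2 + (yp / e$b)^2
}

ellipse_boundary <- function(e, n = 256L) {
  psi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ex <- e$axis
  en <- c(-ex[2], ex[1])
  cbind(e$center[1] + e$a * cos(psi) * ex[1] + e$b * sin(psi) * en[1],
        e$center[2] + e$a * cos(psi) * ex[2] + e$b * sin(psi) * en[2])
}

validate_neck_geometry <- function(geom) {
  R <- geom$outer_radius
  fat_inner <- R - geom$skin_thickness - geom$fat_thickness
  nb <- ellipse_boundary(geom$nodule, 512L)
  if (any(ellipse_level(geom$lobes$left, nb) > 1 + 1e-9)) {
    stop("geometry error: nodule is not contained inside the left lobe")
  }
  for (nm in c("left", "right")) {
    lb <- ellipse_boundary(geom$lobes[[nm]], 512L)
    rr <- sqrt(rowSums(lb^2))
    if (any(rr > fat_inner - 5e-4)) {
      stop(sprintf(paste0("geometry error: %s lobe reaches within 0.5 mm of ",
                          "the fat layer (max radius %.4f m, fat inner ",
                          "boundary %.4f m)"), nm, max(rr), fat_inner))
    }
    dtr <- sqrt((lb[, 1] - geom$trachea$center[1])^2 +
                (lb[, 2] - geom$trachea$center[2])^2)
    if (any(dtr < geom$trachea$radius + 1e-3)) {
      stop(sprintf("geometry error: %s lobe comes within 1 mm of the trachea",
                   nm))
    }
  }
  invisible(geom)
}

#' Classify points by tissue region
#'
#' Deterministic region membership for arbitrary points. Resolution order:
#' outside the neck, skin annulus, fat annulus, tracheal hole, nodule,
#' thyroid lobes, muscle (everything else). The innermost structure wins
#' where structures are nested (nodule over thyroid over muscle).
#'
#' @param geom A \code{\link{neck_geometry}}.
#' @param p Numeric length-2 point or an n x 2 matrix of points, m.
#' @return Character vector of labels: \code{"skin"}, \code{"fat"},
#'   \code{"muscle"}, \code{"thyroid"}, \code{"nodule"}, \code{"trachea"}
#'   (the hole) or \code{"outside"}.
#' @export
classify_point <- function(geom, p) {
  p <- matrix(p, ncol = 2)
  r <- sqrt(rowSums(p^2))
  R <- geom$outer_radius
  lab <- rep("muscle", nrow(p))
  lab[ellipse_level(geom$lobes$left, p) <= 1 |
        ellipse_level(geom$lobes$right, p) <= 1] <- "thyroid"
  lab[ellipse_level(geom$nodule, p) <= 1] <- "nodule"
  dtr <- sqrt((p[, 1] - geom$trachea$center[1])^2 +
              (p[, 2] - geom$trachea$center[2])^2)
  lab[dtr <= geom$trachea$radius] <- "trachea"
  fat_outer <- R - geom$skin_thickness
  if (geom$fat_thickness > 0) {
    lab[r > fat_outer - geom$fat_thickness & r <= fat_outer] <- "fat"
  }
  lab[r > fat_outer] <- "skin"
  lab[r > R] <- "outside"
  lab
}

#' Named probe points of a neck geometry
#'
#' The four reference points used by the analyses: the skin point on the
#' anterior surface radially in front of the nodule, its mirror across the
#' sagittal axis (contralateral point), the nodule centre, and the mirror of
#' the nodule centre inside the healthy lobe.
#'
#' @param geom A \code{\link{neck_geometry}}.
#' @return A list with entries \code{front_of_nodule}, \code{contralateral},
#'   \code{nodule_center}, \code{lobe_mirror} (each a length-2 numeric, m)
#'   and \code{front_arc} (arc coordinate of the front point, m, negative on
#'   the nodule side).
#' @export
probe_points <- function(geom) {
  th <- geom$nodule_angle
  R <- geom$outer_radius
  front <- R * c(-sin(th), cos(th))
  nod <- geom$nodule$center
  list(front_of_nodule = front,
       contralateral = c(-front[1], front[2]),
       nodule_center = nod,
       lobe_mirror = c(-nod[1], nod[2]),
       front_arc = -R * th)
}

#' Mirror a neck geometry across the sagittal axis
#'
#' Swaps the nodule to the contralateral lobe; used to express and test the
#' left/right symmetry of the model.
#'
#' @param geom A \code{\link{neck_geometry}}.
#' @return The reflected geometry.
#' @export
mirror_geometry <- function(geom) {
  geom$nodule <- mirror_ellipse(geom$nodule)
  geom$nodule_angle <- -geom$nodule_angle
  geom$lobes <- list(left = mirror_ellipse(geom$lobes$right),
                     right = mirror_ellipse(geom$lobes$left))
  geom
}

#' Serialize / restore a neck geometry as JSON
#'
#' All primitives (layer thicknesses, ellipse centres/semi-axes/orientations,
#' trachea circle) are written so a run's geometry can be reproduced exactly.
#'
#' @param geom A \code{\link{neck_geometry}}.
#' @param path Output (input) JSON path.
#' @return \code{path} invisibly; \code{geometry_from_json} returns the
#'   restored \code{neck_geometry}.
#' @export
geometry_to_json <- function(geom, path) {
  jsonlite::write_json(unclass(geom), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname geometry_to_json
#' @export
geometry_from_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  g$nodule$center <- as.numeric(g$nodule$center)
  g$nodule$axis <- as.numeric(g$nodule$axis)
  for (nm in c("left", "right")) {
    g$lobes[[nm]]$center <- as.numeric(g$lobes[[nm]]$center)
    g$lobes[[nm]]$axis <- as.numeric(g$lobes[[nm]]$axis)
  }
  g$trachea$center <- as.numeric(g$trachea$center)
  structure(g, class = "neck_geometry")
}

#' @export
print.neck_geometry <- function(x, ...) {
  cat("Neck cross-section geometry\n")
  cat(sprintf("  outer radius %.4f m (perimeter %.1f cm)\n", x$outer_radius,
              200 * pi * x$outer_radius))
  cat(sprintf("  layers: skin %.1f mm, fat %.1f mm, muscle %.1f mm\n",
              1000 * x$skin_thickness, 1000 * x$fat_thickness,
              1000 * x$muscle_thickness))
  cat(sprintf("  nodule: %.2f x %.2f cm semi-axes at %.1f deg left, area %.2f cm^2\n",
              100 * x$nodule$a, 100 * x$nodule$b,
              180 / pi * x$nodule_angle, 1e4 * pi * x$nodule$a * x$nodule$b))
  cat(sprintf("  trachea: r %.1f cm at (%.1f, %.1f) cm\n",
              100 * x$trachea$radius, 100 * x$trachea$center[1],
              100 * x$trachea$center[2]))
  invisible(x)
}

#' @export
plot.neck_geometry <- function(x, n = 256L, ...) {
  R <- x$outer_radius
  graphics::plot(NA, xlim = c(-R, R) * 1.05, ylim = c(-R, R) * 1.05,
                 asp = 1, xlab = "x (m)", ylab = "y (m)",
                 main = "Neck cross-section", ...)
  circ <- function(c0, r) {
    a <- seq(0, 2 * pi, length.out = n)
    graphics::lines(c0[1] + r * cos(a), c0[2] + r * sin(a))
  }
  circ(c(0, 0), R)
  circ(c(0, 0), R - x$skin_thickness)
  if (x$fat_thickness > 0) {
    circ(c(0, 0), R - x$skin_thickness - x$fat_thickness)
  }
  circ(c(0, 0), R - x$skin_thickness - x$fat_thickness - x$muscle_thickness)
  circ(x$trachea$center, x$trachea$radius)
  for (e in list(x$lobes$left, x$lobes$right, x$nodule)) {
    b <- ellipse_boundary(e, n)
    graphics::polygon(b[, 1], b[, 2],
                      border = if (identical(e, x$nodule)) "red" else "blue")
  }
  pp <- probe_points(x)
  graphics::points(rbind(pp$front_of_nodule, pp$contralateral,
                         pp$nodule_center, pp$lobe_mirror),
                   pch = c(19, 1, 17, 2), col = "darkgreen")
  invisible(x)
}
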