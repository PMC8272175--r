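#' Thermophysical properties of the simulated neck tissues
#'
#' Returns the per-tissue thermophysical constants used throughout the
#' simulations: thermal conductivity \code{k} (W/(m K)), specific mass
#' \code{rho} (kg/m^3), specific heat \code{c} (J/(kg K)), blood perfusion
#' \code{wb} ((mL/s)/mL, i.e. 1/s), blood specific mass \code{rho_b} and
#' specific heat \code{c_b} (taken equal to the tissue's own \code{rho} and
#' \code{c}), arterial blood temperature \code{Tb} (degC) and metabolic heat
#' \code{Qm} (W/m^3).
#'
#' Two perfusion presets are provided because the literature units for the
#' gland-tissue perfusions are ambiguous. Taken literally as 1/s, the thyroid
#' (0.098) and nodule (0.465) perfusions thermally clamp those regions to
#' within ~0.02 degC of arterial temperature, which suppresses any metabolic
#' heating signature; read as per-minute rates (divide by 60) the nodule core
#' can run ~1.4 degC above arterial temperature. Both interpretations are kept
#' as named presets and every result records which one it used:
#' \describe{
#'   \item{\code{"as_printed"}}{all perfusions used exactly as tabulated.}
#'   \item{\code{"per_minute_gland"}}{thyroid and nodule perfusions divided
#'     by 60 before use; all other tissues unchanged.}
#' }
#'
#' @param preset Perfusion-units preset, \code{"as_printed"} or
#'   \code{"per_minute_gland"}.
#' @return An object of class \code{tissue_registry}: a data frame with one
#'   row per tissue (skin, fat, muscle, thyroid, nodule) and the columns
#'   described above, plus attribute \code{preset}.
#' @examples
#' reg <- tissue_registry()
#' reg["nodule", "Qm"]
#' tissue_registry("per_minute_gland")["nodule", "wb"]
#' @export
tissue_registry <- function(preset = c("as_printed", "per_minute_gland")) {
  preset <- match.arg(preset)
  tissues <- c("skin", "fat", "muscle", "thyroid", "nodule")
  reg <- data.frame(
    name = tissues,
    k    = c(0.37, 0.21, 0.47, 0.52, 0.89),
    rho  = c(1109, 911, 1090, 1050, 1050),
    c    = c(3391, 2348, 3421, 3609, 3770),
    Tb   = rep(37.0, 5),
    wb   = c(0.00196, 0.000501, 0.000708, 0.098, 0.465),
    Qm   = c(1829.85, 464.61, 1046, 4200, 42000),
    row.names = tissues,
    stringsAsFactors = FALSE
  )
  # blood properties equal to the host tissue's own
  reg$rho_b <- reg$rho
  reg$c_b <- reg$c
  if (preset == "per_minute_gland") {
    gl <- c("thyroid", "nodule")
    reg[gl, "wb"] <- reg[gl, "wb"] / 60
  }
  structure(reg, preset = preset, class = c("tissue_registry", "data.frame"))
}

#' @export
print.tissue_registry <- function(x, ...) {
  cat("Tissue thermophysical registry (preset: ", attr(x, "preset"), ")\n",
      sep = "")
  print.data.frame(x, digits = 6, ...)
  invisible(x)
}

#' Factorial grid of nodule metabolic heat and blood perfusion
#'
#' The 2 x 2 Cartesian product of the metabolic heat values representative of
#' normal thyroid tissue (4200 W/m^3) and of malignant tumours (42,000 W/m^3)
#' with the corresponding blood perfusion rates (0.098 and 0.465 (mL/s)/mL),
#' ordered with perfusion varying fastest.
#'
#' @return A data frame with columns \code{Qm} (W/m^3) and \code{wb}
#'   ((mL/s)/mL) and four rows.
#' @examples
#' nodule_parameter_grid()
#' @export
nodule_parameter_grid <- function() {
  expand.grid(wb = c(0.098, 0.465), Qm = c(4200, 42000),
              KEEP.OUT.ATTRS = FALSE)[, c("Qm", "wb")]
}

#' Apply a nodule (Qm, wb) combination to a tissue registry
#'
#' Replaces the nodule row's metabolic heat and blood perfusion by the given
#' combination. The perfusion value is interpreted in the registry's preset
#' units: under \code{per_minute_gland} the supplied (as-tabulated) \code{wb}
#' is divided by 60, mirroring what \code{\link{tissue_registry}} does for the
#' default nodule row.
#'
#' @param registry A \code{\link{tissue_registry}}.
#' @param Qm Nodule metabolic heat, W/m^3.
#' @param wb Nodule blood perfusion in as-tabulated units, (mL/s)/mL.
#' @return The modified registry.
#' @export
set_nodule_combo <- function(registry, Qm, wb) {
  stopifnot(inherits(registry, "tissue_registry"),
            is.numeric(Qm), length(Qm) == 1L, Qm >= 0,
            is.numeric(wb), length(wb) == 1L, wb >= 0)
  registry["nodule", "Qm"] <- Qm
  registry["nodule", "wb"] <-
    if (identical(attr(registry, "preset"), "per_minute_gland")) wb / 60 else wb
  registry
}

#' Write a tissue registry as CSV
#'
#' Exports the registry in a tabular layout (one column per tissue, one row
#' per parameter) mirroring how such parameter tables are usually printed.
#'
#' @param registry A \code{\link{tissue_registry}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_registry_csv <- function(registry, path) {
  stopifnot(inherits(registry, "tissue_registry"))
  params <- c("k", "rho", "c", "Tb", "wb", "Qm")
  tab <- t(as.matrix(registry[, params]))
  out <- data.frame(parameter = params, tab, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a tissue registry back from CSV
#'
#' Inverse of \code{\link{write_registry_csv}}. The preset cannot be recovered
#' from the numbers alone and must be restated.
#'
#' @param path CSV path written by \code{\link{write_registry_csv}}.
#' @param preset Preset label to attach to the result.
#' @return A \code{tissue_registry}.
#' @export
read_registry_csv <- function(path, preset = "as_printed") {
  raw <- utils::read.csv(path, check.names = FALSE)
  tissues <- setdiff(names(raw), "parameter")
  m <- t(as.matrix(raw[, tissues]))
  colnames(m) <- raw$parameter
  reg <- data.frame(name = tissues, m, row.names = tissues,
                    stringsAsFactors = FALSE)
  reg$rho_b <- reg$rho
  reg$c_b <- reg$c
  structure(reg, preset = preset, class = c("tissue_registry", "data.frame"))
}

#' Nodule size presets
#'
#' Semi-axes (m) of the three elliptic nodule sizes. The tangential semi-axis
#' is the larger of the pair and the radial semi-axis the smaller, so the
#' printed nodule areas (pi * a * b) are 2.64, 8.71 and 17.76 cm^2 for the
#' small, medium and large presets.
#'
#' @param size \code{"small"}, \code{"medium"} or \code{"large"}.
#' @return Numeric length-2 vector \code{c(tangential, radial)} in metres.
#' @export
nodule_semi_axes <- function(size = c("large", "medium", "small")) {
  size <- match.arg(size)
  switch(size,
         small  = c(0.012, 0.007),
         medium = c(0.022, 0.0126),
         large  = c(0.0314, 0.0180))
}

#' Define a simulation case
#'
#' Bundles the parameters that identify one simulated neck: fat layer
#' thickness, nodule size (preset label or explicit semi-axes), the nodule's
#' metabolic heat and blood perfusion, the target mesh size, and the perfusion
#' preset.
#'
#' @param fat_thickness Fat layer thickness, m (any nonnegative value; the
#'   study grid uses 0, 0.003, 0.006 and 0.012).
#' @param nodule_size Either a preset label (\code{"small"}, \code{"medium"},
#'   \code{"large"}) or a numeric length-2 vector of semi-axes in metres.
#' @param Qm Nodule metabolic heat, W/m^3.
#' @param wb Nodule blood perfusion, as-tabulated units.
#' @param preset Perfusion preset, see \code{\link{tissue_registry}}.
#' @param h_target Target mesh edge length, m.
#' @param label Optional case id; derived from the parameters if omitted.
#' @return An object of class \code{case_spec} (a list).
#' @examples
#' case_spec(fat_thickness = 0.006, nodule_size = "large")
#' @export
case_spec <- function(fat_thickness = 0.006, nodule_size = "large",
                      Qm = 42000, wb = 0.465,
                      preset = c("per_minute_gland", "as_printed"),
                      h_target = 0.001, label = NULL) {
  preset <- match.arg(preset)
  stopifnot(is.numeric(fat_thickness), length(fat_thickness) == 1L,
            fat_thickness >= 0, is.numeric(h_target), h_target > 0)
  if (is.character(nodule_size)) {
    size_label <- match.arg(nodule_size, c("small", "medium", "large"))
    semi <- nodule_semi_axes(size_label)
  } else {
    stopifnot(is.numeric(nodule_size), length(nodule_size) == 2L,
              all(nodule_size > 0))
    size_label <- "custom"
    semi <- as.numeric(nodule_size)
  }
  if (is.null(label)) {
    label <- sprintf("fat%.1fcm_%s_Qm%g_wb%g_%s", fat_thickness * 100,
                     size_label, Qm, wb, preset)
  }
  structure(list(fat_thickness = fat_thickness, nodule_size = size_label,
                 nodule_semi_axes = semi, Qm = Qm, wb = wb, preset = preset,
                 h_target = h_target, label = label),
            class = "case_spec")
}

#' @export
print.case_spec <- function(x, ...) {
  cat("Simulation case:", x$label, "\n")
  cat(sprintf("  fat %.1f cm | nodule %s (%.2f x %.2f cm semi-axes)\n",
              x$fat_thickness * 100, x$nodule_size,
              x$nodule_semi_axes[1] * 100, x$nodule_semi_axes[2] * 100))
  cat(sprintf("  nodule Qm %g W/m^3, wb %g (mL/s)/mL [%s] | h_target %.1f mm\n",
              x$Qm, x$wb, x$preset, x$h_target * 1000))
  invisible(x)
}

#' Read a case specification from a YAML or JSON file
#'
#' Accepts files with any subset of the \code{\link{case_spec}} arguments as
#' top-level keys; missing keys take the defaults.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{case_spec}.
#' @export
read_case_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(case_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown case config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(case_spec, cfg)
}
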