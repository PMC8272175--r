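# Thermogram time-series transformations and the scalar summary metrics
# used to compare cases: delta_TCL (contralateral skin difference) and
# delta_TF (temperature drop across the fat layer).

#' Uniformly sampled temperature series
#'
#' @param times Sample times, s; must be uniformly spaced.
#' @param values Temperatures, degC.
#' @param label Series label (probe + case id).
#' @return Object of class \code{temperature_series}.
#' @export
temperature_series <- function(times, values, label = "") {
  stopifnot(length(times) == length(values), length(times) >= 1L)
  if (length(times) > 1L) {
    dtv <- diff(times)
    if (max(abs(dtv - dtv[1])) > 1e-9) {
      stop("temperature series must be uniformly sampled")
    }
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("Temperature series '%s': %d samples", x$label,
              length(x$times)))
  if (length(x$times) > 1L) {
    cat(sprintf(" every %g s, %.2f .. %.2f degC", x$times[2] - x$times[1],
                min(x$values), max(x$values)))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.temperature_series <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "b", pch = 20,
                 xlab = "time (s)", ylab = "T (degC)", main = x$label, ...)
  invisible(x)
}

#' Rebase a series to start at zero
#'
#' Shifts all values so the first equals 0, the common-origin representation
#' used when reheating curves of different cases or patients are compared.
#'
#' @param s A \code{\link{temperature_series}}.
#' @return The rebased series.
#' @export
rebase_series <- function(s) {
  stopifnot(inherits(s, "temperature_series"))
  if (length(s$values) == 0L) stop("cannot rebase an empty series")
  s$values <- s$values - s$values[1]
  s
}

#' Consecutive temperature differences of a series
#'
#' The per-frame differences delta[i] = S[i+1] - S[i]; with uniform sampling
#' these are proportional to the heating/cooling rate.
#'
#' @param s A \code{\link{temperature_series}} with at least two samples.
#' @return List of class \code{difference_series} with \code{times} (from
#'   the second sample) and \code{deltas} (degC per interval).
#' @export
consecutive_differences <- function(s) {
  stopifnot(inherits(s, "temperature_series"))
  if (length(s$values) < 2L) {
    stop("need at least two samples for consecutive differences")
  }
  structure(list(times = s$times[-1L], deltas = diff(s$values),
                 label = s$label),
            class = "difference_series")
}

#' Scalar summary metrics of a simulated case
#'
#' \code{summarize_metrics} computes, from the front and contralateral probe
#' series and the annotated nodule-side line profile: the series start (steady
#' skin temperature), the cooling minimum, the final (end-of-reheating)
#' value, \code{delta_TCL} (front minus contralateral at steady state) and
#' \code{delta_TF} (temperature drop across the fat segment of the line
#' profile, interpolated at the exact layer interfaces).
#'
#' @param series_front,series_contra Time-aligned
#'   \code{\link{temperature_series}} at the front-of-nodule and
#'   contralateral skin probes.
#' @param line_profile Annotated profile from
#'   \code{\link{extract_line_profile}}.
#' @param geom The case's \code{\link{neck_geometry}}.
#' @return List of class \code{summary_metrics}.
#' @export
summarize_metrics <- function(series_front, series_contra, line_profile,
                              geom) {
  stopifnot(inherits(series_front, "temperature_series"),
            inherits(series_contra, "temperature_series"))
  if (length(series_front$times) != length(series_contra$times) ||
      max(abs(series_front$times - series_contra$times)) > 1e-9) {
    stop("front and contralateral series are not aligned in time")
  }
  f <- geom$fat_thickness
  if (f > 0) {
    if (!any(line_profile$tissue == "fat")) {
      stop("line profile has no fat segment although fat_thickness > 0")
    }
    d1 <- geom$skin_thickness
    d2 <- geom$skin_thickness + f
    T1 <- stats::approx(line_profile$depth, line_profile$T, xout = d1)$y
    T2 <- stats::approx(line_profile$depth, line_profile$T, xout = d2)$y
    delta_TF <- T2 - T1
  } else {
    delta_TF <- 0
  }
  structure(list(start = series_front$values[1],
                 cooling_min = min(series_front$values),
                 end = series_front$values[length(series_front$values)],
                 delta_TF = delta_TF,
                 delta_TCL = series_front$values[1] - series_contra$values[1]),
            class = "summary_metrics")
}

#' @export
print.summary_metrics <- function(x, ...) {
  cat(sprintf(paste0("start %.2f degC, cooling min %.2f, end %.2f | ",
                     "delta_TF %.2f, delta_TCL %.2f degC\n"),
              x$start, x$cooling_min, x$end, x$delta_TF, x$delta_TCL))
  invisible(x)
}

#' Summary metrics straight from a protocol result
#'
#' Convenience wrapper: extracts the front and contralateral probe series
#' and the nodule-side line profile of the steady field, then calls
#' \code{\link{summarize_metrics}}.
#'
#' @param result A \code{\link{run_protocol}} result.
#' @return A \code{summary_metrics}.
#' @export
summarize_protocol <- function(result) {
  pp <- probe_points(result$geom)
  sf <- extract_point_series(result, pp$front_of_nodule, "front")
  sc <- extract_point_series(result, pp$contralateral, "contralateral")
  lp <- extract_line_profile(result$steady_field, result$geom,
                             side = "nodule")
  summarize_metrics(sf, sc, lp, result$geom)
}

#' Write / read a temperature or difference series as CSV
#'
#' Plain two-column CSV (time, value) with '#'-prefixed header metadata
#' lines carrying the label and sampling interval.
#'
#' @param s A \code{temperature_series} or \code{difference_series}.
#' @param path Output path.
#' @return \code{path} invisibly; \code{read_series_csv} returns the series.
#' @export
write_series_csv <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("# label: ", s$label, "\n", file = con, sep = "")
  if (inherits(s, "difference_series")) {
    cat("# type: difference\n", file = con)
    df <- data.frame(time = s$times, delta = s$deltas)
  } else {
    cat("# type: temperature\n", file = con)
    df <- data.frame(time = s$times, T = s$values)
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  label <- trimws(sub("^# label:", "", grep("^# label:", meta, value = TRUE)))
  type <- sub("^# type:\\s*", "", grep("^# type:", meta, value = TRUE))
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"))
  if (identical(type, "difference")) {
    structure(list(times = df$time, deltas = df$delta,
                   label = if (length(label)) label else ""),
              class = "difference_series")
  } else {
    temperature_series(df$time, df[[2L]],
                       label = if (length(label)) label else "")
  }
}
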