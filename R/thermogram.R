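# Synthetic thermogram sequences standing in for infrared camera exports,
# plus the matrix I/O and the 11x11 region-of-interest series extraction
# applied to patient examinations.
#
# The emulated acquisition: frames of up to 640 x 480 temperature pixels,
# one every 15 s for 5 min (20 frames) during reheating, additive Gaussian
# sensor noise at the camera's NETD scale (< 40 mK), and one marked pixel
# in the central nodule region whose windowed mean forms the patient series.

CAMERA_RANGE <- c(-40, 2000)  # degC, the camera's capture range

#' Single thermogram frame
#'
#' @param values Temperature matrix, degC (rows x cols).
#' @param timestamp Acquisition time, s.
#' @param marked_point Pixel (row, col) marking the nodule region.
#' @return Object of class \code{thermogram}.
#' @export
thermogram <- function(values, timestamp = 0, marked_point = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < CAMERA_RANGE[1] | values > CAMERA_RANGE[2])) {
    stop(sprintf("validation error: temperatures outside the camera range [%g, %g] degC",
                 CAMERA_RANGE[1], CAMERA_RANGE[2]))
  }
  if (!is.null(marked_point)) {
    stopifnot(length(marked_point) == 2L,
              marked_point[1] >= 1, marked_point[1] <= nrow(values),
              marked_point[2] >= 1, marked_point[2] <= ncol(values))
    marked_point <- as.integer(marked_point)
  }
  structure(list(values = values, timestamp = timestamp,
                 marked_point = marked_point),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram %d x %d px, t = %g s, %.2f .. %.2f degC",
              nrow(x$values), ncol(x$values), x$timestamp,
              min(x$values), max(x$values)))
  if (!is.null(x$marked_point)) {
    cat(sprintf(", marked (%d, %d)", x$marked_point[1], x$marked_point[2]))
  }
  cat("\n")
  invisible(x)
}

# run code under a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthesize a thermogram sequence from a protocol simulation
#'
#' Renders each reheating sample onto an image frame: the skin-surface
#' temperature profile is mapped onto the columns of a horizontal band (one
#' column per arc position, the marked column aligned exactly with the
#' front-of-nodule arc), the background is filled with the air temperature,
#' and i.i.d. Gaussian sensor noise of the requested standard deviation is
#' added under the given seed. Full 2D radiometric rendering of a neck is
#' deliberately out of scope; the band embedding exercises the whole series
#' pipeline.
#'
#' @param result A \code{\link{run_protocol}} result.
#' @param frame_shape Frame size c(rows, cols); default 480 x 640 pixels.
#' @param noise_sd Sensor noise standard deviation, degC (default 0.04, the
#'   NETD bound).
#' @param seed Integer seed; required for any nonzero noise.
#' @return Object of class \code{thermogram_sequence}: list of frames at
#'   uniform spacing plus acquisition metadata.
#' @export
synthesize_thermogram_sequence <- function(result,
                                           frame_shape = c(480L, 640L),
                                           noise_sd = 0.04, seed = 1L) {
  stopifnot(inherits(result, "protocol_result"), noise_sd >= 0,
            length(frame_shape) == 2L, all(frame_shape >= 12L))
  fields <- result$reheating_fields[-1L]
  if (length(fields) == 0L) stop("empty protocol result: no reheating fields")
  nr <- as.integer(frame_shape[1]); nc <- as.integer(frame_shape[2])
  geom <- result$geom
  pp <- probe_points(geom)
  R <- geom$outer_radius
  smax <- R * (pi / 2 - 1e-3)
  arcs <- seq(-smax, smax, length.out = nc)
  mark_col <- which.min(abs(arcs - pp$front_arc))
  arcs <- arcs + (pp$front_arc - arcs[mark_col])  # align marked column
  skin_pts <- cbind(R * sin(arcs / R), R * cos(arcs / R))
  band <- max(1L, nr %/% 3L)
  rows <- seq.int(nr %/% 2L - band %/% 2L, length.out = band)
  mark_row <- as.integer(round(mean(rows)))
  Tair <- result$config$reheating$Tair

  frames <- with_seed(seed, lapply(fields, function(f) {
    vals <- matrix(Tair, nr, nc)
    vals[rows, ] <- matrix(evaluate_field(f, skin_pts), length(rows), nc,
                           byrow = TRUE)
    if (noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
    }
    thermogram(vals, timestamp = f$time,
               marked_point = c(mark_row, mark_col))
  }))
  structure(list(frames = frames, noise_sd = noise_sd, seed = seed,
                 provenance = result$case$label),
            class = "thermogram_sequence")
}

#' @export
print.thermogram_sequence <- function(x, ...) {
  f1 <- x$frames[[1L]]
  cat(sprintf("Thermogram sequence: %d frames of %d x %d px (noise sd %g degC, seed %s)\n",
              length(x$frames), nrow(f1$values), ncol(f1$values),
              x$noise_sd, format(x$seed)))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a thermogram temperature matrix from text
#'
#' Accepts comma- or semicolon-separated rectangular numeric matrices with
#' dot or comma decimal marks (autodetected), as produced by camera export
#' tools. Values are validated against the camera's capture range.
#'
#' @param path File path.
#' @param timestamp,marked_point Passed to \code{\link{thermogram}}.
#' @return A \code{thermogram}.
#' @export
read_thermogram_matrix <- function(path, timestamp = 0,
                                   marked_point = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(";", first, fixed = TRUE)) ";" else ","
  dec <- if (sep == ";" && grepl(",", first, fixed = TRUE)) "," else "."
  df <- tryCatch(
    utils::read.table(path, sep = sep, dec = dec, header = FALSE,
                      colClasses = "numeric", fill = FALSE),
    error = function(e) stop("parse error reading thermogram matrix '",
                             path, "': ", conditionMessage(e)))
  m <- as.matrix(df)
  dimnames(m) <- NULL
  thermogram(m, timestamp = timestamp, marked_point = marked_point)
}

#' Write a thermogram matrix as CSV
#'
#' @param frame A \code{thermogram}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_thermogram_matrix <- function(frame, path) {
  utils::write.table(frame$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Persist / load a thermogram sequence as CSV frames plus JSON manifest
#'
#' One CSV matrix per frame plus \code{manifest.json} holding timestamps,
#' the marked pixel and the noise metadata.
#'
#' @param seq A \code{thermogram_sequence}.
#' @param dir Directory (created if needed).
#' @return The directory (reader: the restored sequence).
#' @export
write_thermogram_sequence <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("frame_%03d.csv", seq_along(seq$frames))
  for (i in seq_along(seq$frames)) {
    write_thermogram_matrix(seq$frames[[i]], file.path(dir, files[i]))
  }
  manifest <- list(files = files,
                   timestamps = vapply(seq$frames, `[[`, numeric(1),
                                       "timestamp"),
                   marked_point = seq$frames[[1L]]$marked_point,
                   noise_sd = seq$noise_sd, seed = seq$seed,
                   provenance = seq$provenance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_thermogram_sequence
#' @export
read_thermogram_sequence <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  frames <- lapply(seq_along(manifest$files), function(i) {
    read_thermogram_matrix(file.path(dir, manifest$files[i]),
                           timestamp = manifest$timestamps[i],
                           marked_point = manifest$marked_point)
  })
  structure(list(frames = frames, noise_sd = manifest$noise_sd,
                 seed = manifest$seed, provenance = manifest$provenance),
            class = "thermogram_sequence")
}

#' Mean temperature of a square window around a pixel
#'
#' Arithmetic mean of the size x size block centred at \code{p}. Windows
#' crossing the frame border are an error (no padding): silent truncation
#' would bias patient series.
#'
#' @param frame A \code{thermogram}.
#' @param p Pixel (row, col).
#' @param size Odd window size; 11 is the protocol's region of interest.
#' @return Mean temperature, degC.
#' @export
window_mean <- function(frame, p = frame$marked_point, size = 11L) {
  stopifnot(inherits(frame, "thermogram"), length(p) == 2L)
  if (size %% 2L != 1L) stop("window size must be odd")
  half <- (size - 1L) %/% 2L
  r <- as.integer(p[1]); cc <- as.integer(p[2])
  if (r - half < 1L || r + half > nrow(frame$values) ||
      cc - half < 1L || cc + half > ncol(frame$values)) {
    stop(sprintf("window error: %dx%d window at (%d, %d) crosses the frame border",
                 size, size, r, cc))
  }
  mean(frame$values[(r - half):(r + half), (cc - half):(cc + half)])
}

#' Patient temperature series from a thermogram sequence
#'
#' Applies \code{\link{window_mean}} at the marked pixel of every frame;
#' the output feeds the series analysis unchanged.
#'
#' @param seq A \code{thermogram_sequence} with a marked point.
#' @param size Window size (odd), default 11.
#' @return A \code{\link{temperature_series}}.
#' @export
patient_series <- function(seq, size = 11L) {
  stopifnot(inherits(seq, "thermogram_sequence"), length(seq$frames) >= 1L)
  vals <- vapply(seq_along(seq$frames), function(i) {
    tryCatch(window_mean(seq$frames[[i]], size = size),
             error = function(e) stop("frame ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  times <- vapply(seq$frames, `[[`, numeric(1), "timestamp")
  temperature_series(times, vals,
                     label = paste0(seq$provenance, " (ROI mean)"))
}
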