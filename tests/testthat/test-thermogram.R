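test_that("window mean equals the brute-force block average", {
  set.seed(9)
  vals <- matrix(rnorm(40 * 50, 32, 0.5), 40, 50)
  fr <- thermogram(vals, marked_point = c(20, 25))
  got <- window_mean(fr, c(20, 25), size = 11L)
  acc <- 0
  for (i in 15:25) for (j in 20:30) acc <- acc + vals[i, j]
  expect_equal(got, acc / 121)
  # constant frame, and symmetry for a linear column gradient
  expect_equal(window_mean(thermogram(matrix(30, 20, 20)), c(10, 10)), 30)
  grad <- thermogram(matrix(rep(seq_len(30), each = 25), 25, 30))
  expect_equal(window_mean(grad, c(13, 16)), grad$values[13, 16])
  # windows may not cross the border, and sizes must be odd
  expect_error(window_mean(fr, c(3, 25)), "border")
  expect_error(window_mean(fr, c(20, 48)), "border")
  expect_error(window_mean(fr, c(20, 25), size = 10L), "odd")
})

test_that("camera range validation rejects impossible temperatures", {
  expect_error(thermogram(matrix(c(30, 2500), 1, 2)), "-40.*2000")
  expect_error(thermogram(matrix(c(30, -50), 1, 2)), "range")
  expect_silent(thermogram(matrix(c(-40, 2000), 1, 2)))
})

test_that("matrix files round-trip and autodetect separators", {
  fr <- thermogram(matrix(c(30.25, 31.5, 29.125, 32, 28, 33.75), 2, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermogram_matrix(fr, path)
  back <- read_thermogram_matrix(path)
  expect_identical(back$values, fr$values)
  expect_equal(dim(back$values), c(2L, 3L))
  # semicolon-separated with comma decimals (European camera exports)
  writeLines(c("30,5;31,25;29", "28;33;32,75"), path)
  eu <- read_thermogram_matrix(path)
  expect_equal(eu$values, matrix(c(30.5, 28, 31.25, 33, 29, 32.75), 2, 3))
  # ragged rows are a parse error, out-of-range cells a validation error
  writeLines(c("30,31", "28"), path)
  expect_error(read_thermogram_matrix(path), "parse error")
  writeLines(c("30,31", "28,2500"), path)
  expect_error(read_thermogram_matrix(path), "range")
})

test_that("synthesized sequences embed the simulation exactly when noiseless", {
  res <- fx_protocol(fat = 0)
  seq0 <- synthesize_thermogram_sequence(res, frame_shape = c(60, 120),
                                         noise_sd = 0, seed = 1)
  expect_length(seq0$frames, 20L)
  fr1 <- seq0$frames[[1L]]
  mp <- fr1$marked_point
  truth <- evaluate_field(res$reheating_fields[[2L]],
                          probe_points(res$geom)$front_of_nodule)
  expect_equal(fr1$values[mp[1], mp[2]], truth)
  # the full patient series tracks the simulated probe series closely
  ps <- patient_series(seq0)
  sim <- vapply(res$reheating_fields[-1L], function(f) {
    evaluate_field(f, probe_points(res$geom)$front_of_nodule)
  }, numeric(1))
  expect_lt(max(abs(ps$values - sim)), 0.05)
  expect_equal(unique(diff(ps$times)), 15)
  # and equals the framewise window-mean loop by definition
  loop <- vapply(seq0$frames, window_mean, numeric(1))
  expect_identical(ps$values, loop)
})

test_that("default acquisition geometry matches the camera description", {
  res <- fx_protocol(fat = 0)
  seqd <- synthesize_thermogram_sequence(res, noise_sd = 0.04, seed = 42)
  expect_length(seqd$frames, 20L)
  expect_equal(dim(seqd$frames[[1L]]$values), c(480L, 640L))
  # empirical noise sd over the background pixels recovers the input
  fr <- seqd$frames[[1L]]
  bg <- fr$values[fr$values < 28]  # background band is at Tair = 25
  expect_gt(length(bg), 1e5)
  expect_gt(stats::sd(bg), 0.039)
  expect_lt(stats::sd(bg), 0.041)
})

test_that("fixed seeds give bit-identical sequences", {
  res <- fx_mini_protocol(fat = 0)
  a <- synthesize_thermogram_sequence(res, c(40, 80), 0.04, seed = 7)
  b <- synthesize_thermogram_sequence(res, c(40, 80), 0.04, seed = 7)
  c3 <- synthesize_thermogram_sequence(res, c(40, 80), 0.04, seed = 8)
  expect_identical(a$frames[[1L]]$values, b$frames[[1L]]$values)
  expect_false(identical(a$frames[[1L]]$values, c3$frames[[1L]]$values))
  # synthesis does not disturb the global RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(synthesize_thermogram_sequence(res, c(40, 80), 0.04, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("window averaging attenuates sensor noise by the expected factor", {
  res <- fx_mini_protocol(fat = 0)
  sim <- vapply(res$reheating_fields[-1L], function(f) {
    evaluate_field(f, probe_points(res$geom)$front_of_nodule)
  }, numeric(1))
  errs <- sapply(1:50, function(sd_seed) {
    sq <- synthesize_thermogram_sequence(res, c(40, 80), noise_sd = 0.04,
                                         seed = sd_seed)
    patient_series(sq)$values - sim
  })  # frames x replicates
  # remove each frame's deterministic embedding offset, pool the noise
  centred <- as.vector(errs - rowMeans(errs))
  # ROI mean of 121 pixels: sd 0.04/11, within 3 standard errors
  se <- 0.04 / 11 / sqrt(2 * length(centred))
  expect_lt(abs(stats::sd(centred) - 0.04 / 11), 3 * se + 2e-4)
})

test_that("sequences persist as CSV frames plus manifest and reload", {
  res <- fx_mini_protocol(fat = 0)
  sq <- synthesize_thermogram_sequence(res, c(30, 60), 0.02, seed = 3)
  dir <- withr::local_tempdir()
  write_thermogram_sequence(sq, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_thermogram_sequence(dir)
  expect_length(back$frames, length(sq$frames))
  expect_equal(back$frames[[2L]]$values, sq$frames[[2L]]$values,
               tolerance = 1e-12)
  expect_identical(back$frames[[2L]]$marked_point,
                   sq$frames[[2L]]$marked_point)
  expect_equal(patient_series(back)$values, patient_series(sq)$values,
               tolerance = 1e-10)
})
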