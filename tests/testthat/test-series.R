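test_that("rebasing sets a zero origin and round-trips exactly", {
  s <- temperature_series(seq(0, 60, 15), c(33.2, 32.8, 32.5, 32.9, 33.0),
                          label = "probe")
  r <- rebase_series(s)
  expect_equal(r$values[1], 0)
  expect_identical(r$times, s$times)
  expect_equal(r$values + s$values[1], s$values)
  cns <- temperature_series(c(0, 15), c(30, 30))
  expect_equal(rebase_series(cns)$values, c(0, 0))
  empty <- structure(list(times = numeric(), values = numeric(), label = ""),
                     class = "temperature_series")
  expect_error(rebase_series(empty), "empty")
})

test_that("consecutive differences telescope and are shift invariant", {
  set.seed(5)
  s <- temperature_series(seq(0, 300, 15), 30 + cumsum(rnorm(21, 0, 0.2)))
  d <- consecutive_differences(s)
  expect_length(d$deltas, length(s$values) - 1L)
  expect_identical(d$times, s$times[-1L])
  expect_equal(sum(d$deltas), s$values[21] - s$values[1])
  # rebasing changes nothing about the differences (exactly)
  expect_identical(consecutive_differences(rebase_series(s))$deltas,
                   d$deltas)
  const <- temperature_series(c(0, 15, 30), rep(31, 3))
  expect_equal(consecutive_differences(const)$deltas, c(0, 0))
  arith <- temperature_series(seq(0, 45, 15), seq(30, 30.6, 0.2))
  expect_equal(consecutive_differences(arith)$deltas, rep(0.2, 3))
  one <- temperature_series(0, 30)
  expect_error(consecutive_differences(one), "two samples")
})

test_that("summary metrics compute the contralateral and fat-layer drops", {
  res <- fx_protocol(fat = 0.006)
  m <- summarize_protocol(res)
  expect_lte(m$cooling_min, m$start)
  expect_true(all(is.finite(unlist(m[1:5]))))
  expect_gt(m$delta_TCL, 0)
  expect_gt(m$delta_TF, 0)  # temperatures rise with depth through fat

  # identical front/contra series give zero contralateral difference
  pp <- probe_points(res$geom)
  sf <- extract_point_series(res, pp$front_of_nodule)
  lp <- extract_line_profile(res$steady_field, res$geom)
  same <- summarize_metrics(sf, sf, lp, res$geom)
  expect_equal(same$delta_TCL, 0)

  # misaligned series are rejected
  s2 <- temperature_series(sf$times[-1], sf$values[-1])
  expect_error(summarize_metrics(sf, s2, lp, res$geom), "aligned")
})

test_that("zero-fat cases have a zero fat-layer drop by definition", {
  res <- fx_mini_protocol(fat = 0)
  m <- summarize_protocol(res)
  expect_identical(m$delta_TF, 0)
})

test_that("series CSVs round-trip with their metadata", {
  s <- temperature_series(seq(0, 45, 15), c(33, 32, 31.5, 31.2), "case-x")
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(s, path)
  expect_true(any(grepl("^#", readLines(path))))
  back <- read_series_csv(path)
  expect_equal(back$values, s$values)
  expect_equal(back$times, s$times)
  expect_identical(back$label, "case-x")
  d <- consecutive_differences(s)
  write_series_csv(d, path)
  backd <- read_series_csv(path)
  expect_s3_class(backd, "difference_series")
  expect_equal(backd$deltas, d$deltas)
})

test_that("reheating rate ordering follows fat thickness", {
  # thinner fat reheats faster: mean reheating delta decreases with fat
  mean_delta <- vapply(c(0.003, 0.012), function(fat) {
    res <- fx_protocol(fat = fat)
    sf <- extract_point_series(res, probe_points(res$geom)$front_of_nodule)
    nc <- length(res$cooling_fields)
    reheat <- temperature_series(sf$times[nc:41] - sf$times[nc],
                                 sf$values[nc:41])
    mean(consecutive_differences(reheat)$deltas)
  }, numeric(1))
  expect_gt(mean_delta[1], mean_delta[2])
})
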