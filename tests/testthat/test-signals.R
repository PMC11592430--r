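test_that("synthetic generator is reproducible and shape-controllable", {
  m1 <- synth_signals(3, 500, seed = 1L)
  m2 <- synth_signals(3, 500, seed = 1L)
  expect_identical(m1, m2)
  expect_identical(dim(m1$data), c(500L, 3L))
  # 19-channel default carries 10-20 labels
  m19 <- synth_signals(19, 200, seed = 2L)
  expect_identical(colnames(m19$data), EEG_1020_LABELS)
  expect_error(synth_signals(0, 500), "invalid sizes")
  expect_error(synth_signals(2, 50), "invalid sizes")
  expect_error(synth_signals(2, 500, noise_sd = 0), "positive")
})

test_that("noise tilt controls the amplitude skewness", {
  skewness <- function(v) mean((v - mean(v))^3) / sd(v)^3
  m0 <- synth_signals(1, 1e5, base_freqs = numeric(0), noise_sd = 1,
                      skew = 0, seed = 3L)
  expect_lt(abs(skewness(m0$data[, 1L])), 0.1)
  mp <- synth_signals(1, 1e5, base_freqs = numeric(0), noise_sd = 1,
                      skew = 0.8, seed = 3L)
  mn <- synth_signals(1, 1e5, base_freqs = numeric(0), noise_sd = 1,
                      skew = -0.8, seed = 3L)
  expect_gt(skewness(mp$data[, 1L]), 1)
  expect_lt(skewness(mn$data[, 1L]), -1)
})

test_that("wider noise widens the support of the channel curve", {
  narrow <- synth_signals(1, 5000, noise_sd = 0.1, seed = 5L)
  wide <- synth_signals(1, 5000, noise_sd = 1.0, seed = 5L)
  cn <- channel_derangetropy(narrow, "ch01")$curve
  cw <- channel_derangetropy(wide, "ch01")$curve
  expect_gt(diff(range(cw$grid)), diff(range(cn$grid)))
})

test_that("signal matrices round-trip through delimited text", {
  m <- synth_signals(2, 1000, seed = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_matrix(m, path, "comma")
  back <- read_signal_matrix(path, "comma", sampling_rate = m$sampling_rate)
  expect_identical(colnames(back$data), colnames(m$data))
  expect_equal(back$data, m$data, tolerance = 1e-12)
})

test_that("malformed matrix files are rejected with coordinates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3"), path)
  expect_error(read_signal_matrix(path, "comma"), "line 3")
  writeLines(c("a,b", rep("1,2", 150L)[-7], "1,oops",
               rep("1,2", 20L)), path)
  # non-numeric cell lands at file row 151 after the removals above
  expect_error(read_signal_matrix(path, "comma"), "column 2")
  writeLines("a,b", path)
  expect_error(read_signal_matrix(path, "comma"), "insufficient")
  writeLines(c("a,b", rep("1,2", 50L)), path)
  expect_error(read_signal_matrix(path, "comma"), "insufficient")
})

test_that("parse errors name the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- rep("0.1,0.2", 120L)
  rows[6L] <- "0.1,bad"  # file line 7 including the header
  writeLines(c("c1,c2", rows), path)
  expect_error(read_signal_matrix(path, "comma"), "row 7")
})

test_that("per-channel curves are valid densities peaking near the median", {
  m <- synth_signals(3, 4000, base_freqs = c(4, 10), noise_sd = 0.5,
                     seed = 6L)
  r <- channel_derangetropy(m, "ch02")
  expect_equal(curve_mass(r$curve), 1, tolerance = 1e-3)
  bw <- unname(r$curve$source$params["bw"])
  expect_lt(abs(r$peak_location - median(m$data[, "ch02"])), bw)
  expect_gte(r$peak_height, r$level_mean)
  expect_error(channel_derangetropy(m, "nope"), "unknown channel")
})

test_that("skewed channels shift the curve peak off the sample midrange", {
  m <- synth_signals(1, 2e4, base_freqs = numeric(0), noise_sd = 1,
                     skew = 1.2, seed = 8L)
  x <- m$data[, 1L]
  r <- channel_derangetropy(m, "ch01")
  # strongly right-skewed amplitudes: the peak tracks the median, which
  # sits below the mean on the high-density (left) side
  expect_lt(r$peak_location, mean(x))
})

test_that("whole-matrix analysis preserves order and skips degeneracies", {
  m <- synth_signals(19, 600, seed = 9L)
  res <- analyze_all(m)
  expect_identical(names(res$results), EEG_1020_LABELS)
  expect_length(res$results, 19L)
  m4 <- synth_signals(4, 600, seed = 10L)
  m4$data[, 3L] <- 1  # constant channel
  res4 <- analyze_all(m4)
  expect_length(res4$results, 3L)
  expect_identical(names(res4$skipped), colnames(m4$data)[3L])
  expect_match(res4$skipped[[1L]], "zero variance")
  mall <- m4
  mall$data[] <- 2
  expect_error(analyze_all(mall), "every channel")
})

test_that("identical channels produce identical curves", {
  m <- synth_signals(2, 1000, seed = 11L)
  m$data[, 2L] <- m$data[, 1L]
  res <- analyze_all(m)
  expect_equal(res$results[[1L]]$curve$values,
               res$results[[2L]]$curve$values, tolerance = 1e-12)
})

test_that("channel exports write long TSV plus JSON summaries", {
  m <- synth_signals(2, 600, seed = 12L)
  res <- analyze_all(m, n_points = 256L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  export_channel_results(res, tsv, json)
  back <- read.delim(tsv)
  expect_identical(names(back), c("channel", "x", "rho"))
  summ <- jsonlite::read_json(json)
  expect_identical(names(summ), colnames(m$data))
  expect_named(summ[[1L]], c("peak_location", "peak_height", "spread",
                             "level_mean"))
})
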