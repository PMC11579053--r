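test_that("protocol validates durations and exposes the bin grid", {
  p <- rb_protocol()
  expect_equal(n_bins(p), 36)
  expect_equal(total_duration(p), 360)
  expect_equal(bin_centers(p)[1:3], c(5, 15, 25))
  expect_equal(table(phase_labels(p))[["baseline"]], 6)
  expect_equal(table(phase_labels(p))[["rebreathing"]], 15)
  expect_error(rb_protocol(baseline_s = 65), "multiples")
  expect_error(rb_protocol(bin_s = 0), "bin_s")
})

test_that("protocol JSON round-trips", {
  p <- rb_protocol(120, 150, 150, 10, 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_protocol(p, path)
  expect_equal(read_protocol(path), p)
})

test_that("capnogram construction enforces uniform sampling and range", {
  expect_error(capnogram(c(0, 0.02, 0.05), c(1, 2, 3)), "non-uniform")
  expect_error(capnogram(c(0, 0.02, 0.04), c(1, 2, 16)), "15")
  expect_error(capnogram(c(0, 0.02, 0.01), c(1, 2, 3)), "increasing")
  cap <- capnogram(seq(0, 1, by = 0.02), rep(1, 51))
  expect_s3_class(cap, "capnogram")
  expect_equal(attr(cap, "sample_rate_hz"), 50)
})

test_that("breath segmentation recovers known trapezoid plateaus exactly", {
  cap <- trapezoid_capnogram(c(5.0, 5.2, 5.4))
  br <- segment_breaths(cap, trough_frac = 0.5)
  expect_equal(br$etco2_pct, c(5.0, 5.2, 5.4))
  expect_true(all(diff(br$breath_end_time_s) > 0))
  expect_true(all(br$etco2_pct <= max(cap$co2_pct)))

  one <- segment_breaths(trapezoid_capnogram(6.0))
  expect_equal(nrow(one), 1)
  expect_equal(one$etco2_pct, 6.0)
})

test_that("flat signals yield a 'no breaths' error", {
  flat <- capnogram(seq(0, 10, by = 0.02), rep(0, 501))
  expect_error(segment_breaths(flat), "no breaths detected")
  const <- capnogram(seq(0, 10, by = 0.02), rep(5, 501))
  expect_error(segment_breaths(const), "no breaths detected")
})

test_that("segmentation tolerates bounded noise to within its amplitude", {
  plateaus <- seq(5, 7, length.out = 10)
  cap <- trapezoid_capnogram(plateaus)
  amp <- 0.05
  noisy <- withr::with_seed(7, {
    capnogram(cap$time_s, pmax(cap$co2_pct + runif(nrow(cap), -amp, amp), 0))
  })
  br <- segment_breaths(noisy, trough_frac = 0.5)
  expect_equal(nrow(br), length(plateaus))
  expect_lt(max(abs(br$etco2_pct - plateaus)), amp + 1e-12)
})

test_that("binning averages within bins and carries forward empty bins", {
  p <- rb_protocol()
  br <- structure(data.frame(breath_end_time_s = c(2, 6), etco2_pct = c(5.0, 5.4)),
                  class = c("breath_series", "data.frame"))
  g <- bin_to_grid(br, p)
  expect_equal(g[1], 5.2)           # mean of the two breaths in bin 1
  expect_equal(length(g), 36)
  expect_equal(g[2:36], rep(5.2, 35))  # carry-forward fills the rest

  # one breath per bin: identity
  br2 <- structure(data.frame(breath_end_time_s = bin_centers(p),
                              etco2_pct = seq(5, 8.5, by = 0.1)),
                   class = c("breath_series", "data.frame"))
  expect_equal(bin_to_grid(br2, p), seq(5, 8.5, by = 0.1))

  # first bin empty is an error
  br3 <- structure(data.frame(breath_end_time_s = 15, etco2_pct = 5),
                   class = c("breath_series", "data.frame"))
  expect_error(bin_to_grid(br3, p), "cannot initialize grid")
})

test_that("binned values stay within the range of contributing breaths", {
  p <- rb_protocol()
  for (seed in 1:5) {
    br <- withr::with_seed(seed, {
      tt <- sort(runif(80, 0, 359.9))
      tt <- c(runif(1, 0, 9), tt)     # ensure first bin occupied
      data.frame(breath_end_time_s = sort(tt),
                 etco2_pct = runif(81, 4, 8))
    })
    g <- bin_to_grid(structure(br, class = c("breath_series", "data.frame")), p)
    expect_length(g, 36)
    idx <- pmin(floor(br$breath_end_time_s / 10) + 1, 36)
    for (k in seq_len(36)) {
      vals <- br$etco2_pct[idx == k]
      if (length(vals)) {
        expect_gte(g[k], min(vals) - 1e-12)
        expect_lte(g[k], max(vals) + 1e-12)
      } else {
        expect_equal(g[k], g[k - 1])
      }
    }
  }
})

test_that("trace CSV write/read round-trips bit-exactly with missing ratings", {
  p <- rb_protocol()
  for (seed in c(3, 4)) {
    tr <- withr::with_seed(seed, {
      et <- runif(36, 4.5, 7.8)
      rt <- runif(36, 0, 100)
      rt[sample(36, 5)] <- NA
      experiment_trace(et, rt, p)
    })
    path <- withr::local_tempfile(fileext = ".csv")
    write_trace(tr, path)
    back <- read_trace(path, protocol = p)
    expect_identical(back$etco2_pct, tr$etco2_pct)
    expect_identical(back$rating, tr$rating)
    expect_identical(back$phase, tr$phase)
    expect_identical(back$time_s, tr$time_s)
  }
})

test_that("trace reading validates columns and rating range", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,rating", "5,10"), path)
  expect_error(read_trace(path), "etco2_pct")

  tr <- experiment_trace(rep(5.5, 36), rep(20, 36))
  write_trace(tr, path)
  txt <- readLines(path)
  txt[3] <- sub(",20$", ",101", txt[3])
  writeLines(txt, path)
  expect_error(read_trace(path), "\\[0, 100\\]")

  expect_error(experiment_trace(rep(5.5, 36), c(-1, rep(10, 35))),
               "\\[0, 100\\]")
  expect_error(experiment_trace(rep(5.5, 10)), "n_bins")
})

test_that("a raw capnogram CSV is reduced to the bin grid on read", {
  p <- rb_protocol()
  targets <- rep(seq(5, 6.6, length.out = 9), each = 10)  # 90 breaths x 4 s
  cap <- generate_capnogram(targets, p, breath_period_s = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = cap$time_s, co2_pct = cap$co2_pct), path,
            row.names = FALSE)
  tr <- read_trace(path, protocol = p)
  expect_s3_class(tr, "experiment_trace")
  expect_equal(nrow(tr), 36)
  expect_true(all(is.na(tr$rating)))
  # 2.5 breaths per bin, plateaus constant within each 40 s block
  expect_equal(tr$etco2_pct[1], 5, tolerance = 1e-10)
})
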