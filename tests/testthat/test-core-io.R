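test_that("chamber geometry and sensor grid are consistent", {
  ch <- apis_chamber()
  expect_equal(ch$position_min, -ch$position_max)
  expect_equal(ch$sensor_pitch, ch$length_cm / ch$n_sensors)
  centers <- sensor_centers(ch)
  expect_length(centers, 26L)
  expect_equal(centers[1], -7.4 + 0.5 * 14.8 / 26)
  expect_equal(max(abs(diff(centers)) - ch$sensor_pitch), 0)
  expect_error(apis_chamber(n_sensors = 1), "n_sensors")
  expect_error(apis_chamber(sampling_rate_hz = 0), "sampling_rate")
})

test_that("protocols have the published structure", {
  for (seed in 1:5) {
    p <- build_protocol("linalool", seed = seed)
    ev <- p$events
    expect_identical(nrow(ev), 12L)
    expect_identical(sum(ev$phase == "training"), 8L)
    expect_identical(sum(ev$phase == "test"), 4L)
    tr <- ev[ev$phase == "training", ]
    expect_identical(sum(tr$role == "CS+"), 4L)
    expect_identical(sum(tr$role == "CS-"), 4L)
    expect_true(p$training_order %in% c("ABBABAAB", "BAABABBA"))
    expect_true(p$test_order %in% c("ABBA", "BAAB"))
    # shock only on training CS+, first offset 2 s then 1 s
    shocked <- !is.na(ev$shock_onset_s)
    expect_true(all(ev$role[shocked] == "CS+" &
                      ev$phase[shocked] == "training"))
    expect_equal(ev$shock_onset_s[shocked], c(2, 1, 1, 1))
    # training sides balanced within each role
    expect_equal(sum(tr$side_index[tr$role == "CS+"]), 0)
    expect_equal(sum(tr$side_index[tr$role == "CS-"]), 0)
    # onsets spaced by duration + ITI within each phase
    expect_equal(unique(diff(ev$t_stim_s[ev$phase == "training"])),
                 p$duration_s + p$iti_s)
  }
  expect_identical(build_protocol("nonanol", seed = 3),
                   build_protocol("nonanol", seed = 3))
})

test_that("order choice is balanced over seeds", {
  orders <- vapply(1:200, function(s)
    build_protocol("linalool", seed = s)$training_order, "")
  frac <- mean(orders == "ABBABAAB")
  expect_gt(frac, 0.35)
  expect_lt(frac, 0.65)
})

test_that("trace logs round-trip exactly and deterministically", {
  rec <- simulate_cohort(1, seed = 11)[[1]]
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.trace.tsv")
  write_trace_log(rec, p1)
  back <- read_trace_log(p1)
  expect_equal(back, rec)
  # byte determinism
  p2 <- file.path(d, "b.trace.tsv")
  write_trace_log(rec, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(file.path(d, "a.events.tsv")),
                   readLines(file.path(d, "b.events.tsv")))
})

test_that("many simulated sessions round-trip exactly", {
  d <- withr::local_tempdir()
  recs <- simulate_cohort(40, seed = 5)
  for (rec in recs) {
    p <- file.path(d, paste0(rec$bee_id, ".trace.tsv"))
    write_trace_log(rec, p)
    expect_equal(read_trace_log(p), rec)
  }
})

test_that("malformed logs are rejected with the offending line", {
  rec <- simulate_cohort(1, seed = 12)[[1]]
  d <- withr::local_tempdir()
  p <- file.path(d, "x.trace.tsv")
  write_trace_log(rec, p)
  lines <- readLines(p)
  data_at <- which(lines == "t_s\tx_cm") + 5L

  out_of_range <- lines
  out_of_range[data_at] <- sub("\t.*$", "\t9.9000", out_of_range[data_at])
  writeLines(out_of_range, p)
  expect_error(read_trace_log(p), sprintf("%d.*9\\.9.*outside", data_at))

  nonmono <- readLines(file.path(d, "x.trace.tsv"))
  write_trace_log(rec, p)  # restore
  nonmono <- readLines(p)
  nonmono[data_at] <- sub("^[0-9.]+", "0.000", nonmono[data_at])
  writeLines(nonmono, p)
  expect_error(read_trace_log(p), "monotone|misspaced")

  writeLines(c("# wrong-header", lines[-1]), p)
  expect_error(read_trace_log(p), "malformed header")
})

test_that("degenerate records are refused on write", {
  rec <- simulate_cohort(1, seed = 13)[[1]]
  rec$trace <- rec$trace[0, ]
  expect_error(write_trace_log(rec, tempfile()), "empty trace")
})

test_that("seeded session matches its golden serialization", {
  # 60-s crop of the seed-1 session, frozen once from the generator
  rec <- apistrack:::crop_session(simulate_cohort(1, seed = 1)[[1]], 60)
  d <- withr::local_tempdir()
  p <- file.path(d, "golden.trace.tsv")
  write_trace_log(rec, p)
  expect_identical(readLines(p),
                   readLines(test_path("golden", "seed1.trace.tsv")))
  expect_identical(readLines(file.path(d, "golden.events.tsv")),
                   readLines(test_path("golden", "seed1.events.tsv")))
})
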