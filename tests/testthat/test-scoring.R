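test_that("escape detection follows the crossing-without-return rule", {
  ch <- apis_chamber()
  # stationary bee on the odor side: no escape
  tr <- quantized_trace(rep(5, 31))
  call <- detect_escape(tr, test_event(si = 1L), ch)
  expect_false(call$escaped)
  expect_true(call$start_side_ok)
  expect_true(is.na(call$crossing_time))

  # monotone crossing +6 -> -6 over 2 s then constant
  x <- c(rep(6, 6), 6 - 6 * seq(0.2, 2, by = 0.2), rep(-6, 10))
  call <- detect_escape(quantized_trace(x), test_event(si = 1L), ch)
  expect_true(call$escaped)
  expect_lt(abs(call$crossing_time - 1.0), 0.2 + 1e-9)

  # crossing to -2 then returning to +1: the return cancels the escape
  fx <- fixtures()
  expect_false(detect_escape(fx$recross$trace, fx$recross$events,
                             ch)$escaped)
  expect_true(detect_escape(fx$monotone_crossing$trace,
                            fx$monotone_crossing$events, ch)$escaped)

  # bee on the wrong side at onset: flagged, never an escape
  call <- detect_escape(quantized_trace(rep(-5, 31)), test_event(si = 1L),
                        ch)
  expect_false(call$escaped)
  expect_false(call$start_side_ok)

  # a sample exactly at the midline inherits the previous side
  tr0 <- data.frame(t_s = seq(0, 6, by = 0.2),
                    x_cm = c(rep(2, 10), 0, rep(2, 20)))
  expect_false(detect_escape(tr0, test_event(si = 1L), ch)$escaped)
})

test_that("escape calls agree with the brute-force suffix oracle", {
  ch <- apis_chamber()
  set.seed(424)
  for (k in 1:1000) {
    x <- cumsum(c(runif(1, -7, 7), rnorm(30, 0, 1.3)))
    x <- apistrack:::fold_box(x, 7.4)$x
    tr <- quantized_trace(x)
    ev <- test_event(si = sample(c(-1L, 1L), 1))
    got <- detect_escape(tr, ev, ch)
    want <- escape_oracle(tr, ev)
    expect_identical(got$escaped, want$escaped)
    expect_identical(got$crossing_time, want$crossing_time)
  }
})

test_that("spline velocity is exact on linear traces and symmetric", {
  ch <- apis_chamber()
  # stationary
  expect_identical(estimate_velocity(quantized_trace(rep(3, 31)),
                                     test_event(si = 1L), ch), 0)
  # linear +6 -> +2 over the 2-s window (positions off the sensor grid on
  # purpose: the estimator sees the logged values as-is)
  tr <- data.frame(t_s = seq(0, 6, by = 0.2),
                   x_cm = 6 - 2 * pmax(0, pmin(seq(0, 6, by = 0.2) - 1, 2)))
  expect_equal(estimate_velocity(tr, test_event(si = 1L), ch), -2)
  # mirror: x -> -x with SI -> -1 gives the same signed value
  trm <- tr; trm$x_cm <- -trm$x_cm
  expect_equal(estimate_velocity(trm, test_event(si = -1L), ch), -2)
  # window extending past the trace is an error
  expect_error(estimate_velocity(tr, test_event(t_stim = 5.5, si = 1L), ch),
               "past the trace")
})

test_that("quantized sinusoids give velocities near the analytic mean slope", {
  ch <- apis_chamber()
  errs <- vapply(seq(0, 2 * pi, length.out = 50), function(ph) {
    f <- function(t) 4 * sin(0.8 * t + ph)
    tr <- sensor_sample(f, ch, t_end = 10)
    est <- estimate_velocity(tr, test_event(t_stim = 3, si = 1L), ch)
    abs(est - (f(5) - f(3)) / 2)
  }, 1)
  expect_lt(mean(errs), 0.15)  # mean error within the quantization budget
  expect_lt(max(errs), 0.30)   # worst case bounded by one sensor pitch
})

test_that("the attractance integral is exact on piecewise-linear traces", {
  ch <- apis_chamber()
  tt <- seq(0, 6, by = 0.2)
  # constant at the right wall
  tr <- data.frame(t_s = tt, x_cm = rep(7.4, length(tt)))
  expect_equal(raw_attractance_integral(tr, test_event(si = 1L), ch), 29.6)
  # constant at the midline
  tr0 <- data.frame(t_s = tt, x_cm = rep(0, length(tt)))
  expect_equal(raw_attractance_integral(tr0, test_event(si = 1L), ch), 0)
  # mirror invariance through the SI product
  set.seed(11)
  xr <- cumsum(rnorm(length(tt))); xr <- 6 * xr / max(abs(xr))
  trr <- data.frame(t_s = tt, x_cm = xr)
  trm <- data.frame(t_s = tt, x_cm = -xr)
  expect_equal(raw_attractance_integral(trr, test_event(si = 1L), ch),
               raw_attractance_integral(trm, test_event(si = -1L), ch))
  # piecewise-linear with breakpoints on sample times: trapezoid is exact;
  # closed form for x(t) = a + b t on [1, 5]
  a <- 1.5; b <- -0.8
  trl <- data.frame(t_s = tt, x_cm = a + b * tt)
  expect_equal(raw_attractance_integral(trl, test_event(si = 1L), ch),
               a * 4 + b * (5^2 - 1^2) / 2)
  # off-grid stimulus onset: boundary positions linearly interpolated
  expect_equal(raw_attractance_integral(trl, test_event(t_stim = 1.13,
                                                        si = 1L), ch),
               a * 4 + b * (5.13^2 - 1.13^2) / 2)
})

test_that("AI normalization maps the population onto [-1, 1]", {
  co <- data.frame(raw_integral_cm_s = c(-10, 0, 10))
  expect_equal(normalize_ai(co)$ai, c(-1, 0, 1))
  # degenerate cohort
  expect_equal(normalize_ai(data.frame(raw_integral_cm_s = rep(3, 4)))$ai,
               rep(0, 4))
  expect_error(normalize_ai(data.frame(raw_integral_cm_s = numeric())),
               "empty")
  # monotone: Spearman(raw, ai) = 1 on any cohort
  set.seed(9)
  co <- data.frame(raw_integral_cm_s = rnorm(50, 0, 10))
  nz <- normalize_ai(co)
  expect_equal(cor(nz$raw_integral_cm_s, nz$ai, method = "spearman"), 1)
  expect_equal(attr(nz, "min_raw"), min(co$raw_integral_cm_s))
  # symmetric variant preserves zero and stays within [-1, 1]
  sy <- normalize_ai(co, method = "symmetric")
  expect_equal(sy$ai, co$raw_integral_cm_s /
                 max(abs(range(co$raw_integral_cm_s))))
  expect_true(all(abs(sy$ai) <= 1))
})

test_that("AI thresholds classify attraction and avoidance", {
  expect_identical(classify_response(0.35), "attraction")
  expect_identical(classify_response(0.3), "attraction")
  expect_identical(classify_response(0.05), "avoidance")
  expect_identical(classify_response(0.1), "avoidance")
  expect_identical(classify_response(0.2), "indeterminate")
  expect_error(classify_response(1.2), "\\[-1, 1\\]")
})

test_that("cohort scoring is complete, ordered and deterministic", {
  sc <- test_cohort_scores()
  expect_identical(nrow(sc), 174L * 4L)
  expect_identical(sc, score_cohort(test_cohort_records()))
  expect_false(is.unsorted(sc$bee_id))
  # records with missing test events are skipped with a warning
  recs <- fixtures()$cohort8
  broken <- recs[[1]]
  broken$events <- broken$events[broken$events$phase == "training", ]
  expect_warning(out <- score_cohort(c(list(broken), recs[2:3])),
                 "skipping")
  expect_identical(length(unique(out$bee_id)), 2L)
  # empty input
  expect_identical(nrow(suppressWarnings(score_cohort(list()))), 0L)
})

test_that("normalized AI spans [-1, 1] with both extremes attained", {
  sc <- test_cohort_scores()
  expect_true(all(sc$ai >= -1 & sc$ai <= 1))
  expect_equal(min(sc$ai), -1)
  expect_equal(max(sc$ai), 1)
})

test_that("reflecting the chamber and the odor sides leaves scores unchanged", {
  recs <- fixtures()$cohort8
  a <- score_cohort(recs)
  b <- score_cohort(lapply(recs, mirror_record))
  expect_equal(b$escaped, a$escaped)
  expect_equal(b$crossing_time_s, a$crossing_time_s)
  expect_equal(b$velocity_cm_s, a$velocity_cm_s)
  expect_equal(b$raw_integral_cm_s, a$raw_integral_cm_s)
  expect_equal(b$ai, a$ai)
})

test_that("escaped stimuli carry more negative velocities than non-escaped", {
  sc <- test_cohort_scores()
  expect_lt(mean(sc$velocity_cm_s[sc$escaped]),
            mean(sc$velocity_cm_s[!sc$escaped]))
})
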