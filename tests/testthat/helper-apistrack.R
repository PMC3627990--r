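# Shared fixtures, computed once per test run and cached.

.apis_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.apis_test_cache[[key]]))
    assign(key, force(expr), envir = .apis_test_cache)
  .apis_test_cache[[key]]
}

# Seeds fixed up front for the whole suite.
TEST_SEED <- 7001L

# One scored 174-bee cohort at the calibrated defaults.
test_cohort_records <- function() {
  cached("recs174", simulate_cohort(174, seed = TEST_SEED))
}

test_cohort_scores <- function() {
  cached("scores174", score_cohort(test_cohort_records()))
}

# Twenty scored replicate cohorts (the first one is the test cohort above).
replicate_scores <- function() {
  cached("reps", lapply(0:19, function(i)
    score_cohort(simulate_cohort(174, seed = TEST_SEED + i))))
}

fixtures <- function() cached("fixtures", make_fixtures(seed = 1))

# A single-stimulus event helper for hand-built traces.
test_event <- function(t_stim = 1, si = 1L, duration = 4) {
  list(index = 1L, phase = "test", t_stim_s = t_stim,
       duration_s = duration, side_index = as.integer(si))
}

# Hand-built trace on the sensor grid: quantize a path to sensor centers.
quantized_trace <- function(x, chamber = apis_chamber(), dt = 0.2) {
  bin <- pmin(pmax(floor((x - chamber$position_min) / chamber$sensor_pitch),
                   0), chamber$n_sensors - 1)
  data.frame(t_s = round(seq(0, by = dt, length.out = length(x)), 3),
             x_cm = round(chamber$position_min +
                            (bin + 0.5) * chamber$sensor_pitch, 4))
}

# Brute-force escape oracle: scan every suffix of the window for an
# all-non-odor-side run (independent of the cumprod implementation).
escape_oracle <- function(trace, event) {
  si <- event$side_index
  idx <- which(trace$t_s >= event$t_stim_s - 1e-6 &
                 trace$t_s <= event$t_stim_s + event$duration_s + 1e-6)
  x <- trace$x_cm[idx]
  sides <- sign(x)
  prev <- si
  for (i in seq_along(sides)) {
    if (sides[i] == 0) sides[i] <- prev else prev <- sides[i]
  }
  if (sides[1] != si)
    return(list(escaped = FALSE, crossing_time = NA_real_))
  for (k in seq_along(sides)) {
    if (all(sides[k:length(sides)] == -si))
      return(list(escaped = TRUE,
                  crossing_time = trace$t_s[idx[k]] - event$t_stim_s))
  }
  list(escaped = FALSE, crossing_time = NA_real_)
}

# Mirror a session record through the chamber midline.
mirror_record <- function(rec) {
  rec$trace$x_cm <- -rec$trace$x_cm
  rec$events$side_index <- -rec$events$side_index
  rec$protocol$events <- rec$events
  rec
}
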