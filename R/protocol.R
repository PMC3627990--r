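#' Differential conditioning session protocol
#'
#' Builds the stimulus schedule of one session: 8 training presentations in
#' one of the two pseudorandomized orders ABBABAAB / BAABABBA (A is the
#' shock-paired odor, the CS+), followed after a 5-min pause by 4 test
#' presentations in the order ABBA or BAAB. Stimuli last 4 s with a 34-s
#' inter-trial interval. During training every CS+ carries a 3-s shock train
#' (1.2 pulses/s, 200 ms pulses) starting 2 s after odor onset on the bee's
#' first CS+ and 1 s after onset on the later ones. Training-phase injection
#' sides are balanced (two left and two right per CS role); test-phase sides
#' are left `NA` because the odor is delivered on whichever side the bee
#' occupies at onset.
#'
#' @param csplus_odor Odor used as CS+, `"linalool"` or `"nonanol"`.
#' @param training_start `"A"`, `"B"`, or `"auto"`: whether the training
#'   sequence opens with the CS+ (`ABBABAAB`) or the CS- (`BAABABBA`);
#'   `"auto"` draws one at random, giving the balanced presentation.
#' @param test_start Same for the test sequence (`ABBA` vs `BAAB`).
#' @param iti_s Inter-trial interval (odor offset to next onset), seconds.
#' @param duration_s Odor stimulus duration, seconds.
#' @param acclimation_s Time before the first training stimulus, seconds.
#' @param test_delay_s Pause between last training offset and first test
#'   onset, seconds.
#' @param seed Optional integer; when given, the random choices (orders and
#'   training side assignment) are drawn from this seed without disturbing
#'   the caller's RNG stream.
#'
#' @return An object of class `apis_protocol`: a list with the resolved
#'   orders, odor assignment, timing constants, shock constants
#'   (`shock_duration_s` 3, `shock_pulse_rate_hz` 1.2, `shock_pulse_width_s`
#'   0.2, `shock_voltage` 10) and an `events` data frame with one row per
#'   stimulus: `index`, `phase` (`training` / `test`), `t_stim_s`,
#'   `duration_s`, `odor`, `role`, `side_index` (+1 right, -1 left, `NA` for
#'   test), `shock_onset_s` (seconds after odor onset, `NA` when unshocked)
#'   and `shock_dur_s`.
#' @examples
#' p <- build_protocol("linalool", seed = 1)
#' table(p$events$phase, p$events$role)
#' @export
build_protocol <- function(csplus_odor = c("linalool", "nonanol"),
                           training_start = c("auto", "A", "B"),
                           test_start = c("auto", "A", "B"),
                           iti_s = 34, duration_s = 4,
                           acclimation_s = 30, test_delay_s = 300,
                           seed = NULL) {
  csplus_odor <- match.arg(csplus_odor)
  training_start <- match.arg(training_start)
  test_start <- match.arg(test_start)
  stopifnot(iti_s > duration_s, duration_s > 0, acclimation_s >= 0,
            test_delay_s >= 0)
  csminus_odor <- setdiff(c("linalool", "nonanol"), csplus_odor)

  draw <- function() {
    if (training_start == "auto")
      training_start <<- sample(c("A", "B"), 1L)
    if (test_start == "auto")
      test_start <<- sample(c("A", "B"), 1L)
    # balanced sides within each role of the training block
    sides_a <<- sample(c(-1L, -1L, 1L, 1L))
    sides_b <<- sample(c(-1L, -1L, 1L, 1L))
  }
  sides_a <- sides_b <- NULL
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())

  training_order <- if (training_start == "A") "ABBABAAB" else "BAABABBA"
  test_order <- if (test_start == "A") "ABBA" else "BAAB"

  letters12 <- c(strsplit(training_order, "")[[1]],
                 strsplit(test_order, "")[[1]])
  role <- ifelse(letters12 == "A", "CS+", "CS-")
  odor <- ifelse(letters12 == "A", csplus_odor, csminus_odor)
  phase <- rep(c("training", "test"), c(8L, 4L))

  step <- duration_s + iti_s
  t_train <- acclimation_s + (0:7) * step
  t_test <- t_train[8] + duration_s + test_delay_s + (0:3) * step
  t_stim <- c(t_train, t_test)

  side <- rep(NA_integer_, 12L)
  side[phase == "training" & role == "CS+"] <- sides_a
  side[phase == "training" & role == "CS-"] <- sides_b

  shock_onset <- rep(NA_real_, 12L)
  shock_dur <- rep(NA_real_, 12L)
  csp_train <- which(phase == "training" & role == "CS+")
  shock_onset[csp_train] <- c(2, rep(1, length(csp_train) - 1L))
  shock_dur[csp_train] <- 3

  events <- data.frame(
    index = seq_len(12L), phase = phase, t_stim_s = t_stim,
    duration_s = duration_s, odor = odor, role = role, side_index = side,
    shock_onset_s = shock_onset, shock_dur_s = shock_dur,
    stringsAsFactors = FALSE)

  structure(list(
    csplus_odor = csplus_odor, csminus_odor = csminus_odor,
    training_order = training_order, test_order = test_order,
    iti_s = iti_s, duration_s = duration_s,
    acclimation_s = acclimation_s, test_delay_s = test_delay_s,
    shock_duration_s = 3, shock_pulse_rate_hz = 1.2,
    shock_pulse_width_s = 0.2, shock_voltage = 10,
    events = events
  ), class = "apis_protocol")
}

#' @export
print.apis_protocol <- function(x, ...) {
  cat(sprintf("<apis_protocol> CS+ = %s; training %s, test %s; ITI %g s\n",
              x$csplus_odor, x$training_order, x$test_order, x$iti_s))
  invisible(x)
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
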