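#' Behavioral parameters of the chamber simulator
#'
#' The simulator draws a bee's response to each test stimulus from a small
#' set of calibrated parameters. Escape probabilities and velocities refer to
#' the recall (test) phase; a drawn velocity `v` is realized so that the
#' bee's displacement over the first 2 s of the stimulus equals `2 v` cm
#' (odor-relative sign: negative is away from the injection side), which is
#' exactly what the spline velocity estimator measures.
#'
#' Defaults are calibrated to the recall statistics of a 174-bee aversive
#' conditioning experiment: 54.0% / 17.8% first-trial CS+ / CS- escape
#' rates, -2.5 cm/s mean escape-run velocity on the CS+, and population mean
#' velocities of -1.5 (CS+) and -0.2 cm/s (CS-). The non-escape drifts are
#' moment-matched to those means, e.g.
#' `v_nonescape_csplus = (-1.5 - 0.54 * (-2.5)) / 0.46`.
#'
#' @param p_escape_csplus,p_escape_csminus Probability of an escape run on a
#'   test CS+ / CS- presentation (both trials of each class).
#' @param v_escape_csplus,v_escape_csminus Mean drawn velocity (cm/s, signed
#'   toward the odor, so negative) of escape runs per class.
#' @param v_nonescape_csplus,v_nonescape_csminus Mean drift (cm/s) of
#'   non-escaping bees during the stimulus per class.
#' @param sd_velocity SD (cm/s) of the per-stimulus velocity draws.
#' @param explore_speed Free-running walk speed between stimuli, cm/s.
#' @param attraction_dwell Fraction of non-escape CS- presentations whose
#'   second half is spent at a home position in the odor-side third of the
#'   chamber (the rest dwell nearer the middle).
#' @param startle_jump Instantaneous displacement (cm) at each shock pulse
#'   during training (training is simulated but never scored).
#' @param left_bias Probability that a fresh exploration heading points
#'   left; 0.5 is symmetric.
#'
#' @return An object of class `apis_behavior_params` (a validated list).
#' @export
behavior_params <- function(p_escape_csplus = 0.540,
                            p_escape_csminus = 0.178,
                            v_escape_csplus = -2.5,
                            v_escape_csminus = -1.8,
                            v_nonescape_csplus = -0.33,
                            v_nonescape_csminus = 0.15,
                            sd_velocity = 1.0,
                            explore_speed = 2.0,
                            attraction_dwell = 0.8,
                            startle_jump = 1.5,
                            left_bias = 0.5) {
  p <- list(p_escape_csplus = p_escape_csplus,
            p_escape_csminus = p_escape_csminus,
            v_escape_csplus = v_escape_csplus,
            v_escape_csminus = v_escape_csminus,
            v_nonescape_csplus = v_nonescape_csplus,
            v_nonescape_csminus = v_nonescape_csminus,
            sd_velocity = sd_velocity,
            explore_speed = explore_speed,
            attraction_dwell = attraction_dwell,
            startle_jump = startle_jump,
            left_bias = left_bias)
  for (nm in c("p_escape_csplus", "p_escape_csminus", "attraction_dwell",
               "left_bias"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("%s must be in [0, 1]", nm), call. = FALSE)
  if (p$sd_velocity < 0) stop("sd_velocity must be >= 0", call. = FALSE)
  if (p$explore_speed < 0) stop("explore_speed must be >= 0", call. = FALSE)
  if (p$startle_jump < 0) stop("startle_jump must be >= 0", call. = FALSE)
  if (p$v_escape_csplus >= 0 || p$v_escape_csminus >= 0)
    stop("escape velocities must be negative (away from the odor)",
         call. = FALSE)
  structure(p, class = "apis_behavior_params")
}

#' @export
print.apis_behavior_params <- function(x, ...) {
  cat("<apis_behavior_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Fold an unbounded coordinate into [-half, half] as a reflecting box.
# Also returns the reflection parity (odd parity flips the heading).
fold_box <- function(w, half) {
  L <- 2 * half
  y <- (w + half) %% (2 * L)
  x <- ifelse(y < L, y - half, 3 * half - y)
  parity <- (floor((w + half) / L) %% 2) == 1
  list(x = x, parity = parity)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# --- internal path construction ------------------------------------------
# The hidden continuous path is integrated with Euler steps on a fixed grid
# (default 50 Hz) and assembled segment by segment inside an environment
# carrying the running state (position, heading, fill pointer).

new_sim_state <- function(n_grid, x0, dir0) {
  e <- new.env(parent = emptyenv())
  e$pos <- numeric(n_grid)
  e$pos[1] <- x0
  e$cur <- x0
  e$dir <- dir0
  e$i <- 1L          # index of the last filled grid point
  e
}

# Free exploration: the bee shuttles end to end, walking at explore_speed
# to a drawn waypoint (chamber ends preferred; left with probability
# left_bias) and pausing there briefly before heading off again.
fill_explore <- function(st, n, params, chamber, dt, speed_mult = 1) {
  half <- chamber$position_max
  speed <- params$explore_speed * speed_mult
  left <- n
  while (left > 0L) {
    sgn <- if (stats::runif(1) < params$left_bias) -1 else 1
    target <- sgn * stats::runif(1, 2.0, half - 0.1)
    n_need <- if (speed > 0)
      max(1L, ceiling(abs(target - st$cur) / (speed * dt))) else left
    k <- min(left, n_need)
    fill_goto(st, k, target, speed, chamber)
    left <- left - k
    if (left > 0L) {
      p <- min(left, max(1L, round(stats::runif(1, 0.3, 1.5) / dt)))
      fill_hold(st, p)
      left <- left - p
    }
  }
  invisible(st)
}

# Hold position for n steps (freezing / dwelling).
fill_hold <- function(st, n) {
  if (n > 0L) {
    st$pos[st$i + seq_len(n)] <- st$cur
    st$i <- st$i + n
  }
  invisible(st)
}

# Straight motion at signed velocity v (chamber frame) for n steps, stopped
# (not reflected) at a small wall margin.
fill_run <- function(st, n, v, chamber, margin = 0.05) {
  if (n > 0L) {
    dt_path <- st$cur + v * (st$pos_dt * seq_len(n))
    dt_path <- clamp(dt_path, chamber$position_min + margin,
                     chamber$position_max - margin)
    st$pos[st$i + seq_len(n)] <- dt_path
    st$i <- st$i + n
    st$cur <- dt_path[n]
  }
  invisible(st)
}

# Walk toward `target` at `speed`, then hold there for the remaining steps.
fill_goto <- function(st, n, target, speed, chamber) {
  if (n <= 0L) return(invisible(st))
  dtv <- st$pos_dt
  dist <- target - st$cur
  n_need <- if (speed > 0) ceiling(abs(dist) / (speed * dtv)) else Inf
  n_move <- min(n, n_need)
  if (n_move > 0L) {
    step <- sign(dist) * speed * dtv
    path <- st$cur + step * seq_len(n_move)
    if (n_need <= n) path[n_move] <- target  # land exactly on the target
    st$pos[st$i + seq_len(n_move)] <- path
    st$i <- st$i + n_move
    st$cur <- path[n_move]
  }
  fill_hold(st, n - n_move)
}

# Simulate one test stimulus window of `n` steps starting at the current
# position; returns the realized side index. Updates escape bookkeeping in
# `st$last_escape`.
fill_test_window <- function(st, n, role, params, chamber, dt) {
  x0 <- st$cur
  si <- if (x0 >= 0) 1L else -1L
  half <- chamber$position_max
  margin <- 0.05
  p_esc <- if (role == "CS+") params$p_escape_csplus else params$p_escape_csminus
  v_esc <- if (role == "CS+") params$v_escape_csplus else params$v_escape_csminus
  v_non <- if (role == "CS+") params$v_nonescape_csplus else params$v_nonescape_csminus
  escaping <- stats::runif(1) < p_esc
  n_first <- round(2 / dt)           # the 2-s velocity phase
  if (escaping) {
    lat <- stats::runif(1, 0.2, 1.0)
    v <- NA_real_
    for (try in seq_len(1000L)) {    # escape runs must move away
      cand <- stats::rnorm(1, v_esc, params$sd_velocity)
      if (cand < -0.1) { v <- cand; break }
    }
    if (is.na(v))
      stop("could not draw a negative escape velocity; check v_escape_* ",
           "and sd_velocity", call. = FALSE)
    n_lat <- round(lat / dt)
    fill_hold(st, min(n_lat, n))
    u <- 2 * abs(v) / (2 - lat)       # run speed, realizes 2 s displacement 2|v|
    n_run_a <- max(0L, n_first - n_lat)
    fill_run(st, n_run_a, -si * u, chamber)
    # after the velocity phase the run continues to a dwell point whose
    # depth grows with the drawn speed; a slow run speeds up here so that
    # the midline is always crossed well inside the window
    z2 <- si * st$cur
    far_rel <- clamp(0.5 - 2 * abs(v) + stats::runif(1, -0.5, 0.5),
                     -7.2, -1.6)
    u2 <- max(u, if (z2 > -0.45) (z2 + 0.45) / 0.8 else 0)
    n_left <- n - min(n_lat, n) - n_run_a
    fill_goto(st, n_left, si * far_rel, u2, chamber)
    st$dir <- -si
  } else {
    v <- stats::rnorm(1, v_non, params$sd_velocity)
    fill_run(st, min(n_first, n), si * v, chamber)
    # settle for the rest of the window at a home position that continues
    # the drift (so the attractance integral tracks the velocity); CS- bees
    # are pulled into the odor-side third with probability attraction_dwell
    home_rel <- if (role == "CS-") {
      if (stats::runif(1) < params$attraction_dwell)
        clamp(5.0 + 2 * v + stats::runif(1, -0.5, 0.5), 3.0, 6.9)
      else stats::runif(1, 0.3, 2.4)
    } else {
      clamp(2.6 + 2 * v + stats::runif(1, -0.5, 0.5), 0.4, 6.8)
    }
    fill_goto(st, n - min(n_first, n), si * home_rel, 2.5, chamber)
    st$dir <- if (stats::runif(1) < params$left_bias) -1 else 1
  }
  si
}

#' Simulate one conditioning session
#'
#' Runs the agent-based chamber model for a full session (training + test)
#' and returns the session record a physical chamber would have logged: the
#' 5 Hz sensor-quantized trace and the realized event table. The hidden path
#' is integrated at `internal_hz` (default 50 Hz) with Euler steps; only the
#' quantized trace is exported, so scoring never sees the hidden path.
#'
#' Behavioral repertoire: free exploration end to end between stimuli;
#' during training CS+ windows a startle jump at every shock pulse and a
#' transient speed-up (training behavior is simulated but not scored);
#' during test stimuli the odor is delivered on the side the bee occupies at
#' onset (the event's `side_index` is set accordingly) and the bee either
#' initiates an escape run after a uniform 0.2-1.0 s latency, crossing the
#' midline without return for the rest of the window, or drifts and then
#' settles at a role-dependent home position on the odor side.
#'
#' @param protocol An [build_protocol()] schedule.
#' @param params [behavior_params()].
#' @param chamber [apis_chamber()].
#' @param seed Integer seed; together with the other arguments it fully
#'   determines the returned record.
#' @param bee_id Identifier stored in the record.
#' @param internal_hz Hidden-path integration rate (must be a multiple of
#'   the sensor sampling rate).
#' @return An `apis_session` object: list with `bee_id`, `chamber`,
#'   `protocol`, `events` (test `side_index` filled in), `trace` (data frame
#'   `t_s`, `x_cm`) and `provenance`.
#' @examples
#' rec <- simulate_session(build_protocol(seed = 1), behavior_params(),
#'                         apis_chamber(), seed = 1)
#' head(rec$trace)
#' @export
simulate_session <- function(protocol, params = behavior_params(),
                             chamber = apis_chamber(), seed,
                             bee_id = sprintf("bee%06d", seed),
                             internal_hz = 50) {
  stopifnot(inherits(protocol, "apis_protocol"),
            inherits(params, "apis_behavior_params"),
            inherits(chamber, "apis_chamber"))
  dt <- 1 / internal_hz
  ratio <- internal_hz / chamber$sampling_rate_hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("internal_hz must be a multiple of the chamber sampling rate",
         call. = FALSE)
  ev <- protocol$events
  t_end <- if (nrow(ev)) max(ev$t_stim_s + ev$duration_s) + 10
           else protocol$acclimation_s + 10
  n_grid <- round(t_end / dt) + 1L
  idx_of <- function(t) round(t / dt) + 1L

  rec <- with_preserved_seed(seed, {
    st <- new_sim_state(n_grid, stats::runif(1, -1, 1),
                        if (stats::runif(1) < params$left_bias) -1 else 1)
    st$pos_dt <- dt
    side_out <- ev$side_index
    for (k in seq_len(nrow(ev))) {
      i_on <- idx_of(ev$t_stim_s[k])
      fill_explore(st, i_on - st$i, params, chamber, dt)
      n_win <- idx_of(ev$t_stim_s[k] + ev$duration_s[k]) - i_on
      if (ev$phase[k] == "training") {
        if (ev$role[k] == "CS+") {
          # shock pulse train; startle jumps and a transient speed-up
          pt <- ev$shock_onset_s[k] +
            seq(0, by = 1 / protocol$shock_pulse_rate_hz,
                length.out = ceiling(protocol$shock_duration_s *
                                       protocol$shock_pulse_rate_hz))
          pt <- pt[pt < protocol$shock_duration_s + ev$shock_onset_s[k]]
          n_ext <- min(idx_of(ev$t_stim_s[k] + max(pt) + 0.5) - i_on,
                       n_grid - i_on)
          bounds <- c(0, pt, n_ext * dt)
          for (j in seq_len(length(bounds) - 1L)) {
            n_sub <- idx_of(ev$t_stim_s[k] + bounds[j + 1]) -
              idx_of(ev$t_stim_s[k] + bounds[j])
            fill_explore(st, n_sub, params, chamber, dt,
                         speed_mult = if (j == 1) 1 else 1.5)
            if (j < length(bounds) - 1L) { # startle at the pulse
              jdir <- if (stats::runif(1) < 0.5) -1 else 1
              st$cur <- fold_box(st$cur + jdir * params$startle_jump,
                                 chamber$position_max)$x
            }
          }
        } else {
          fill_explore(st, n_win, params, chamber, dt)
        }
      } else {
        side_out[k] <- fill_test_window(st, n_win, ev$role[k], params,
                                        chamber, dt)
      }
    }
    fill_explore(st, n_grid - st$i, params, chamber, dt)
    list(pos = st$pos, side = side_out)
  })

  ev$side_index <- rec$side
  protocol$events <- ev   # realized schedule (test sides filled in)
  tr <- sensor_sample(list(t = (seq_len(n_grid) - 1L) * dt, x = rec$pos),
                      chamber)
  structure(list(
    bee_id = bee_id, chamber = chamber, protocol = protocol, events = ev,
    trace = tr,
    provenance = list(seed = as.integer(seed), generator = "apistrack-sim v1")
  ), class = "apis_session")
}

#' @export
print.apis_session <- function(x, ...) {
  cat(sprintf("<apis_session> %s: %d samples over %.1f s, %d events (%s)\n",
              x$bee_id, nrow(x$trace), max(x$trace$t_s), nrow(x$events),
              x$provenance$generator %||% "measured"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantize a continuous path through the photo sensor array
#'
#' Emulates the chamber's acquisition: the path is read at the sampling rate
#' and each position is reported as the center of the sensor interval it
#' falls in, so the quantization error is at most half the sensor pitch
#' (about 0.2846 cm for the default chamber). Logged positions are kept at
#' 4 decimals, the resolution of the trace log dialect.
#'
#' @param path Either a function of time returning positions, or a list /
#'   data frame with numeric `t` and `x` densely covering the session span
#'   (intermediate times are linearly interpolated).
#' @param chamber [apis_chamber()].
#' @param t_end Last sample time; defaults to the end of the supplied path.
#' @return Data frame `t_s`, `x_cm`: the 5 Hz quantized trace.
#' @examples
#' ch <- apis_chamber()
#' tr <- sensor_sample(function(t) 7.4 * sin(t), ch, t_end = 2)
#' max(abs(tr$x_cm - 7.4 * sin(tr$t_s))) <= ch$sensor_pitch / 2 + 5e-5
#' @export
sensor_sample <- function(path, chamber = apis_chamber(), t_end = NULL) {
  dt_s <- 1 / chamber$sampling_rate_hz
  if (is.function(path)) {
    if (is.null(t_end)) stop("t_end is required for a functional path",
                             call. = FALSE)
    ts <- seq(0, t_end, by = dt_s)
    xs <- path(ts)
  } else {
    tt <- path$t
    if (is.null(t_end)) t_end <- max(tt)
    ts <- seq(0, t_end + 1e-9, by = dt_s)
    ts <- ts[ts <= max(tt) + 1e-9]
    xs <- stats::approx(tt, path$x, xout = pmin(ts, max(tt)))$y
  }
  bad <- position_violations(xs, chamber)
  if (length(bad))
    stop("path leaves the chamber at t = ", ts[bad[1]], call. = FALSE)
  bin <- clamp(floor((xs - chamber$position_min) / chamber$sensor_pitch),
               0, chamber$n_sensors - 1)
  centers <- chamber$position_min + (bin + 0.5) * chamber$sensor_pitch
  data.frame(t_s = round(ts, 3), x_cm = round(centers, 4))
}

#' Simulate a cohort of sessions
#'
#' Runs [simulate_session()] for `n` bees with per-bee seeds derived
#' deterministically from `seed`. The CS+ odor is balanced across the cohort
#' (alternating linalool / nonanol) as are the stimulus orders (drawn per
#' bee).
#'
#' @param n Number of bees.
#' @param seed Master seed for the cohort.
#' @param params,chamber Passed to [simulate_session()].
#' @param scenario Name of a parameter preset; `"paper-recall"` is the
#'   calibrated default set ([behavior_params()]). A non-NULL `params`
#'   overrides the scenario.
#' @return List of `apis_session` records (class `apis_cohort_records`).
#' @export
simulate_cohort <- function(n, seed, params = NULL,
                            chamber = apis_chamber(),
                            scenario = "paper-recall") {
  stopifnot(n >= 1)
  if (is.null(params)) params <- scenario_params(scenario)
  seeds <- with_preserved_seed(seed, sample.int(2147483646L, n + n))
  odors <- rep(c("linalool", "nonanol"), length.out = n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    prot <- build_protocol(odors[i], seed = seeds[n + i])
    recs[[i]] <- simulate_session(prot, params, chamber, seed = seeds[i],
                                  bee_id = sprintf("bee%04d", i))
  }
  structure(recs, class = "apis_cohort_records")
}

#' @export
print.apis_cohort_records <- function(x, ...) {
  cat(sprintf("<apis_cohort_records> %d sessions\n", length(x)))
  invisible(x)
}

#' Named behavioral parameter presets
#'
#' @param name Preset name; `"paper-recall"` is the calibrated default.
#' @return A [behavior_params()] object.
#' @export
scenario_params <- function(name = "paper-recall") {
  switch(name,
         "paper-recall" = behavior_params(),
         stop("unknown scenario: ", name, call. = FALSE))
}
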