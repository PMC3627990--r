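# Samples of `trace` falling in [from, to] (closed window, 1 us slack).
window_idx <- function(trace, from, to) {
  if (from < trace$t_s[1] - 1e-6 || to > trace$t_s[nrow(trace)] + 1e-6)
    stop(sprintf("stimulus window [%.3f, %.3f] extends past the trace",
                 from, to), call. = FALSE)
  which(trace$t_s >= from - 1e-6 & trace$t_s <= to + 1e-6)
}

# Side of each sample: sign(x), with x == 0 inheriting the previous
# sample's side (`prev` seeds the first sample; the midline itself has no
# sensor, so zeros only arise in hand-made traces).
sample_sides <- function(x, prev) {
  s <- sign(x)
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- prev else prev <- s[i]
  }
  s
}

#' Detect an escape during a stimulus window
#'
#' A presentation is scored as an escape when the bee, starting on the
#' odor-injected side, crosses the chamber midline during the stimulus and
#' never returns before the window ends: formally, there is a sample time
#' from which every remaining in-window sample lies on the non-odor side.
#' The call is made on the logged 5 Hz samples only, so a single-sample
#' excursion back across the midline cancels the escape.
#'
#' @param trace Data frame `t_s`, `x_cm` (a session's logged trace).
#' @param event One event (single-row data frame or list) with `t_stim_s`,
#'   `duration_s` and `side_index`.
#' @param chamber [apis_chamber()] (bounds check only).
#' @return List with `escaped` (logical), `crossing_time` (s after odor
#'   onset of the first sample of the non-returning run; `NA` if no
#'   escape), and `start_side_ok` (`TRUE` when the bee was on the odor side
#'   at the first in-window sample; when `FALSE` — possible for
#'   training-phase events only — `escaped` is `FALSE` and the presentation
#'   should be excluded from rate summaries).
#' @export
detect_escape <- function(trace, event, chamber = apis_chamber()) {
  si <- event$side_index
  stopifnot(si %in% c(-1L, 1L))
  t0 <- event$t_stim_s
  idx <- window_idx(trace, t0, t0 + event$duration_s)
  prev_side <- if (idx[1] > 1L) {
    ps <- sign(trace$x_cm[seq_len(idx[1] - 1L)])
    ps <- ps[ps != 0]
    if (length(ps)) ps[length(ps)] else si
  } else si
  sides <- sample_sides(trace$x_cm[idx], prev_side)
  if (sides[1] != si)
    return(list(escaped = FALSE, crossing_time = NA_real_,
                start_side_ok = FALSE))
  # first index from which all remaining samples sit on the non-odor side
  on_far <- sides == -si
  run <- rev(cumprod(rev(on_far)))   # 1 where the suffix is all non-odor
  if (run[length(run)] == 0 || !any(run == 1))
    return(list(escaped = FALSE, crossing_time = NA_real_,
                start_side_ok = TRUE))
  first <- which(run == 1)[1]
  list(escaped = TRUE,
       crossing_time = trace$t_s[idx[first]] - t0,
       start_side_ok = TRUE)
}

# Dwell-collapsed knots of a position series: consecutive samples at the
# same logged position merge into one knot at the dwell's midpoint time.
dwell_knots <- function(t, x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(t = (t[starts] + t[ends]) / 2, x = r$values)
}

#' Signed walking velocity over the first 2 s of a stimulus
#'
#' Follows the dwell-time construction: consecutive samples at the same
#' logged position collapse into a single knot at the midpoint of the dwell,
#' a natural cubic spline is fitted through the knots, and the velocity is
#' the mean of the spline's derivative over the window, which by the
#' fundamental theorem of calculus is the endpoint form
#' `(s(t0 + 2) - s(t0)) / 2`. Outside the knot range the spline is extended
#' with the nearest knot value (window boundaries between samples are the
#' only place this matters). The result is signed relative to the
#' odor-injected side: movement away from the odor is negative.
#'
#' @inheritParams detect_escape
#' @param window_s Length of the velocity window (2 s).
#' @return Velocity in cm/s; 0 for a stationary bee (fewer than two
#'   distinct knots).
#' @export
estimate_velocity <- function(trace, event, chamber = apis_chamber(),
                              window_s = 2) {
  si <- event$side_index
  stopifnot(si %in% c(-1L, 1L))
  t0 <- event$t_stim_s
  idx <- window_idx(trace, t0, t0 + window_s)
  kn <- dwell_knots(trace$t_s[idx], trace$x_cm[idx])
  if (nrow(kn) < 2L) return(0)
  at <- clamp(c(t0, t0 + window_s), min(kn$t), max(kn$t))
  s <- stats::spline(kn$t, kn$x, method = "natural", xout = at)$y
  si * (s[2] - s[1]) / window_s
}

# Composite trapezoid rule on (t, x) pairs.
trapezoid <- function(t, x) sum(diff(t) * (x[-length(x)] + x[-1]) / 2)

#' Raw attractance integral of a stimulus window
#'
#' The side-signed time integral of position over the 4-s stimulus window,
#' `SI * integral of P(t) dt` from odor onset to offset, approximated with
#' the composite trapezoid rule over the logged samples. The window
#' boundaries are taken at exactly the onset and offset times, with the
#' boundary positions linearly interpolated between the flanking samples
#' (nearest sample extended if a boundary falls beyond the last sample by a
#' partial step). Positive values indicate presence on the odor side.
#'
#' @inheritParams detect_escape
#' @return Integral in cm s.
#' @export
raw_attractance_integral <- function(trace, event, chamber = apis_chamber()) {
  si <- event$side_index
  stopifnot(si %in% c(-1L, 1L))
  t0 <- event$t_stim_s
  t1 <- t0 + event$duration_s
  idx <- window_idx(trace, t0, t1)
  tt <- trace$t_s[idx]
  xx <- trace$x_cm[idx]
  # boundary positions at exactly t0 and t1
  bound <- stats::approx(trace$t_s, trace$x_cm, xout = c(t0, t1),
                         rule = 2)$y
  inner <- tt > t0 + 1e-9 & tt < t1 - 1e-9
  si * trapezoid(c(t0, tt[inner], t1), c(bound[1], xx[inner], bound[2]))
}

#' Normalize attractance integrals to the Attractance Index
#'
#' Maps the raw integrals of a scored cohort onto the dimensionless [-1, 1]
#' Attractance Index using the minimum and maximum observed integral of the
#' whole tested population (all test stimuli of all bees pooled):
#' `ai = 2 (raw - min) / (max - min) - 1`, so the population minimum maps to
#' -1 and the maximum to +1. The alternative `"symmetric"` mapping
#' `ai = raw / max(|min|, |max|)` preserves the zero point (an integral of 0
#' stays an AI of 0) at the cost of not attaining both extremes. A
#' degenerate cohort (all integrals equal) maps to 0 everywhere.
#'
#' @param cohort An `apis_cohort` score table (see [score_cohort()]) or any
#'   data frame with a `raw_integral_cm_s` column.
#' @param method `"minmax"` (default) or `"symmetric"`.
#' @return The cohort with the `ai` column filled and normalization
#'   constants stored in attributes `min_raw`, `max_raw`, `ai_norm`.
#' @export
normalize_ai <- function(cohort, method = c("minmax", "symmetric")) {
  method <- match.arg(method)
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  raw <- cohort$raw_integral_cm_s
  lo <- min(raw); hi <- max(raw)
  cohort$ai <- if (hi == lo) {
    rep(0, length(raw))
  } else if (method == "minmax") {
    2 * (raw - lo) / (hi - lo) - 1
  } else {
    raw / max(abs(lo), abs(hi))
  }
  attr(cohort, "min_raw") <- lo
  attr(cohort, "max_raw") <- hi
  attr(cohort, "ai_norm") <- method
  cohort
}

#' Classify an Attractance Index value
#'
#' An AI of 0.3 or higher is regarded as attraction; 0.1 or lower is typical
#' for avoidance; values between are indeterminate.
#'
#' @param ai Numeric vector of AI values in [-1, 1].
#' @return Character vector: `"attraction"`, `"avoidance"` or
#'   `"indeterminate"`.
#' @export
classify_response <- function(ai) {
  if (any(is.na(ai)) || any(ai < -1 - 1e-9) || any(ai > 1 + 1e-9))
    stop("ai must lie in [-1, 1]", call. = FALSE)
  ifelse(ai >= 0.3, "attraction",
         ifelse(ai <= 0.1, "avoidance", "indeterminate"))
}

#' Score a cohort of session records
#'
#' Applies [detect_escape()], [estimate_velocity()] and
#' [raw_attractance_integral()] to every test stimulus of every record,
#' then normalizes the Attractance Index once over the pooled cohort.
#' Records lacking the full set of 4 test events are skipped with a
#' warning. Rows are ordered by `bee_id`, then stimulus index.
#'
#' @param records List of `apis_session` records (e.g. from
#'   [simulate_cohort()] or [read_trace_log()]).
#' @param ai_norm Normalization mapping, see [normalize_ai()].
#' @return An `apis_cohort` data frame with one row per test stimulus:
#'   `bee_id`, `stim_index`, `trial` (1st or 2nd presentation within the CS
#'   role), `phase`, `odor`, `role`, `side_index`, `escaped`,
#'   `start_side_ok`, `crossing_time_s`, `velocity_cm_s`,
#'   `raw_integral_cm_s`, `ai`; normalization constants in attributes.
#' @export
score_cohort <- function(records, ai_norm = c("minmax", "symmetric")) {
  ai_norm <- match.arg(ai_norm)
  if (inherits(records, "apis_session")) records <- list(records)
  rows <- list()
  skipped <- 0L
  for (rec in records) {
    ev <- rec$events[rec$events$phase == "test", , drop = FALSE]
    if (nrow(ev) != 4L || anyNA(ev$side_index)) {
      warning(sprintf("skipping %s: expected 4 complete test events, got %d",
                      rec$bee_id, nrow(ev)), call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    for (k in seq_len(nrow(ev))) {
      e <- ev[k, ]
      esc <- detect_escape(rec$trace, e, rec$chamber)
      rows[[length(rows) + 1L]] <- data.frame(
        bee_id = rec$bee_id, stim_index = e$index, phase = e$phase,
        odor = e$odor, role = e$role, side_index = e$side_index,
        escaped = esc$escaped, start_side_ok = esc$start_side_ok,
        crossing_time_s = esc$crossing_time,
        velocity_cm_s = estimate_velocity(rec$trace, e, rec$chamber),
        raw_integral_cm_s = raw_attractance_integral(rec$trace, e,
                                                     rec$chamber),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(bee_id = character(), stim_index = integer(),
                      phase = character(), odor = character(),
                      role = character(), side_index = integer(),
                      escaped = logical(), start_side_ok = logical(),
                      crossing_time_s = numeric(),
                      velocity_cm_s = numeric(),
                      raw_integral_cm_s = numeric(), ai = numeric())
    attr(out, "n_skipped") <- skipped
    class(out) <- c("apis_cohort", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$bee_id, out$stim_index), , drop = FALSE]
  rownames(out) <- NULL
  # presentation number within each bee x role (1st or 2nd test trial)
  out$trial <- stats::ave(seq_len(nrow(out)),
                          out$bee_id, out$role,
                          FUN = function(i) rank(i))
  out <- out[, c("bee_id", "stim_index", "trial", "phase", "odor", "role",
                 "side_index", "escaped", "start_side_ok",
                 "crossing_time_s", "velocity_cm_s", "raw_integral_cm_s")]
  out <- normalize_ai(out, ai_norm)
  attr(out, "n_skipped") <- skipped
  class(out) <- c("apis_cohort", "data.frame")
  out
}

#' @export
print.apis_cohort <- function(x, ...) {
  cat(sprintf("<apis_cohort> %d stimuli from %d bees (ai: %s, raw range [%.2f, %.2f])\n",
              nrow(x), length(unique(x$bee_id)),
              attr(x, "ai_norm") %||% "none",
              attr(x, "min_raw") %||% NA, attr(x, "max_raw") %||% NA))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Summarize a scored cohort
#'
#' Per stimulus class and trial: escape rate with exact binomial CI, mean
#' velocity and mean AI (all responses and escape subset).
#'
#' @param object An `apis_cohort`.
#' @param ... Unused.
#' @return Data frame of per-class summaries (class `summary.apis_cohort`).
#' @export
summary.apis_cohort <- function(object, ...) {
  x <- object[object$start_side_ok, , drop = FALSE]
  grp <- interaction(x$role, x$trial, drop = TRUE)
  res <- lapply(split(x, grp), function(d) {
    cp <- clopper_pearson(sum(d$escaped), nrow(d))
    data.frame(role = d$role[1], trial = d$trial[1], n = nrow(d),
               escapes = sum(d$escaped), escape_rate = cp$rate,
               ci_low = cp$ci_low, ci_high = cp$ci_high,
               mean_velocity = mean(d$velocity_cm_s),
               mean_ai = mean(d$ai),
               mean_velocity_escapes = mean(d$velocity_cm_s[d$escaped]),
               mean_ai_escapes = mean(d$ai[d$escaped]))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$role, out$trial), ]
  rownames(out) <- NULL
  class(out) <- c("summary.apis_cohort", "data.frame")
  out
}

#' @export
print.summary.apis_cohort <- function(x, ...) {
  cat("Escape rates, velocities and AI by stimulus class:\n")
  print(as.data.frame(lapply(x, function(col)
    if (is.numeric(col)) round(col, 3) else col)))
  invisible(x)
}
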