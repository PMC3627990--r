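TRACE_HEADER <- "# apistrack-trace v1"

# Metadata keys written to the trace log, in fixed order (deterministic
# serialization).
meta_keys <- function() c(
  "bee_id", "seed", "generator", "csplus_odor", "csminus_odor",
  "training_order", "test_order", "iti_s", "duration_s", "acclimation_s",
  "test_delay_s", "shock_duration_s", "shock_pulse_rate_hz",
  "shock_pulse_width_s", "shock_voltage", "length_cm", "width_cm",
  "depth_cm", "n_sensors", "sampling_rate_hz")

num_str <- function(x) {
  # shortest exact decimal; metadata values are simple decimals
  s <- sub("0+$", "", sprintf("%.6f", x))
  sub("\\.$", "", s)
}

#' Write a session record to a trace + event log pair
#'
#' Serializes an `apis_session` deterministically: a trace TSV with the
#' header line `# apistrack-trace v1`, `#key<TAB>value` metadata lines (bee
#' id, seed, protocol and chamber fields, fixed order), a `t_s<TAB>x_cm`
#' column header and one sample per line (`t` at 3 decimals, `x` at 4); and
#' an event TSV with columns `index phase t_stim_s duration_s odor role
#' side_index shock_onset_s shock_dur_s` (`NA` for absent shock fields).
#' Writing the same record twice produces identical bytes, and
#' [read_trace_log()] restores the record exactly.
#'
#' @param record An `apis_session` (see [simulate_session()]).
#' @param path Trace file path; by convention `<stem>.trace.tsv`.
#' @param events_path Event file path; defaults to the trace path with
#'   `.trace.tsv` replaced by `.events.tsv` (or `.events.tsv` appended).
#' @return `path`, invisibly.
#' @export
write_trace_log <- function(record, path, events_path = NULL) {
  stopifnot(inherits(record, "apis_session"))
  if (is.null(record$trace) || nrow(record$trace) == 0L)
    stop("record has an empty trace; nothing to serialize", call. = FALSE)
  if (is.null(events_path)) events_path <- default_events_path(path)
  ch <- record$chamber; pr <- record$protocol
  meta <- c(
    bee_id = record$bee_id,
    seed = as.character(record$provenance$seed %||% "NA"),
    generator = record$provenance$generator %||% "measured",
    csplus_odor = pr$csplus_odor, csminus_odor = pr$csminus_odor,
    training_order = pr$training_order, test_order = pr$test_order,
    iti_s = num_str(pr$iti_s), duration_s = num_str(pr$duration_s),
    acclimation_s = num_str(pr$acclimation_s),
    test_delay_s = num_str(pr$test_delay_s),
    shock_duration_s = num_str(pr$shock_duration_s),
    shock_pulse_rate_hz = num_str(pr$shock_pulse_rate_hz),
    shock_pulse_width_s = num_str(pr$shock_pulse_width_s),
    shock_voltage = num_str(pr$shock_voltage),
    length_cm = num_str(ch$length_cm), width_cm = num_str(ch$width_cm),
    depth_cm = num_str(ch$depth_cm), n_sensors = as.character(ch$n_sensors),
    sampling_rate_hz = num_str(ch$sampling_rate_hz))
  lines <- c(
    TRACE_HEADER,
    sprintf("#%s\t%s", meta_keys(), unname(meta[meta_keys()])),
    "t_s\tx_cm",
    sprintf("%.3f\t%.4f", record$trace$t_s, record$trace$x_cm))
  writeLines(lines, path)
  ev <- record$events
  fmt_na <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  ev_lines <- c(
    "index\tphase\tt_stim_s\tduration_s\todor\trole\tside_index\tshock_onset_s\tshock_dur_s",
    sprintf("%d\t%s\t%.3f\t%.3f\t%s\t%s\t%s\t%s\t%s",
            ev$index, ev$phase, ev$t_stim_s, ev$duration_s, ev$odor, ev$role,
            ifelse(is.na(ev$side_index), "NA",
                   sprintf("%d", ev$side_index)),
            fmt_na(ev$shock_onset_s), fmt_na(ev$shock_dur_s)))
  writeLines(ev_lines, events_path)
  invisible(path)
}

default_events_path <- function(path) {
  if (grepl("\\.trace\\.tsv$", path))
    sub("\\.trace\\.tsv$", ".events.tsv", path)
  else paste0(path, ".events.tsv")
}

io_fail <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

#' Read a session record from a trace + event log pair
#'
#' Parses the dialect written by [write_trace_log()], validating as it
#' goes: the header line must match exactly, timestamps must be strictly
#' increasing with spacing `1/sampling_rate` (within 1 ms), and every
#' position must lie inside the chamber. Any violation is rejected with the
#' offending line number; nothing is silently coerced.
#'
#' @param path Trace file path.
#' @param events_path Event file path (same default convention as
#'   [write_trace_log()]).
#' @return An `apis_session` record.
#' @export
read_trace_log <- function(path, events_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(events_path)) events_path <- default_events_path(path)
  if (!file.exists(events_path))
    stop("no such event file: ", events_path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != TRACE_HEADER)
    io_fail(path, 1L, paste0("malformed header (expected '", TRACE_HEADER, "')"))
  i <- 2L
  meta <- character()
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
    if (length(kv) != 2L) io_fail(path, i, "malformed metadata line")
    meta[kv[1]] <- kv[2]
    i <- i + 1L
  }
  if (i > length(lines) || lines[i] != "t_s\tx_cm")
    io_fail(path, i, "missing 't_s\\tx_cm' column header")
  need <- setdiff(meta_keys(), names(meta))
  if (length(need))
    io_fail(path, 2L, paste("missing metadata keys:",
                            paste(need, collapse = ", ")))
  chamber <- apis_chamber(
    length_cm = as.numeric(meta["length_cm"]),
    width_cm = as.numeric(meta["width_cm"]),
    depth_cm = as.numeric(meta["depth_cm"]),
    n_sensors = as.integer(meta["n_sensors"]),
    sampling_rate_hz = as.numeric(meta["sampling_rate_hz"]))

  first_data <- i + 1L
  body <- lines[seq.int(first_data, length(lines))]
  if (!length(body)) io_fail(path, first_data, "empty trace body")
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    io_fail(path, first_data + which(nf != 2L)[1] - 1L,
            "expected two tab-separated fields")
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  t_s <- suppressWarnings(as.numeric(m[, 1]))
  x_cm <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(t_s))
    io_fail(path, first_data + which(is.na(t_s))[1] - 1L, "non-numeric t_s")
  bad_x <- which(is.na(x_cm) & m[, 2] != "NaN")
  if (length(bad_x))
    io_fail(path, first_data + bad_x[1] - 1L, "non-numeric x_cm")
  dt_exp <- 1 / chamber$sampling_rate_hz
  dts <- diff(t_s)
  bad_t <- which(dts <= 0 | abs(dts - dt_exp) > 1e-3)
  if (length(bad_t))
    io_fail(path, first_data + bad_t[1], sprintf(
      "non-monotone or misspaced timestamp (expected step %.3f s)", dt_exp))
  bad_pos <- position_violations(x_cm, chamber)
  if (length(bad_pos))
    io_fail(path, first_data + bad_pos[1] - 1L, sprintf(
      "position %.4f cm outside chamber [%.4f, %.4f]",
      x_cm[bad_pos[1]], chamber$position_min, chamber$position_max))

  events <- read_event_log(events_path)
  span_ok <- events$t_stim_s >= t_s[1] &
    events$t_stim_s + events$duration_s <= t_s[length(t_s)] + 1e-9
  if (!all(span_ok))
    stop(sprintf("%s: event %d window lies outside the trace time span",
                 events_path, events$index[which(!span_ok)[1]]),
         call. = FALSE)

  protocol <- structure(list(
    csplus_odor = unname(meta["csplus_odor"]),
    csminus_odor = unname(meta["csminus_odor"]),
    training_order = unname(meta["training_order"]),
    test_order = unname(meta["test_order"]),
    iti_s = as.numeric(meta["iti_s"]),
    duration_s = as.numeric(meta["duration_s"]),
    acclimation_s = as.numeric(meta["acclimation_s"]),
    test_delay_s = as.numeric(meta["test_delay_s"]),
    shock_duration_s = as.numeric(meta["shock_duration_s"]),
    shock_pulse_rate_hz = as.numeric(meta["shock_pulse_rate_hz"]),
    shock_pulse_width_s = as.numeric(meta["shock_pulse_width_s"]),
    shock_voltage = as.numeric(meta["shock_voltage"]),
    events = events), class = "apis_protocol")

  seed <- if (meta["seed"] == "NA") NULL else as.integer(meta["seed"])
  structure(list(
    bee_id = unname(meta["bee_id"]), chamber = chamber, protocol = protocol,
    events = events, trace = data.frame(t_s = t_s, x_cm = x_cm),
    provenance = list(seed = seed, generator = unname(meta["generator"]))
  ), class = "apis_session")
}

read_event_log <- function(path) {
  header <- "index\tphase\tt_stim_s\tduration_s\todor\trole\tside_index\tshock_onset_s\tshock_dur_s"
  lines <- readLines(path)
  if (!length(lines) || lines[1] != header)
    io_fail(path, 1L, "malformed event log header")
  df <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                          na.strings = "NA")
  for (col in c("t_stim_s", "duration_s", "shock_onset_s", "shock_dur_s")) {
    if (is.logical(df[[col]])) df[[col]] <- as.numeric(df[[col]])
    if (!is.numeric(df[[col]]))
      io_fail(path, 2L, paste("non-numeric column", col))
  }
  df$index <- as.integer(df$index)
  df$side_index <- as.integer(df$side_index)
  bad_si <- which(!is.na(df$side_index) & !(df$side_index %in% c(-1L, 1L)))
  if (length(bad_si))
    io_fail(path, bad_si[1] + 1L, "side_index must be -1 or +1")
  bad_role <- which(!(df$role %in% c("CS+", "CS-")))
  if (length(bad_role))
    io_fail(path, bad_role[1] + 1L, "role must be CS+ or CS-")
  df
}
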