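#' Write a scored cohort to a TSV file
#'
#' Deterministic serialization of an [score_cohort()] table: `#` header
#' lines carry the AI normalization constants, followed by tab-separated
#' columns `bee_id, stim_index, phase, odor, role, side_index, escaped,
#' crossing_time_s, velocity_cm_s, raw_integral_cm_s, ai`.
#'
#' @param cohort An `apis_cohort`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(cohort, path) {
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.5f", x))
  lines <- c(
    sprintf("#ai_norm\t%s", attr(cohort, "ai_norm") %||% "none"),
    sprintf("#min_raw\t%s", num(attr(cohort, "min_raw") %||% NA_real_)),
    sprintf("#max_raw\t%s", num(attr(cohort, "max_raw") %||% NA_real_)),
    paste(c("bee_id", "stim_index", "phase", "odor", "role", "side_index",
            "escaped", "crossing_time_s", "velocity_cm_s",
            "raw_integral_cm_s", "ai"), collapse = "\t"))
  if (nrow(cohort))
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
      cohort$bee_id, cohort$stim_index, cohort$phase, cohort$odor,
      cohort$role, cohort$side_index, as.integer(cohort$escaped),
      num(cohort$crossing_time_s), num(cohort$velocity_cm_s),
      num(cohort$raw_integral_cm_s), num(cohort$ai)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scored cohort written by [write_scores()]
#'
#' @param path Scores TSV file.
#' @return An `apis_cohort` data frame (with the `trial` column
#'   reconstructed from the stimulus order).
#' @export
read_scores <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t", fixed = TRUE))
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE, na.strings = "NA")
  df$escaped <- as.logical(df$escaped)
  df$trial <- stats::ave(seq_len(nrow(df)), df$bee_id, df$role,
                         FUN = function(i) rank(i))
  kv <- stats::setNames(meta[, 2], meta[, 1])
  attr(df, "ai_norm") <- unname(kv["ai_norm"])
  attr(df, "min_raw") <- as.numeric(kv["min_raw"])
  attr(df, "max_raw") <- as.numeric(kv["max_raw"])
  class(df) <- c("apis_cohort", "data.frame")
  df
}

#' Inferential summary of a scored cohort
#'
#' The full statistical layer over a scored cohort: exact binomial escape
#' rates per stimulus class (1st/2nd CS+ and CS-), proportion and McNemar
#' comparisons between classes (McNemar both per trial and per bee pooled,
#' the pairing the per-bee test design admits), bootstrapped Spearman
#' correlations between velocity, escape and AI, and cluster-bootstrap
#' group comparisons of velocity and AI by stimulus class (all responses
#' and the escape subset).
#'
#' @param cohort An `apis_cohort` (scored, AI normalized).
#' @param n_boot Bootstrap resamples for correlations and group means.
#' @param seed Seed for all resampling in this summary.
#' @return A nested list (class `apis_cohort_stats`) ready for JSON
#'   serialization; undefined entries are replaced by
#'   `list(degenerate = TRUE, reason = ...)`.
#' @export
cohort_stats <- function(cohort, n_boot = 2000, seed = 7) {
  x <- cohort[cohort$start_side_ok %||% TRUE, , drop = FALSE]
  if (is.null(x$trial))
    x$trial <- stats::ave(seq_len(nrow(x)), x$bee_id, x$role,
                          FUN = function(i) rank(i))
  x$class <- paste0(x$role, x$trial)
  safe <- function(expr) tryCatch(expr, error = function(e)
    list(degenerate = TRUE, reason = conditionMessage(e)))
  rate_of <- function(d) {
    r <- clopper_pearson(sum(d$escaped), nrow(d))
    list(k = r$k, n = r$n, rate = r$rate, ci_low = r$ci_low,
         ci_high = r$ci_high)
  }
  rates <- lapply(split(x, x$class), function(d) safe(rate_of(d)))

  by_bee <- function(cls) {
    d <- x[x$class == cls, ]
    stats::setNames(d$escaped, d$bee_id)
  }
  pooled <- function(role) {
    d <- x[x$role == role, ]
    vapply(split(d$escaped, d$bee_id), any, TRUE)
  }
  mcnemar_pair <- function(a, b) {
    common <- intersect(names(a), names(b))
    bb <- sum(a[common] & !b[common]); cc <- sum(!a[common] & b[common])
    safe(mcnemar_test(bb, cc))
  }
  k_of <- function(cls) sum(x$escaped[x$class == cls])
  n_of <- function(cls) sum(x$class == cls)
  tests <- list(
    prop_csp1_vs_csm1 = safe(two_proportion_test(
      k_of("CS+1"), n_of("CS+1"), k_of("CS-1"), n_of("CS-1"))),
    prop_csp_vs_csm_both = safe(two_proportion_test(
      sum(x$escaped[x$role == "CS+"]), sum(x$role == "CS+"),
      sum(x$escaped[x$role == "CS-"]), sum(x$role == "CS-"))),
    mcnemar_csp1_vs_csm1 = mcnemar_pair(by_bee("CS+1"), by_bee("CS-1")),
    mcnemar_csp2_vs_csm2 = mcnemar_pair(by_bee("CS+2"), by_bee("CS-2")),
    mcnemar_csp1_vs_csp2 = mcnemar_pair(by_bee("CS+1"), by_bee("CS+2")),
    mcnemar_pooled_csp_vs_csm = mcnemar_pair(pooled("CS+"), pooled("CS-")))

  cor_of <- function(a, b) {
    r <- spearman_bootstrap(a, b, n_boot = n_boot, seed = seed)
    r[c("rho", "se", "n")]
  }
  correlations <- list(
    velocity_escape = safe(cor_of(x$velocity_cm_s, x$escaped)),
    ai_escape = safe(cor_of(x$ai, x$escaped)),
    velocity_ai = safe(cor_of(x$velocity_cm_s, x$ai)))

  gc_of <- function(d, field) {
    g <- cluster_bootstrap_means(d, field, "class", "bee_id",
                                 n_boot = n_boot, seed = seed)
    list(groups = g$groups, p_overlap = g$p_overlap, n_boot = g$n_boot)
  }
  esc <- x[x$escaped, , drop = FALSE]
  groups <- list(
    velocity_all = safe(gc_of(x, "velocity_cm_s")),
    ai_all = safe(gc_of(x, "ai")),
    velocity_escapes = safe(gc_of(esc, "velocity_cm_s")),
    ai_escapes = safe(gc_of(esc, "ai")))

  structure(list(
    n_bees = length(unique(x$bee_id)), n_stimuli = nrow(x),
    ai_norm = attr(cohort, "ai_norm") %||% "none",
    min_raw = attr(cohort, "min_raw") %||% NA_real_,
    max_raw = attr(cohort, "max_raw") %||% NA_real_,
    rates = rates, tests = tests, correlations = correlations,
    group_comparisons = groups,
    settings = list(n_boot = n_boot, seed = seed)
  ), class = "apis_cohort_stats")
}

#' @export
print.apis_cohort_stats <- function(x, ...) {
  cat(sprintf("<apis_cohort_stats> %d bees, %d stimuli\n", x$n_bees,
              x$n_stimuli))
  for (nm in names(x$rates)) {
    r <- x$rates[[nm]]
    if (!isTRUE(r$degenerate))
      cat(sprintf("  %s escape rate %d/%d = %.3f [%.3f, %.3f]\n", nm,
                  r$k, r$n, r$rate, r$ci_low, r$ci_high))
  }
  for (nm in names(x$correlations)) {
    r <- x$correlations[[nm]]
    if (!isTRUE(r$degenerate))
      cat(sprintf("  rho %s = %.3f (se %.3f)\n", nm, r$rho, r$se))
  }
  invisible(x)
}

# ---- run configuration ---------------------------------------------------

#' Resolve a pipeline run configuration
#'
#' Fills defaults and type-checks overrides for [run_pipeline()]. A config
#' is a named list (or YAML file) with any of: `scenario`, `n`, `seed`,
#' `out_dir`, `ai_norm`, `n_boot`, `stats_seed`, and `chamber` (a named
#' list of [apis_chamber()] arguments).
#'
#' @param config Named list or path to a YAML file.
#' @return Validated config list (class `apis_run_config`).
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(scenario = "paper-recall", n = 174L, seed = 1L,
                   out_dir = "apistrack-run", ai_norm = "minmax",
                   n_boot = 2000L, stats_seed = 7L, chamber = list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (!is.numeric(cfg$n) || cfg$n < 1) stop("n must be >= 1", call. = FALSE)
  if (!cfg$ai_norm %in% c("minmax", "symmetric"))
    stop("ai_norm must be minmax or symmetric", call. = FALSE)
  bad <- setdiff(names(cfg$chamber), names(formals(apis_chamber)))
  if (length(bad))
    stop("unknown chamber overrides: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg$n <- as.integer(cfg$n); cfg$seed <- as.integer(cfg$seed)
  cfg$n_boot <- as.integer(cfg$n_boot)
  cfg$stats_seed <- as.integer(cfg$stats_seed)
  structure(cfg, class = c("apis_run_config", "list"))
}

#' Run the full pipeline: simulate, score, analyse, report
#'
#' One-shot orchestration. Creates `out_dir` containing `traces/` (one
#' trace + event log pair per bee), `scores.tsv`, `stats.json`,
#' `report.html`, `run.log` and the resolved `config.yaml`. Everything
#' except the timestamps in `run.log` is byte-identical across runs with
#' the same configuration.
#'
#' @param config See [run_config()].
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "traces"), showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  cat("", file = logf)
  logit <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = logf, sep = "", append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  logit("apistrack %s | scenario=%s n=%d seed=%d",
        as.character(utils::packageVersion("apistrack")), cfg$scenario,
        cfg$n, cfg$seed)

  chamber <- do.call(apis_chamber, cfg$chamber)
  recs <- stage("simulate", {
    r <- simulate_cohort(cfg$n, cfg$seed, chamber = chamber,
                         scenario = cfg$scenario)
    for (rec in r)
      write_trace_log(rec, file.path(cfg$out_dir, "traces",
                                     paste0(rec$bee_id, ".trace.tsv")))
    r
  })
  logit("simulated %d sessions", length(recs))

  sc <- stage("score", {
    s <- score_cohort(recs, ai_norm = cfg$ai_norm)
    write_scores(s, file.path(cfg$out_dir, "scores.tsv"))
    s
  })
  logit("scored %d stimuli; ai normalization %s over [%.3f, %.3f]",
        nrow(sc), attr(sc, "ai_norm"), attr(sc, "min_raw"),
        attr(sc, "max_raw"))

  stt <- stage("stats", {
    s <- cohort_stats(sc, n_boot = cfg$n_boot, seed = cfg$stats_seed)
    jsonlite::write_json(unclass(s), file.path(cfg$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    s
  })
  logit("stats written (n_boot=%d)", cfg$n_boot)

  stage("report", render_report(stt, file.path(cfg$out_dir, "report.html")))
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))
  logit("report rendered; run complete")
  invisible(cfg$out_dir)
}

#' One-shot reproduction of the recall-phase analysis
#'
#' Convenience wrapper: [run_pipeline()] with the calibrated scenario and a
#' 174-bee cohort.
#'
#' @param out_dir Output directory.
#' @param seed Cohort seed.
#' @param n Cohort size.
#' @return Run directory, invisibly.
#' @export
reproduce_recall <- function(out_dir = "apistrack-recall", seed = 1,
                             n = 174) {
  run_pipeline(list(scenario = "paper-recall", n = n, seed = seed,
                    out_dir = out_dir))
}

# ---- HTML report (inline SVG; no binary output) --------------------------

svg_bars <- function(labels, values, lo, hi, ylab, ylim, title,
                     width = 460, height = 300) {
  n <- length(values)
  pad_l <- 56; pad_b <- 40; pad_t <- 28
  pw <- width - pad_l - 16; ph <- height - pad_t - pad_b
  sy <- function(v) pad_t + ph * (ylim[2] - v) / (ylim[2] - ylim[1])
  bw <- pw / (1.6 * n + 0.6)
  bx <- function(i) pad_l + (0.6 + 1.6 * (i - 1)) * bw
  el <- character()
  ticks <- pretty(ylim, 5)
  ticks <- ticks[ticks >= ylim[1] & ticks <= ylim[2]]
  for (tk in ticks)
    el <- c(el,
            sprintf('<line x1="%d" y1="%.1f" x2="%d" y2="%.1f" stroke="#ddd"/>',
                    pad_l, sy(tk), width - 16, sy(tk)),
            sprintf('<text x="%d" y="%.1f" font-size="10" text-anchor="end">%g</text>',
                    pad_l - 6, sy(tk) + 3, tk))
  zero <- max(min(0, ylim[2]), ylim[1])
  for (i in seq_len(n)) {
    y0 <- sy(zero); y1 <- sy(values[i])
    el <- c(el, sprintf(
      '<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="#7a9cc6"/>',
      bx(i), min(y0, y1), bw, abs(y0 - y1)))
    if (!is.na(lo[i]) && !is.na(hi[i]))
      el <- c(el,
              sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#333"/>',
                      bx(i) + bw / 2, sy(lo[i]), bx(i) + bw / 2, sy(hi[i])),
              sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#333"/>',
                      bx(i) + bw * 0.3, sy(lo[i]), bx(i) + bw * 0.7, sy(lo[i])),
              sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#333"/>',
                      bx(i) + bw * 0.3, sy(hi[i]), bx(i) + bw * 0.7, sy(hi[i])))
    el <- c(el, sprintf(
      '<text x="%.1f" y="%d" font-size="11" text-anchor="middle">%s</text>',
      bx(i) + bw / 2, height - pad_b + 16, labels[i]))
  }
  paste0(
    sprintf('<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
            width, height),
    sprintf('<text x="%d" y="16" font-size="13" font-weight="bold">%s</text>',
            pad_l, title),
    sprintf('<text x="14" y="%.1f" font-size="11" transform="rotate(-90 14 %.1f)" text-anchor="middle">%s</text>',
            pad_t + ph / 2, pad_t + ph / 2, ylab),
    paste(el, collapse = ""),
    sprintf('<line x1="%d" y1="%.1f" x2="%d" y2="%.1f" stroke="#000"/>',
            pad_l, sy(zero), width - 16, sy(zero)),
    "</svg>")
}

render_report <- function(stt, path) {
  cls_order <- c("CS+1", "CS+2", "CS-1", "CS-2")
  rates <- stt$rates[intersect(cls_order, names(stt$rates))]
  ok <- !vapply(rates, function(r) isTRUE(r$degenerate), TRUE)
  parts <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
             "<title>apistrack report</title></head><body>",
             "<h1>Recall-phase report</h1>")
  if (any(ok)) {
    r <- rates[ok]
    parts <- c(parts, svg_bars(
      names(r), 100 * vapply(r, `[[`, 1, "rate"),
      100 * vapply(r, `[[`, 1, "ci_low"), 100 * vapply(r, `[[`, 1, "ci_high"),
      "escape rate (%)", c(0, 100),
      "Escape rates by stimulus class (95% CP CI)"))
  }
  for (panel in c("velocity_all", "ai_all", "velocity_escapes",
                  "ai_escapes")) {
    g <- stt$group_comparisons[[panel]]
    if (isTRUE(g$degenerate)) {
      parts <- c(parts, sprintf("<p>%s: degenerate (%s)</p>", panel,
                                g$reason))
      next
    }
    gr <- g$groups
    ylab <- if (grepl("velocity", panel)) "velocity (cm/s)" else "AI"
    ylim <- if (grepl("velocity", panel)) c(-4, 2) else c(-1, 1)
    parts <- c(parts, svg_bars(
      gr$group, gr$mean, gr$ci_low, gr$ci_high, ylab, ylim,
      sprintf("%s (cluster bootstrap 95%%)", gsub("_", " ", panel))))
  }
  co <- stt$correlations
  rows <- vapply(names(co), function(nm) {
    r <- co[[nm]]
    if (isTRUE(r$degenerate))
      sprintf("<tr><td>%s</td><td colspan='2'>degenerate</td></tr>", nm)
    else sprintf("<tr><td>%s</td><td>%.3f</td><td>%.3f</td></tr>", nm,
                 r$rho, r$se)
  }, "")
  parts <- c(parts,
             "<h2>Rank correlations</h2>",
             "<table border='1' cellpadding='4'><tr><th>pair</th><th>rho</th><th>bootstrap se</th></tr>",
             rows, "</table>",
             sprintf("<p>AI normalization: %s over raw range [%.3f, %.3f]; %d bees, %d stimuli.</p>",
                     stt$ai_norm, stt$min_raw, stt$max_raw, stt$n_bees,
                     stt$n_stimuli),
             "</body></html>")
  writeLines(parts, path)
  invisible(path)
}

# ---- fixtures ------------------------------------------------------------

#' Construct the hand-built and seeded fixtures used by the test suite
#'
#' Returns hand-constructed single-stimulus session records exercising the
#' escape definition (`stationary`, `monotone_crossing`, `recross`) plus a
#' small simulated cohort (`cohort8`). Regeneration with the same seed
#' reproduces the fixtures exactly.
#'
#' @param seed Seed for the simulated part.
#' @return Named list of fixtures.
#' @export
make_fixtures <- function(seed = 1) {
  ch <- apis_chamber()
  mk <- function(bee_id, xs, si) {
    n <- length(xs)
    ev <- data.frame(index = 1L, phase = "test", t_stim_s = 1.0,
                     duration_s = 4, odor = "linalool", role = "CS+",
                     side_index = as.integer(si), shock_onset_s = NA_real_,
                     shock_dur_s = NA_real_, stringsAsFactors = FALSE)
    prot <- build_protocol("linalool", "A", "A", seed = seed)
    prot$events <- ev
    structure(list(
      bee_id = bee_id, chamber = ch, protocol = prot, events = ev,
      trace = data.frame(t_s = round(seq(0, by = 0.2,
                                         length.out = n), 3),
                         x_cm = round(xs, 4)),
      provenance = list(seed = as.integer(seed),
                        generator = "apistrack-fixture v1")
    ), class = "apis_session")
  }
  quant <- function(x) {
    bin <- clamp(floor((x - ch$position_min) / ch$sensor_pitch), 0,
                 ch$n_sensors - 1)
    ch$position_min + (bin + 0.5) * ch$sensor_pitch
  }
  n <- 31  # 6 s at 5 Hz covers the 1 s + 4 s window with margin
  stationary <- mk("stationary", quant(rep(5, n)), +1)
  cross_path <- quant(clamp(6 - 2.4 * pmax(0, seq(0, 6, by = 0.2) - 1),
                            -6, 6))
  monotone <- mk("monotone_crossing", cross_path, +1)
  t_rel <- seq(0, 6, by = 0.2) - 1
  re_path <- quant(ifelse(t_rel < 0, 4,
                          ifelse(t_rel < 1.4, 4 - 5 * t_rel,
                                 ifelse(t_rel < 2.8, -3 + 4 * (t_rel - 1.4),
                                        2.6))))
  recross <- mk("recross", re_path, +1)
  list(stationary = stationary, monotone_crossing = monotone,
       recross = recross,
       cohort8 = simulate_cohort(8, seed = seed))
}

# Crop a session record to its first `t_max` seconds (used for compact
# golden-file fixtures); events outside the cropped span are dropped.
crop_session <- function(record, t_max) {
  keep <- record$trace$t_s <= t_max + 1e-9
  record$trace <- record$trace[keep, , drop = FALSE]
  rownames(record$trace) <- NULL
  ev_keep <- record$events$t_stim_s + record$events$duration_s <= t_max
  record$events <- record$events[ev_keep, , drop = FALSE]
  rownames(record$events) <- NULL
  record$protocol$events <- record$events
  record
}
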