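#' Exact (Clopper-Pearson) binomial rate summary
#'
#' Response rate with the exact confidence interval obtained by inverting
#' the binomial tails. The lower bound is 0 when `k = 0` and the upper
#' bound 1 when `k = n`.
#'
#' @param k Number of responders.
#' @param n Number tested.
#' @param level Confidence level (default 0.95).
#' @return List of class `apis_rate`: `k`, `n`, `rate`, `ci_low`,
#'   `ci_high`, `level`.
#' @examples
#' clopper_pearson(94, 174)  # rate 0.540
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n)
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  ci <- stats::binom.test(k, n, conf.level = level)$conf.int
  structure(list(k = as.integer(k), n = as.integer(n), rate = k / n,
                 ci_low = ci[1], ci_high = ci[2], level = level),
            class = "apis_rate")
}

#' @export
print.apis_rate <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f, %g%% CI [%.3f, %.3f]\n", x$k, x$n, x$rate,
              100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Two-sample proportion test
#'
#' 1-df chi-square test of equality of two proportions (2x2 table), with
#' Yates continuity correction by default.
#'
#' @param k1,n1 Responders / total in group 1.
#' @param k2,n2 Responders / total in group 2.
#' @param correct Apply the continuity correction.
#' @return List: `statistic`, `df`, `p_value`, `estimate` (the two rates).
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = TRUE) {
  if (n1 < 1 || n2 < 1) stop("empty margin", call. = FALSE)
  ht <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, estimate = unname(ht$estimate))
}

#' McNemar test for paired proportions
#'
#' Within-subject comparison of two binary responses via the discordant
#' pair counts `b` (1 then 0) and `c` (0 then 1). Default is the textbook
#' uncorrected statistic `(b - c)^2 / (b + c)`; the continuity-corrected
#' variant is available behind `correct = TRUE`. P-values are two-sided.
#'
#' @param b,c Discordant pair counts.
#' @param correct Apply the continuity correction.
#' @return List: `statistic`, `df`, `p_value`, `b`, `c`.
#' @export
mcnemar_test <- function(b, c, correct = FALSE) {
  if (b < 0 || c < 0 || b + c < 1)
    stop("need non-negative discordant counts with b + c >= 1",
         call. = FALSE)
  ht <- stats::mcnemar.test(matrix(c(0, c, b, 0), nrow = 2),
                            correct = correct)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, b = b, c = c)
}

#' Spearman rank correlation with bootstrap uncertainty
#'
#' Correlation by the average-rank (tie-corrected) formula, with a standard
#' error estimated as the SD of the statistic over case resamples.
#'
#' @param x,y Equal-length numeric (or logical) vectors, length >= 3.
#' @param n_boot Number of case resamples.
#' @param seed Optional seed for the resampling (caller's RNG preserved).
#' @return List: `rho`, `se`, `n`, `n_boot`, and `note` when the
#'   correlation is undefined (constant input), in which case `rho` is NA.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 2000, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not supported", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, se = NA_real_, n = n, n_boot = 0L,
                note = "undefined: constant input"))
  rho <- stats::cor(x, y, method = "spearman")
  boot <- function() {
    r <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      i <- sample.int(n, n, replace = TRUE)
      r[b] <- suppressWarnings(stats::cor(x[i], y[i], method = "spearman"))
    }
    r
  }
  r <- if (is.null(seed)) boot() else with_preserved_seed(seed, boot())
  list(rho = rho, se = stats::sd(r, na.rm = TRUE), n = n, n_boot = n_boot)
}

#' Cluster-bootstrap comparison of group means
#'
#' Nonparametric analogue of a mixed model with a subject random effect:
#' whole clusters (bees) are resampled with replacement within each group,
#' giving a bootstrap distribution of each group mean. Reported per group:
#' the observed mean and a percentile interval; between groups: the overlap
#' probability `p_overlap(g1, g2)`, the fraction of group-1 resampled means
#' falling inside group 2's interval (the significance rule used with
#' simulated posterior parameters). With every cluster of size 1 this
#' reduces to the ordinary case bootstrap.
#'
#' @param table Data frame of observations.
#' @param value_field Name of the numeric response column.
#' @param group_field Name of the grouping column (>= 2 groups).
#' @param cluster_field Name of the cluster (subject) column; every group
#'   needs >= 2 clusters.
#' @param n_boot Number of resamples.
#' @param seed Optional seed (caller's RNG preserved).
#' @param level Interval level (default 0.95).
#' @return Object of class `apis_group_comparison`: data frame `groups`
#'   (group, n_clusters, n_obs, mean, ci_low, ci_high), matrix `p_overlap`,
#'   `n_boot`, `level`.
#' @export
cluster_bootstrap_means <- function(table, value_field, group_field,
                                    cluster_field, n_boot = 2000,
                                    seed = NULL, level = 0.95) {
  stopifnot(all(c(value_field, group_field, cluster_field) %in%
                  names(table)))
  v <- table[[value_field]]
  g <- as.character(table[[group_field]])
  cl <- as.character(table[[cluster_field]])
  if (anyNA(v)) stop("missing values in the response", call. = FALSE)
  groups <- sort(unique(g))
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  by_group <- lapply(groups, function(gg) {
    split(v[g == gg], cl[g == gg])
  })
  nc <- vapply(by_group, length, 1L)
  if (any(nc < 2L))
    stop("group '", groups[which(nc < 2L)[1]], "' has fewer than 2 clusters",
         call. = FALSE)
  run <- function() {
    bm <- matrix(NA_real_, n_boot, length(groups))
    for (j in seq_along(groups)) {
      cls <- by_group[[j]]
      m <- length(cls)
      for (b in seq_len(n_boot)) {
        pick <- sample.int(m, m, replace = TRUE)
        bm[b, j] <- mean(unlist(cls[pick], use.names = FALSE))
      }
    }
    bm
  }
  bm <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  alpha <- (1 - level) / 2
  ci <- apply(bm, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  res <- data.frame(
    group = groups,
    n_clusters = nc,
    n_obs = vapply(groups, function(gg) sum(g == gg), 1L),
    mean = vapply(groups, function(gg) mean(v[g == gg]), 1),
    ci_low = ci[1, ], ci_high = ci[2, ],
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  po <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (a in seq_along(groups)) for (b2 in seq_along(groups)) {
    if (a != b2)
      po[a, b2] <- mean(bm[, a] >= ci[1, b2] & bm[, a] <= ci[2, b2])
  }
  structure(list(groups = res, p_overlap = po, n_boot = n_boot,
                 level = level),
            class = "apis_group_comparison")
}

#' @export
print.apis_group_comparison <- function(x, ...) {
  cat(sprintf("<apis_group_comparison> %d groups, %d cluster resamples\n",
              nrow(x$groups), x$n_boot))
  print(within(x$groups, {
    mean <- round(mean, 3); ci_low <- round(ci_low, 3)
    ci_high <- round(ci_high, 3)
  }))
  cat("p_overlap (row mean within column interval):\n")
  print(round(x$p_overlap, 3))
  invisible(x)
}

#' Percent agreement between two binary raters
#'
#' Overall concordance: the percentage of positions at which two binary
#' call vectors (e.g. automatic and manually observed escapes) agree.
#'
#' @param calls_a,calls_b Equal-length binary (logical or 0/1) vectors.
#' @return Percent agreement in [0, 100].
#' @export
concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b))
    stop("length mismatch", call. = FALSE)
  if (!length(calls_a)) stop("empty input", call. = FALSE)
  a <- as.logical(calls_a); b <- as.logical(calls_b)
  if (anyNA(a) || anyNA(b)) stop("missing calls", call. = FALSE)
  100 * mean(a == b)
}
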