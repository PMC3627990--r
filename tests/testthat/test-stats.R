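test_that("Clopper-Pearson intervals match tail inversion", {
  expect_equal(clopper_pearson(0, 10)$ci_low, 0)
  expect_equal(clopper_pearson(10, 10)$ci_high, 1)
  r <- clopper_pearson(94, 174)
  expect_equal(round(r$rate, 3), 0.540)
  # bisection oracle on the binomial tails
  tail_invert <- function(k, n, alpha = 0.05) {
    lo <- if (k == 0) 0 else
      stats::uniroot(function(p) 1 - pbinom(k - 1, n, p) - alpha / 2,
                     c(1e-12, 1 - 1e-12), tol = 1e-10)$root
    hi <- if (k == n) 1 else
      stats::uniroot(function(p) pbinom(k, n, p) - alpha / 2,
                     c(1e-12, 1 - 1e-12), tol = 1e-10)$root
    c(lo, hi)
  }
  for (kn in list(c(5, 10), c(1, 20), c(94, 174), c(31, 174))) {
    got <- clopper_pearson(kn[1], kn[2])
    want <- tail_invert(kn[1], kn[2])
    expect_lt(abs(got$ci_low - want[1]), 1e-6)
    expect_lt(abs(got$ci_high - want[2]), 1e-6)
  }
  expect_error(clopper_pearson(5, 4), "k <= n")
})

test_that("Clopper-Pearson coverage is at least nominal", {
  # exact coverage: sum binomial mass of the k whose interval contains p
  coverage <- function(n, p) {
    k <- 0:n
    inside <- vapply(k, function(kk) {
      ci <- clopper_pearson(kk, n)
      ci$ci_low <= p && p <= ci$ci_high
    }, TRUE)
    sum(dbinom(k, n, p)[inside])
  }
  for (n in c(20, 174)) for (p in c(0.1, 0.5, 0.9))
    expect_gte(coverage(n, p), 0.95)
})

test_that("proportion test matches enumeration and is symmetric", {
  r <- two_proportion_test(12, 40, 12, 40)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 1)
  # CS+ vs CS- rates differ decisively
  expect_lt(two_proportion_test(94, 174, 31, 174)$p_value, 0.001)
  # symmetry under swapping groups
  a <- two_proportion_test(10, 40, 20, 40)
  b <- two_proportion_test(20, 40, 10, 40)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  # margin-conditional enumeration oracle
  enum_p <- function(k1, n1, k2, n2) {
    m <- k1 + k2
    ks <- max(0, m - n2):min(n1, m)
    pr <- dhyper(ks, n1, n2, m)
    obs <- abs(k1 / n1 - (m - k1) / n2)
    sum(pr[abs(ks / n1 - (m - ks) / n2) >= obs - 1e-12])
  }
  for (tb in list(c(10, 40, 20, 40), c(15, 50, 25, 50), c(8, 30, 16, 30),
                  c(30, 80, 45, 80)))
    expect_lt(abs(two_proportion_test(tb[1], tb[2], tb[3], tb[4])$p_value -
                    enum_p(tb[1], tb[2], tb[3], tb[4])), 0.02)
  expect_error(two_proportion_test(0, 0, 1, 5), "empty margin")
})

test_that("McNemar statistic follows the discordant-pair formula", {
  expect_equal(mcnemar_test(5, 5)$statistic, 0)
  expect_equal(mcnemar_test(15, 5)$statistic, 5)
  # symmetry
  expect_equal(mcnemar_test(3, 9)$statistic, mcnemar_test(9, 3)$statistic)
  expect_error(mcnemar_test(0, 0), "b \\+ c")
  # continuity-corrected variant tracks the exact sign test
  for (n in 3:30) for (b in 0:n) {
    p_mc <- mcnemar_test(b, n - b, correct = TRUE)$p_value
    p_exact <- binom.test(b, n, 0.5)$p.value
    expect_lt(abs(p_mc - p_exact), 0.021)
  }
})

test_that("Spearman correlation handles ties, bounds and degeneracy", {
  r <- spearman_bootstrap(1:10, (1:10)^2, n_boot = 50, seed = 1)
  expect_equal(r$rho, 1)
  expect_equal(spearman_bootstrap(1:10, 10:1, n_boot = 50, seed = 1)$rho, -1)
  # tie handling equals the average-rank (Pearson-on-ranks) formula
  x <- c(1, 2, 2, 3, 4, 4); y <- c(2, 1, 4, 4, 4, 6)
  got <- spearman_bootstrap(x, y, n_boot = 50, seed = 1)$rho
  expect_equal(got, cor(rank(x), rank(y)))
  # constant input is reported as undefined, not guessed
  r0 <- spearman_bootstrap(rep(1, 6), 1:6, n_boot = 50, seed = 1)
  expect_true(is.na(r0$rho))
  expect_match(r0$note, "constant")
  expect_error(spearman_bootstrap(1:4, 1:5), "length mismatch")
})

test_that("Spearman bootstrap is seed-reproducible", {
  set.seed(3); x <- rnorm(40); y <- x + rnorm(40)
  a <- spearman_bootstrap(x, y, n_boot = 300, seed = 42)
  b <- spearman_bootstrap(x, y, n_boot = 300, seed = 42)
  expect_identical(a, b)
  expect_gt(a$se, 0)
})

test_that("cluster bootstrap compares group means with overlap probabilities", {
  # identical values: zero-width intervals, full overlap
  tab <- data.frame(v = rep(1, 12), g = rep(c("a", "b"), each = 6),
                    bee = rep(1:6, 2))
  r <- cluster_bootstrap_means(tab, "v", "g", "bee", n_boot = 100, seed = 1)
  expect_equal(r$groups$ci_low, r$groups$ci_high)
  expect_true(all(r$p_overlap[!is.na(r$p_overlap)] == 1))
  # determinism
  set.seed(8)
  tab2 <- data.frame(v = rnorm(60), g = rep(c("a", "b"), each = 30),
                     bee = rep(1:20, 3))
  expect_identical(
    cluster_bootstrap_means(tab2, "v", "g", "bee", n_boot = 200, seed = 5),
    cluster_bootstrap_means(tab2, "v", "g", "bee", n_boot = 200, seed = 5))
  # single-cluster group is refused
  bad <- data.frame(v = rnorm(5), g = c("a", "a", "a", "a", "b"),
                    bee = c(1, 1, 2, 2, 3))
  expect_error(cluster_bootstrap_means(bad, "v", "g", "bee"), "clusters")
})

test_that("singleton clusters reduce to the ordinary bootstrap", {
  set.seed(21)
  v <- rnorm(200)
  tab <- data.frame(v = v, g = rep(c("a", "b"), 100),
                    bee = sprintf("s%03d", 1:200))
  r <- cluster_bootstrap_means(tab, "v", "g", "bee", n_boot = 2000,
                               seed = 13)
  for (j in 1:2) {
    gi <- r$groups[j, ]
    vv <- v[tab$g == gi$group]
    clt <- mean(vv) + c(-1.96, 1.96) * sd(vv) / sqrt(length(vv))
    expect_lt(abs(gi$ci_low - clt[1]), 0.12)
    expect_lt(abs(gi$ci_high - clt[2]), 0.12)
  }
})

test_that("cluster bootstrap is calibrated under the null", {
  # exchangeable clusters: overlap probability rarely small
  ok <- vapply(1:30, function(i) {
    set.seed(500 + i)
    tab <- data.frame(
      v = rnorm(48) + rep(rnorm(24, 0, 0.5), each = 2),
      g = rep(c("a", "b"), each = 24),
      bee = rep(1:24, each = 2))
    r <- cluster_bootstrap_means(tab, "v", "g", "bee", n_boot = 400,
                                 seed = i)
    min(r$p_overlap, na.rm = TRUE) > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("cluster bootstrap intervals cover the true mean at ~95%", {
  hits <- vapply(1:150, function(i) {
    set.seed(1000 + i)
    cl <- rep(1:50, each = 2)
    tab <- data.frame(v = 0.3 + rnorm(50, 0, 0.6)[cl] + rnorm(100),
                      g = rep(c("a", "b"), 50), bee = cl)
    r <- cluster_bootstrap_means(tab, "v", "g", "bee", n_boot = 300,
                                 seed = i)
    r$groups$ci_low[1] <= 0.3 && 0.3 <= r$groups$ci_high[1]
  }, TRUE)
  expect_gt(mean(hits), 0.87)
  expect_lt(mean(hits), 0.995)
})

test_that("concordance is the percentage of matching calls", {
  a <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(concordance(a, a), 100)
  expect_equal(concordance(a, !a), 0)
  expect_equal(concordance(c(1, 0, 1, 0), c(1, 1, 1, 0)), 75)
  set.seed(77)
  x <- runif(1e4) < 0.5; y <- runif(1e4) < 0.5
  expect_lt(abs(concordance(x, y) - 50), 2.5)
  expect_error(concordance(1:3, 1:4), "length mismatch")
})
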