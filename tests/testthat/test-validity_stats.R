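# Frozen reference values for the omnibus normality test were computed
# independently with scipy.stats.normaltest / skewtest / kurtosistest.
.norm_sample <- c(
  10.002460, 10.597491, 9.451724, 8.218816, 9.090658, 8.016707, 10.120287,
  12.680430, 9.015587, 8.759050, 10.979684, 10.713774, 10.210828, 8.139064,
  9.941496, 11.390606, 7.311571, 9.084768, 6.197555, 7.420925, 6.316530,
  9.529818, 7.465107, 10.542529, 10.313502, 9.626138, 4.966481, 8.922614,
  9.902998, 10.226618, 6.939728, 9.044493, 8.042962, 8.382326, 12.121797,
  8.384931, 9.934957, 11.768780, 8.832799, 9.776596)
.lnorm_sample <- c(
  1.116796, 1.065860, 0.293741, 1.079114, 3.891612, 0.212855, 2.361702,
  1.126769, 0.526518, 7.392135, 2.143114, 0.301408, 1.077363, 1.780136,
  0.827967, 1.979631, 0.935647, 1.948866, 4.214465, 0.508819, 1.225242,
  0.629199, 1.135722, 0.305076, 0.560290, 0.821851, 2.456565, 3.143139,
  0.266195, 0.451743, 1.909618, 0.136365, 0.629286, 0.907296, 3.514914,
  1.992527, 0.720930, 0.691719, 0.778649, 4.588391, 0.651795, 0.738097,
  1.422746, 0.886237, 0.820957, 0.328221, 0.988545, 0.641734, 3.209540,
  1.921466, 0.976146, 1.951076, 0.711863, 2.863734, 0.994615, 1.792090,
  0.275025, 1.414364, 0.184851, 0.130638)

test_that("D'Agostino-Pearson matches the published transforms", {
  r <- dagostino_pearson(.norm_sample)
  expect_equal(r$statistic, 1.0883416501725542, tolerance = 1e-9)
  expect_equal(r$p, 0.5803227729852358, tolerance = 1e-9)
  expect_equal(r$z_skew, -0.860926391956989, tolerance = 1e-9)
  expect_equal(r$z_kurt, 0.5891921569441292, tolerance = 1e-9)
  r2 <- dagostino_pearson(.lnorm_sample)
  expect_equal(r2$statistic, 43.43994514217191, tolerance = 1e-9)
  expect_equal(r2$p, 3.690929631042116e-10, tolerance = 1e-6)
  expect_error(dagostino_pearson(rep(1, 30)), "degenerate")
  expect_warning(dagostino_pearson(rnorm(12)), "unreliable")
})

test_that("normality test has power against heavy skew", {
  set.seed(101)
  hits <- 0
  for (i in 1:200) {
    if (dagostino_pearson(rexp(500))$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.99)
})

test_that("right-tailed Spearman: exact small-sample p-values", {
  r <- spearman_right(1:4, c(2, 4, 6, 8))
  expect_equal(r$rho, 1)
  expect_equal(r$p_right, 1 / 24)
  # at rho = -1 every permutation satisfies rho_perm >= rho_obs, so the
  # exact right-tailed p is 1 (as in cor.test's exact branch)
  r2 <- spearman_right(1:4, c(8, 6, 4, 2))
  expect_equal(r2$rho, -1)
  expect_equal(r2$p_right, 1)
  # ties: rho equals brute-force average-rank computation
  x <- c(1, 2, 2, 4)
  y <- c(3, 1, 4, 5)
  r3 <- spearman_right(x, y)
  expect_equal(r3$rho, cor(rank(x), rank(y)))
  expect_error(spearman_right(rep(1, 5), 1:5), "undefined correlation")
  expect_error(spearman_right(1:3, 1:3), "at least 4")
})

test_that("exact Spearman p agrees with independent enumeration", {
  set.seed(111)
  for (i in 1:8) {
    n <- sample(5:7, 1)
    x <- sample(n)
    y <- round(x + rnorm(n, 0, 2))  # induces occasional ties
    r <- spearman_right(x, y)
    expect_equal(r$p_right, oracle_spearman_right(x, y), tolerance = 1e-12)
  }
})

test_that("t-approximation matches cor.test and tracks the exact branch", {
  set.seed(121)
  x <- rnorm(30)
  y <- x + rnorm(30)
  r <- spearman_right(x, y)
  ref <- cor.test(x, y, method = "spearman", alternative = "greater",
                  exact = FALSE, continuity = FALSE)
  expect_equal(r$rho, unname(ref$estimate))
  expect_equal(r$p_right, ref$p.value, tolerance = 1e-10)
  # crossover: approximation within 0.02 absolute of exact at n = 8
  mx <- 0
  for (i in 1:40) {
    xx <- sample(8)
    yy <- xx + rnorm(8, 0, 3)
    pe <- spearman_right(xx, yy, exact = TRUE)$p_right
    pa <- spearman_right(xx, yy, exact = FALSE)$p_right
    mx <- max(mx, abs(pe - pa))
  }
  expect_lte(mx, 0.02)
})

test_that("Bonferroni adjustment is capped, monotone, elementwise", {
  expect_equal(bonferroni_adjust(0.001, 18), 0.018)
  expect_equal(bonferroni_adjust(0.2, 18), 1)
  expect_equal(bonferroni_adjust(0.07, 1), 0.07)
  p <- runif(20)
  expect_true(all(diff(bonferroni_adjust(sort(p), 6)) >= 0))
})

test_that("Wilcoxon signed-rank: exact enumeration and approximations", {
  r <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
  expect_equal(r$W, 15)
  expect_equal(r$p, 0.0625)
  # antisymmetric differences sit at the null centre
  r2 <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3), rep(0, 6))
  expect_gte(r2$p, 0.9)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "degenerate")
  # n = 8: matches both the sign-enumeration oracle and wilcox.test
  set.seed(131)
  for (i in 1:6) {
    a <- rnorm(8)
    b <- rnorm(8)
    r3 <- wilcoxon_signed_rank(a, b)
    expect_equal(r3$p, oracle_wilcoxon(a - b), tolerance = 1e-12)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(r3$p, ref$p.value, tolerance = 1e-12)
  }
  # above the exact range: close to wilcox.test's corrected approximation
  set.seed(132)
  a <- rnorm(20)
  b <- a + rnorm(20, 0.3)
  r4 <- wilcoxon_signed_rank(a, b)
  ref4 <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(r4$p, ref4$p.value, tolerance = 0.02)
  expect_equal(r4$method, "normal approximation")
})

test_that("cutoff sweep fits OLS per retained subset", {
  r <- rep(4:30, 2)
  v <- r
  sw <- cutoff_sweep(v, r, c(10, 20, 30))
  expect_equal(sw$r_squared, rep(1, 3))
  expect_equal(sw$slope, rep(1, 3))
  sw2 <- cutoff_sweep(0.5 * r, r, c(15, 30))
  expect_equal(sw2$slope, rep(0.5, 2), tolerance = 1e-12)
  expect_equal(sw2$r_squared, rep(1, 2))
  # cutoffs retaining < 3 bouts are skipped with a note
  sw3 <- cutoff_sweep(c(5, 6, 25), c(5, 6, 25), c(4, 30))
  expect_equal(sw3$cutoff, 30)
  expect_equal(attr(sw3, "skipped"), 4)
})

test_that("difference metrics follow their definitions", {
  d <- difference_metrics(c(10, 12), c(10, 10))
  expect_equal(d$mean_diff, 1)
  expect_equal(d$mean_abs_diff, 1)
  expect_equal(d$percent_diff, 10)
  d0 <- difference_metrics(1:5, 1:5)
  expect_equal(d0$mean_diff, 0)
  expect_equal(d0$percent_diff, 0)
  # non-positive references excluded from the percent term, with a count
  d2 <- difference_metrics(c(1, 2, 3), c(0, 2, 3))
  expect_equal(d2$n_excluded_percent, 1)
  # arithmetic oracle on random tables
  set.seed(141)
  v <- rnorm(50, 10)
  r <- rnorm(50, 10)
  d3 <- difference_metrics(v, r)
  expect_equal(d3$mean_diff, mean(v - r))
  expect_equal(d3$mean_abs_diff, mean(abs(v - r)))
  pos <- r > 0
  expect_equal(d3$percent_diff, 100 * mean(abs(v[pos] - r[pos]) / r[pos]))
})

test_that("validity report covers every pair and stratum", {
  set.seed(151)
  n <- 24
  truth <- data.frame(bout_id = as.character(1:n),
                      n_steps = sample(8:20, n, TRUE),
                      cadence = rnorm(n, 110, 8),
                      step_time_cv = runif(n, 2, 9))
  feats <- rbind(
    transform(truth, annotation_method = "auto"),
    transform(truth, annotation_method = "manual"))
  feats$cadence <- feats$cadence + rnorm(2 * n, 0, 0.01)
  rep <- validity_report(feats, truth)
  expect_equal(nrow(rep), 3 * 2)  # 3 shared features x 2 strata
  expect_true(all(rep$rho > 0.99))
  expect_true(all(rep$p_adj <= 1 & rep$p_adj >= rep$p_right))
  expect_equal(unique(rep$bonferroni_factor), 2)
  # permuted video column: correlations collapse
  featp <- feats
  featp$cadence <- sample(featp$cadence)
  repp <- validity_report(featp, truth, pairing = list(cadence = "cadence"))
  expect_true(all(abs(repp$rho) < 0.6))
  expect_true(all(repp$p_adj > 0.05))
})

test_that("Spearman is invariant to strictly monotone transforms", {
  set.seed(161)
  x <- rnorm(15)
  y <- x + rnorm(15)
  base <- spearman_right(x, y)
  tr <- spearman_right(exp(x), y^3 + 5 * y)
  expect_equal(tr$rho, base$rho, tolerance = 1e-12)
  expect_equal(tr$p_right, base$p_right, tolerance = 1e-12)
})
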