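# Summary-statistics t tests, one-way ANOVA, Fisher exact, post hoc tests

test_that("raw-sample and summary paths agree exactly", {
  set.seed(41)
  x <- rnorm(8, 10, 2); y <- rnorm(6, 12, 3)
  sx <- summary_stats(mean(x), sd(x) / sqrt(8), 8)
  sy <- summary_stats(mean(y), sd(y) / sqrt(6), 6)
  raw <- group_t_test(x, y); smr <- group_t_test(sx, sy)
  expect_equal(raw$statistic, smr$statistic, tolerance = 1e-10)
  expect_equal(raw$p.value, smr$p.value, tolerance = 1e-10)
  raww <- group_t_test(x, y, welch = "on")
  smrw <- group_t_test(sx, sy, welch = "on")
  expect_equal(raww$statistic, smrw$statistic, tolerance = 1e-10)
  expect_equal(raww$df, smrw$df, tolerance = 1e-10)
  z <- rnorm(5, 11, 2)
  sz <- summary_stats(mean(z), sd(z) / sqrt(5), 5)
  aov_raw <- one_way_anova(list(x, y, z))
  aov_smr <- one_way_anova(list(sx, sy, sz))
  expect_equal(aov_raw$statistic, aov_smr$statistic, tolerance = 1e-10)
})

test_that("the pooled t test matches t.test and the ANOVA matches aov", {
  set.seed(42)
  x <- rnorm(8, 10, 2); y <- rnorm(6, 12, 3); z <- rnorm(7, 11, 2)
  r <- group_t_test(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p.value, ref$p.value, tolerance = 1e-12)
  rw <- group_t_test(x, y, welch = "on")
  refw <- t.test(x, y)
  expect_equal(rw$statistic, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(rw$df, unname(refw$parameter), tolerance = 1e-10)
  a <- one_way_anova(list(x, y, z))
  dat <- data.frame(v = c(x, y, z),
                    g = factor(rep(1:3, c(8, 6, 7))))
  refa <- summary(aov(v ~ g, dat))[[1]]
  expect_equal(a$statistic, refa[["F value"]][1], tolerance = 1e-10)
  expect_equal(a$p.value, refa[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("identical groups give t = 0, p = 1 and F near 0", {
  s <- summary_stats(10, 1, 8)
  r <- group_t_test(s, s)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  a <- one_way_anova(list(s, s, s))
  expect_equal(a$statistic, 0)
})

test_that("the t statistic flips sign under group swap; p is invariant", {
  a <- summary_stats(24.4, 1.2, 8); b <- summary_stats(16.5, 1.8, 6)
  r1 <- group_t_test(a, b); r2 <- group_t_test(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p.value, r2$p.value)
})

test_that("printed group summaries reproduce the published test statistics", {
  # myelinated axon counts after cross-anastomosis: t(4) = 0.5061
  t4 <- group_t_test(summary_stats(722.4, 133.9, 3),
                     summary_stats(649.2, 54.92, 3))
  expect_equal(t4$df, 4)
  expect_equal(t4$statistic, 0.5061, tolerance = 0.03)
  expect_equal(t4$p.value, 0.6394, tolerance = 0.03)
  # A-beta conduction velocities across intact/self/cross: F(2,68) = 20.66
  f1 <- one_way_anova(list(summary_stats(15.58, 0.72, 22),
                           summary_stats(11.84, 0.37, 31),
                           summary_stats(10.82, 0.50, 18)))
  expect_equal(f1$df, c(2, 68))
  expect_equal(f1$statistic, 20.66, tolerance = 0.03)
  expect_lt(f1$p.value, 1e-4)
  # RAM vibration thresholds: F(2,26) = 2.543, p = 0.098 (n.s.)
  f2 <- one_way_anova(list(summary_stats(13.9, 2.4, 10),
                           summary_stats(7.1, 1.3, 14),
                           summary_stats(10.6, 5.2, 5)))
  expect_equal(f2$df, c(2, 26))
  expect_equal(f2$statistic, 2.543, tolerance = 0.03)
  expect_gt(f2$p.value, 0.05)
})

test_that("welch auto-trigger fires only for clearly unequal variances", {
  equal <- group_t_test(summary_stats(10, 1, 10),
                        summary_stats(12, 1.1, 10), welch = "auto")
  expect_equal(equal$method, "student")
  unequal <- group_t_test(summary_stats(10, 0.3, 10),
                          summary_stats(12, 3, 10), welch = "auto")
  expect_equal(unequal$method, "welch")
})

test_that("fisher_exact follows the point-probability rule", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2, 2))$p.value, 1)
  # [[0,5],[5,0]]: 6 admissible tables, the two extremes have p = 1/252
  expect_equal(fisher_exact(matrix(c(0, 5, 5, 0), 2, 2))$p.value, 2 / 252)
  expect_error(fisher_exact(matrix(0L, 2, 2)), "margin")
  expect_error(fisher_exact(matrix(c(1, -1, 1, 1), 2, 2)), "non-negative")
})

test_that("fisher_exact agrees with enumeration and fisher.test on random tables", {
  set.seed(77)
  for (i in 1:40) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2, 2)
    if (sum(tab) == 0) next
    p <- fisher_exact(tab)$p.value
    expect_equal(p, brute_fisher(tab), tolerance = 1e-12)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-6)
  }
  # the electrical-search proportions: computed p from the printed counts
  p_abeta <- fisher_exact(matrix(c(10, 33, 28, 20), 2, 2))$p.value
  expect_equal(p_abeta, brute_fisher(matrix(c(10, 33, 28, 20), 2, 2)),
               tolerance = 1e-12)
  expect_lt(p_abeta, 0.05)
})

test_that("post hoc tests order the shifted group first and match TukeyHSD", {
  set.seed(55)
  g1 <- rnorm(9, 10); g2 <- rnorm(9, 10); g3 <- rnorm(9, 13)
  ph <- pairwise_posthoc(list(a = g1, b = g2, c = g3), "tukey")
  # the two pairs involving the shifted group have the smallest adjusted p
  ord <- ph$p.adj[order(ph$pair)]         # a-b, a-c, b-c
  expect_gt(ord[1], max(ord[2], ord[3]))
  ref <- TukeyHSD(aov(v ~ g, data.frame(
    v = c(g1, g2, g3), g = factor(rep(c("a", "b", "c"), each = 9)))))$g
  expect_equal(sort(ph$p.adj), sort(unname(ref[, "p adj"])),
               tolerance = 1e-8)
  # bonferroni with a single comparison equals the unadjusted t test
  pb <- pairwise_posthoc(list(a = g1, b = g3), "bonferroni")
  expect_equal(pb$p.adj, group_t_test(g1, g3)$p.value)
  # identical groups: all adjusted p = 1
  s <- summary_stats(5, 1, 6)
  ph0 <- pairwise_posthoc(list(s, s, s), "bonferroni")
  expect_true(all(ph0$p.adj == 1))
  expect_error(pairwise_posthoc(list(g1, g2), "tukey"), ">= 3")
})
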