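test_that("Student's t: identical groups give t = 0, p = 1", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  cmp <- compare_groups(v, g, method = "student_t")
  expect_equal(cmp$omnibus$statistic, 0)
  expect_equal(cmp$omnibus$p, 1)
  # matches stats::t.test with pooled variance on a non-degenerate fixture
  v2 <- c(1, 2, 3, 4, 2, 4, 6, 9)
  g2 <- rep(c("a", "b"), each = 4)
  cmp2 <- compare_groups(v2, g2, method = "student_t")
  ref <- t.test(v2[1:4], v2[5:8], var.equal = TRUE)
  expect_equal(cmp2$omnibus$p, ref$p.value)
  expect_equal(cmp2$omnibus$statistic, unname(ref$statistic))
})

test_that("Kruskal-Wallis H matches the direct rank-sum formula", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  cmp <- compare_groups(v, g, method = "kruskal_dunn_bh")
  # oracle: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1), no ties
  N <- 9; rbar <- c(2, 5, 8)
  H <- 12 / (N * (N + 1)) * sum(3 * rbar^2) - 3 * (N + 1)
  expect_equal(cmp$omnibus$statistic, H)
  expect_equal(cmp$omnibus$statistic, unname(kruskal.test(v, factor(g))$statistic))
})

test_that("Dunn + BH: adjusted p >= raw p, order preserved", {
  set.seed(1)
  v <- c(rnorm(6), rnorm(6, 1), rnorm(6, 3))
  g <- rep(c("a", "b", "c"), each = 6)
  d <- dunn_test(v, g, p_adjust = "BH")
  expect_true(all(d$p_adj >= d$p_raw - 1e-12))
  expect_equal(order(d$p_adj), order(d$p_raw))
  expect_equal(d$p_adj, p.adjust(d$p_raw, "BH"))
})

test_that("one-way ANOVA + Tukey returns adjusted pairwise p-values", {
  set.seed(2)
  v <- c(rnorm(8, 0), rnorm(8, 0.5), rnorm(8, 3))
  g <- rep(c("a", "b", "c"), each = 8)
  cmp <- compare_groups(v, g, method = "oneway_anova_tukey")
  expect_equal(nrow(cmp$pairs), 3L)
  expect_true(all(cmp$pairs$p_adj >= 0 & cmp$pairs$p_adj <= 1))
  ref <- summary(aov(v ~ factor(g)))[[1]]
  expect_equal(cmp$omnibus$statistic, ref$`F value`[1])
  expect_lt(cmp$pairs$p_adj[cmp$pairs$group1 == "c" |
                            cmp$pairs$group2 == "c"][2], 0.05)
})

test_that("two-way ANOVA reports the interaction term", {
  set.seed(3)
  g1 <- rep(c("ctl", "cas"), each = 12)
  g2 <- rep(rep(c("dark", "lit"), each = 6), 2)
  v <- rnorm(24) + ifelse(g1 == "cas" & g2 == "lit", 2, 0)
  cmp <- compare_groups(v, g1, method = "twoway_anova_interaction",
                        group2 = g2)
  ref <- summary(aov(v ~ factor(g1) * factor(g2)))[[1]]
  expect_equal(cmp$omnibus$statistic, ref$`F value`[3])
  expect_equal(cmp$omnibus$p, ref$`Pr(>F)`[3])
})

test_that("parametric p is close to the exhaustive permutation p (small n)", {
  v <- c(3.1, 4.2, 2.8, 5.0, 6.1, 5.4, 7.0, 6.6)
  g <- rep(c("a", "b"), each = 4)
  cmp <- compare_groups(v, g, method = "student_t")
  # oracle: all 70 assignments of 4 values to group a
  idx <- combn(8, 4)
  tstat <- function(ia) {
    x <- v[ia]; y <- v[-ia]
    sp <- sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 6)
    (mean(x) - mean(y)) / (sp * sqrt(0.5))
  }
  t_obs <- abs(tstat(1:4))
  perm_p <- mean(apply(idx, 2, function(ia) abs(tstat(ia)) >= t_obs - 1e-12))
  expect_lt(abs(cmp$omnibus$p - perm_p), 0.05)
})

test_that("group summaries: mean, SEM and n", {
  rec <- data.frame(cond = c("a", "a", "a", "b"),
                    tip_count = c(2, 4, 6, 5),
                    total_length_um = c(10, 20, 30, 40))
  s <- summarize_records(rec, keys = "cond")
  row <- s[s$cond == "a" & s$metric == "tip_count", ]
  expect_equal(row$mean, 4)
  expect_equal(row$sem, 2 / sqrt(3), tolerance = 1e-9)
  expect_equal(row$n, 3L)
  single <- s[s$cond == "b" & s$metric == "tip_count", ]
  expect_true(is.na(single$sem))
  expect_equal(sum(s$n[s$metric == "tip_count"]), nrow(rec))
})

test_that("degenerate inputs are rejected or reported", {
  expect_error(compare_groups(1:3, c("a", "a", "a")), "2 groups")
  expect_error(compare_groups(c(1, 2, 3), c("a", "b", "b")), "n >= 2")
  cmp <- compare_groups(rep(5, 6), rep(c("a", "b"), 3), method = "student_t")
  expect_equal(cmp$omnibus$p, 1)   # constant data reported, not crashed
})
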