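test_that("the excess-over-baseline fold convention reproduces table claims", {
  km_mature <- mean(c(22.28, 53.12))     # glycosylated mature fractions
  km_premature <- mean(c(327.0, 233.7))  # non-glycosylated fractions
  f1 <- fold_difference(km_premature, km_mature)
  expect_equal(round_half_away(as.numeric(f1), 1), 6.4)
  expect_identical(attr(f1, "direction"), "higher")

  f2 <- fold_difference(2102.0, km_premature)
  expect_equal(round_half_away(as.numeric(f2), 1), 6.5)
  expect_identical(attr(f2, "direction"), "higher")

  expect_equal(as.numeric(fold_difference(7, 7)), 0)
  expect_identical(attr(fold_difference(7, 7), "direction"), "equal")
  expect_equal(as.numeric(fold_difference(6, 2, "ratio")), 3)
  expect_error(fold_difference(-1, 2), "positive")
})

test_that("fold difference is symmetric; direction is not", {
  expect_equal(as.numeric(fold_difference(280.35, 37.70)),
               as.numeric(fold_difference(37.70, 280.35)))
  expect_identical(attr(fold_difference(37.70, 280.35), "direction"),
                   "lower")
})

test_that("percent change matches the prose conventions and rounding", {
  expect_equal(round_half_away(percent_change(2102.0, 4068.0, "increase")),
               94)
  expect_equal(round_half_away(percent_change(27.74, 12.05, "reduction")),
               57)
  expect_equal(round_half_away(percent_change(21.26, 11.73, "reduction")),
               45)
  expect_equal(round_half_away(percent_change(39.50, 59.51, "increase")),
               51)
  expect_equal(percent_change(5, 5, "increase"), 0)
  expect_error(percent_change(0, 5), "> 0")
})

test_that("increase percent and excess fold agree when new > reference", {
  set.seed(3)
  for (i in 1:10) {
    ref <- stats::runif(1, 1, 50)
    new <- ref * stats::runif(1, 1, 10)
    expect_equal(percent_change(ref, new, "increase"),
                 100 * as.numeric(fold_difference(new, ref)),
                 tolerance = 1e-12)
  }
})

test_that("round_half_away rounds halves away from zero", {
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(-2.5), -3)
  expect_equal(round_half_away(6.45, 1), 6.5)
  expect_equal(round_half_away(93.53), 94)
})

test_that("pooled t-test on estimates matches the t CDF oracle", {
  a <- estimate_with_se(22.28, 5.32, 26)   # mature fraction Km
  b <- estimate_with_se(53.12, 8.47, 26)
  r <- pooled_estimate_ttest(a, b)
  t_oracle <- (22.28 - 53.12) / sqrt(5.32^2 + 8.47^2)
  expect_equal(r$t, t_oracle, tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-abs(t_oracle), 26), tolerance = 1e-12)
  expect_equal(round(abs(r$t), 2), 3.08)
  expect_true(r$significant)   # consistent with distinct superscripts

  same <- pooled_estimate_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  far <- pooled_estimate_ttest(estimate_with_se(10, 1, 20),
                               estimate_with_se(100, 1, 20))
  expect_lt(far$p, 0.001)
})

test_that("degenerate zero-SE comparisons are flagged", {
  z1 <- pooled_estimate_ttest(list(value = 2, se = 0, df = 10),
                              list(value = 2, se = 0, df = 10))
  expect_equal(z1$p, 1)
  z2 <- pooled_estimate_ttest(list(value = 2, se = 0, df = 10),
                              list(value = 3, se = 0, df = 10))
  expect_equal(z2$p, 0)
  expect_true(z2$degenerate)
})

test_that("the pooled t-test is invariant to common rescaling", {
  a <- estimate_with_se(25.47, 4.75, 28)
  b <- estimate_with_se(29.21, 4.75, 28)
  r1 <- pooled_estimate_ttest(a, b)
  r2 <- pooled_estimate_ttest(estimate_with_se(25.47 * 1e3, 4.75 * 1e3, 28),
                              estimate_with_se(29.21 * 1e3, 4.75 * 1e3, 28))
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("identical groups share a letter and give F near zero", {
  g <- list(jejunum = c(1, 2, 3, 2), ileum = c(1, 2, 3, 2),
            cecum = c(1, 2, 3, 2))
  r <- oneway_anova_tukey(g)
  expect_lt(r$F, 1e-20)
  expect_true(all(r$tukey$p_adj > 0.99))
  expect_equal(length(unique(r$letters)), 1L)
})

test_that("with two groups Tukey collapses to the pooled t-test", {
  set.seed(8)
  g <- list(a = stats::rnorm(6, 10, 1), b = stats::rnorm(6, 11, 1))
  r <- oneway_anova_tukey(g)
  tt <- stats::t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(r$tukey$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey-adjusted p-values never undercut the unadjusted pair test", {
  set.seed(13)
  g <- list(a = stats::rnorm(5, 10), b = stats::rnorm(5, 10.8),
            c = stats::rnorm(5, 11.5))
  r <- oneway_anova_tukey(g)
  raw_p <- c(stats::t.test(g$a, g$b, var.equal = TRUE)$p.value,
             stats::t.test(g$a, g$c, var.equal = TRUE)$p.value,
             stats::t.test(g$b, g$c, var.equal = TRUE)$p.value)
  # pairwise order in TukeyHSD: b-a, c-a, c-b
  expect_true(all(r$tukey$p_adj >= raw_p - 1e-10))
})

test_that("a 5-sigma shifted group earns its own letter", {
  # single-run agreement with a brute-force permutation oracle on the F
  # statistic, then letter recovery across seeded replications
  set.seed(21)
  g <- list(a = stats::rnorm(4, 10, 1), b = stats::rnorm(4, 10, 1),
            c = stats::rnorm(4, 15, 1))
  r <- oneway_anova_tukey(g)
  vals <- unlist(g); grp <- rep(names(g), each = 4)
  fstat <- function(v) summary(stats::aov(v ~ factor(grp)))[[1]][1, "F value"]
  perm <- replicate(999, fstat(sample(vals)))
  p_perm <- (1 + sum(perm >= r$F)) / 1000
  expect_lt(p_perm, 0.01)
  expect_lt(r$p, 0.01)

  set.seed(77)
  hits <- 0
  for (i in 1:50) {
    g <- list(a = stats::rnorm(4, 10, 1), b = stats::rnorm(4, 10, 1),
              c = stats::rnorm(4, 15, 1))
    r <- oneway_anova_tukey(g)
    if (!r$letters["c"] %in% r$letters[c("a", "b")]) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("groups with fewer than two replicates are refused", {
  expect_error(oneway_anova_tukey(list(a = 1, b = c(1, 2))), "< 2")
  expect_error(oneway_anova_tukey(list(a = c(1, 2))), "2 groups")
})
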