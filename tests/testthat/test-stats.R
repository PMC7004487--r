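# the statistical battery, pinned to hand oracles and reference
# implementations

test_that("Kruskal-Wallis H matches the hand rank-sum formula and base R", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  r <- kruskal_wallis(g)
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)

  # tie-corrected H agrees with kruskal.test on tied data
  set.seed(31)
  gt <- list(sample(1:4, 10, TRUE), sample(2:6, 12, TRUE), sample(1:5, 8, TRUE))
  ref <- kruskal.test(gt)
  got <- kruskal_wallis(gt)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$statistic, 0)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(32)
  g <- list(rnorm(7), rnorm(9), rnorm(5))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v) + 1))$statistic
  expect_equal(h1, h2)
})

test_that("Dunn z follows the closed form and its square recovers H for k = 2", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  d <- dunn_test(g)
  z13 <- d$posthoc$z[d$posthoc$group_i == "group1" &
                       d$posthoc$group_j == "group3"]
  expect_equal(z13, -6 / sqrt(5), tolerance = 1e-12)

  same <- dunn_test(list(c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(same$posthoc$z == 0))
  expect_true(all(same$posthoc$p_raw == 1))

  set.seed(33)
  g2 <- list(sample(1:6, 9, TRUE), sample(3:8, 11, TRUE))
  d2 <- dunn_test(g2)
  expect_equal(d2$posthoc$z^2, kruskal_wallis(g2)$statistic, tolerance = 1e-9)

  dh <- dunn_test(list(rnorm(6), rnorm(6), rnorm(6)), adjust = "holm")
  expect_true(all(dh$posthoc$p_adjusted >= dh$posthoc$p_raw))
})

test_that("Pearson chi-squared matches the 2x2 closed form and chisq.test", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  r <- chi_square(tab)
  N <- sum(tab)
  expect_equal(r$statistic,
               N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
                 prod(rowSums(tab), colSums(tab)),
               tolerance = 1e-12)
  expect_equal(r$df, 1)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)

  prop <- matrix(c(10, 20, 30, 60), 2)   # proportional rows
  expect_equal(chi_square(prop)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi_square(tab)$statistic, chi_square(t(tab))$statistic)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "margins")
  expect_error(chi_square(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("paired t matches hand arithmetic, t.test, and sign conventions", {
  x <- c(2, 3, 4); y <- c(1, 1, 1)
  r <- paired_t(x, y)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)

  expect_equal(paired_t(x, x)$statistic, 0)
  expect_equal(paired_t(x, x)$p_value, 1)
  expect_equal(paired_t(y, x)$statistic, -r$statistic)
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "undefined")
  expect_error(paired_t(1, 2), "2 pairs")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("Type II sums of squares match car::Anova on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(34)
  n <- c(4, 7, 5, 6)
  a <- rep(rep(c("g1", "g2"), 2), n)
  b <- rep(c("u", "u", "v", "v"), n)
  y <- rnorm(sum(n)) + (a == "g1") * 0.8
  got <- two_way_anova(y, a, b)
  ref <- car::Anova(lm(y ~ af * bf,
                       data = data.frame(af = factor(a), bf = factor(b))),
                    type = 2)
  expect_equal(got$effects$SS, ref$`Sum Sq`[1:3], tolerance = 1e-9)
  expect_equal(got$effects$F, ref$`F value`[1:3], tolerance = 1e-9)
  expect_equal(got$effects$p, ref$`Pr(>F)`[1:3], tolerance = 1e-9)
})

test_that("zero-noise equal cell means give F = 0 throughout", {
  a <- rep(c("g1", "g2"), each = 6)
  b <- rep(rep(c("u", "v"), each = 3), 2)
  y <- rep(5, 12)
  r <- two_way_anova(y, a, b)
  expect_equal(r$effects$F, c(0, 0, 0))
  expect_equal(r$effects$p, c(1, 1, 1))
  a2 <- rep(c("g1", "g2"), each = 4)
  b2 <- c("u", "u", "v", "v", "u", "u", "u", "u")   # (g2, v) unobserved
  expect_error(two_way_anova(rnorm(8), a2, b2), "empty cell")
})

test_that("balanced 2x2 sums of squares equal the hand decomposition", {
  # cell means: (g1,u)=1, (g1,v)=3, (g2,u)=2, (g2,v)=8; n = 3 per cell, no noise
  a <- rep(c("g1", "g2"), each = 6)
  b <- rep(rep(c("u", "v"), each = 3), 2)
  y <- rep(c(1, 3, 2, 8), each = 3)
  r <- two_way_anova(y, a, b)
  # grand mean 3.5; A means 2 and 5; B means 1.5 and 5.5
  expect_equal(r$effects$SS, c(6 * (2 - 3.5)^2 + 6 * (5 - 3.5)^2,
                               6 * (1.5 - 3.5)^2 + 6 * (5.5 - 3.5)^2,
                               sum(3 * (c(1, 3, 2, 8) -
                                          c(2 + 1.5, 2 + 5.5, 5 + 1.5, 5 + 5.5) +
                                          3.5)^2)),
               tolerance = 1e-9)
})

test_that("repeated-measures layout reproduces the split-plot aov strata", {
  set.seed(35)
  subject <- rep(1:8, times = 3)
  a <- c("WT", "WT", "WT", "WT", "KO", "KO", "KO", "KO")[subject]
  b <- rep(c("s1", "s2", "s3"), each = 8)
  y <- rnorm(24) + (a == "WT") * 0.4
  got <- two_way_anova(y, a, b, repeated_on = subject)
  ref <- summary(aov(y ~ af * bf + Error(sf / bf),
                     data = data.frame(af = factor(a), bf = factor(b),
                                       sf = factor(subject))))
  between <- ref[["Error: sf"]][[1]]
  within <- ref[["Error: sf:bf"]][[1]]
  expect_equal(got$effects$F[1], between$`F value`[1], tolerance = 1e-9)
  expect_equal(got$effects$F[2:3], within$`F value`[1:2], tolerance = 1e-9)
  expect_equal(got$effects$df_error, c(6, 12, 12))
  expect_true(got$sphericity_assumed)
  # incomplete within-subject data is rejected
  expect_error(two_way_anova(y[-1], a[-1], b[-1], repeated_on = subject[-1]),
               "one observation per subject")
})

test_that("Holm-Sidak adjustment is monotone and bounded", {
  p <- c(0.001, 0.02, 0.04, 0.3, 0.7)
  adj <- gustaquant:::holm_sidak_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_equal(adj[1], 1 - (1 - 0.001)^5, tolerance = 1e-12)
})

test_that("two-way ANOVA null rejection rate is nominal", {
  set.seed(36)
  rej <- mean(replicate(400, {
    a <- rep(c("g1", "g2"), each = 10)
    b <- rep(rep(c("u", "v"), each = 5), 2)
    two_way_anova(rnorm(20), a, b, posthoc = "none")$effects$p[1] < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
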