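#' Kruskal-Wallis rank test
#'
#' Rank-based k-sample test: `H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2`,
#' divided by the tie correction `1 - sum(t^3 - t)/(N^3 - N)`, with
#' `df = k - 1` and a chi-squared approximation for the p-value.
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return list of class `stat_result`: `test`, `statistic` (H), `df`,
#'   `p_value`, `n` (per-group sizes).
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  # all observations identical: numerator is already 0; define H = 0
  H <- if (tie_corr > 0) H / tie_corr else 0
  df <- length(groups) - 1
  structure(list(test = "Kruskal-Wallis", statistic = H, df = df,
                 p_value = pchisq(H, df, lower.tail = FALSE),
                 n = unname(n)),
            class = "stat_result")
}

check_groups <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2,
              "at least 2 groups are required")
  for (i in seq_along(groups)) {
    assert_that(length(groups[[i]]) >= 1, "group %d is empty", i)
    assert_that(all(is.finite(groups[[i]])), "group %d has non-finite values", i)
  }
  invisible(TRUE)
}

#' Dunn post-hoc test for pairwise group comparisons
#'
#' Follows a Kruskal-Wallis test: for each pair of groups,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))` with ranks over the pooled data, two-sided normal
#' p-values, and optional multiplicity adjustment.
#'
#' @param groups list of numeric vectors; names label the groups.
#' @param adjust `"none"` (default), `"holm"`, or `"bonferroni"`.
#' @return `stat_result` whose `posthoc` table has one row per pair:
#'   `group_i`, `group_j`, `z`, `p_raw`, `p_adjusted`, `method`.
#' @export
dunn_test <- function(groups, adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  check_groups(groups)
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(length(groups), 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    data.frame(group_i = nm[i], group_j = nm[j], z = unname(z),
               p_raw = 2 * pnorm(-abs(unname(z))))
  })
  posthoc <- do.call(rbind, rows)
  posthoc$p_adjusted <- switch(adjust,
                               none = posthoc$p_raw,
                               stats::p.adjust(posthoc$p_raw, method = adjust))
  posthoc$method <- adjust
  kw <- kruskal_wallis(groups)
  structure(list(test = "Dunn", statistic = kw$statistic, df = kw$df,
                 p_value = kw$p_value, posthoc = posthoc, n = unname(n)),
            class = "stat_result")
}

#' Pearson chi-squared test of independence
#'
#' @param tab nonnegative integer contingency table (matrix) with positive
#'   row and column margins.
#' @return `stat_result` with `statistic`, `df = (r-1)(c-1)`, `p_value`,
#'   and the `expected` counts.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(all(tab >= 0) && all(tab == floor(tab)),
              "table must contain nonnegative integers")
  assert_that(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "all row and column margins must be positive")
  N <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  structure(list(test = "chi-squared", statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 expected = expected, n = N),
            class = "stat_result")
}

#' Paired t test
#'
#' `t = dbar / (s_d / sqrt(n))` on the differences `x - y`, `df = n - 1`,
#' two-sided p-value.  Zero-variance differences with a nonzero mean are an
#' error (the statistic is undefined), not a silent infinity; identical
#' vectors give `t = 0`, `p = 1`.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return `stat_result` with `statistic`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 2, "at least 2 pairs are required")
  d <- x - y
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    assert_that(mean(d) == 0,
                "differences have zero variance and nonzero mean: t undefined")
    t_stat <- 0
  } else {
    t_stat <- mean(d) / (s / sqrt(n))
  }
  structure(list(test = "paired t", statistic = t_stat, df = n - 1,
                 p_value = 2 * pt(-abs(t_stat), n - 1),
                 mean_diff = mean(d), n = n),
            class = "stat_result")
}

#' Two-way ANOVA with Holm-Sidak pairwise comparisons
#'
#' Fixed-effects two-factor analysis with Type II sums of squares (each main
#' effect adjusted for the other, the interaction adjusted for both), which
#' is appropriate for the unbalanced per-bud layouts this pipeline produces.
#' With `repeated_on` set, a split-plot/repeated-measures analysis is run
#' instead (between-subject factor tested against the subject stratum,
#' within-subject factor and interaction against the subject-by-factor
#' stratum); sphericity is assumed and flagged.  Post hoc, levels of
#' `factor_a` are compared pairwise within each level of `factor_b` with
#' Holm-Sidak-adjusted t tests on the appropriate error term.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factors (coerced) of the same length as `values`.
#' @param repeated_on optional subject identifier; when given, `factor_b` is
#'   treated as the within-subject factor and the within-subject data must
#'   be complete.
#' @param posthoc `"holm_sidak"` or `"none"`.
#' @return `stat_result` with an `effects` table (term, df, SS, F, p) and a
#'   `posthoc` table of pairwise comparisons.
#' @export
two_way_anova <- function(values, factor_a, factor_b, repeated_on = NULL,
                          posthoc = c("holm_sidak", "none")) {
  posthoc <- match.arg(posthoc)
  a <- factor(factor_a); b <- factor(factor_b)
  assert_that(length(values) == length(a) && length(values) == length(b),
              "values and factors must have equal length")
  assert_that(all(is.finite(values)), "values must be finite")
  if (is.null(repeated_on)) {
    res <- anova2_type2(values, a, b)
  } else {
    res <- anova2_repeated(values, a, b, factor(repeated_on))
  }
  eff <- res$effects
  ph <- NULL
  if (posthoc == "holm_sidak") {
    ph <- pairwise_holm_sidak(values, a, b, res$mse_comp, res$df_comp)
  }
  structure(list(test = if (is.null(repeated_on)) "two-way ANOVA (Type II)"
                 else "two-way repeated-measures ANOVA",
                 statistic = eff$F[1], df = c(eff$df[1], res$df_resid[1]),
                 p_value = eff$p[1], effects = eff, posthoc = ph,
                 sphericity_assumed = !is.null(repeated_on),
                 n = length(values)),
            class = "stat_result")
}

rss <- function(fit) sum(resid(fit)^2)

# F and p with the degenerate zero-signal / zero-error cases pinned down:
# an effect with (numerically) zero SS is F = 0, p = 1 regardless of MSE.
safe_f <- function(ss, df1, mse, df2, tol) {
  if (ss <= tol) return(c(F = 0, p = 1))
  if (mse <= tol / max(df2, 1)) return(c(F = Inf, p = 0))
  f <- (ss / df1) / mse
  c(F = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

anova2_type2 <- function(y, a, b) {
  cells <- table(a, b)
  assert_that(all(cells > 0),
              "empty cell(s) in the two-factor layout: %s",
              paste(outer(rownames(cells), colnames(cells), paste, sep = ":")[cells == 0],
                    collapse = ", "))
  d <- data.frame(y = y, a = a, b = b)
  m_full <- lm(y ~ a * b, data = d)
  m_ab <- lm(y ~ a + b, data = d)
  m_a <- lm(y ~ a, data = d)
  m_b <- lm(y ~ b, data = d)
  ss_a <- rss(m_b) - rss(m_ab)
  ss_b <- rss(m_a) - rss(m_ab)
  ss_int <- rss(m_ab) - rss(m_full)
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1; df_int <- df_a * df_b
  df_res <- length(y) - nlevels(a) * nlevels(b)
  assert_that(df_res > 0, "no residual degrees of freedom")
  mse <- rss(m_full) / df_res
  tol <- 1e-10 * max(sum(y^2), 1)
  rows <- rbind(
    c(df_a, ss_a, safe_f(ss_a, df_a, mse, df_res, tol)),
    c(df_b, ss_b, safe_f(ss_b, df_b, mse, df_res, tol)),
    c(df_int, ss_int, safe_f(ss_int, df_int, mse, df_res, tol)))
  effects <- data.frame(term = c("A", "B", "A:B"), df = rows[, 1],
                        SS = rows[, 2], F = rows[, 3], p = rows[, 4],
                        df_error = df_res)
  list(effects = effects, df_resid = df_res, mse_comp = mse, df_comp = df_res)
}

anova2_repeated <- function(y, a, b, subject) {
  # subjects nested in a; b within-subject
  tab <- table(subject, b)
  assert_that(all(tab[rowSums(tab) > 0, ] == 1),
              "repeated-measures layout requires exactly one observation per subject per within-factor level")
  sub_a <- tapply(as.integer(a), subject, function(v) length(unique(v)))
  assert_that(all(sub_a[!is.na(sub_a)] == 1),
              "each subject must belong to exactly one level of the between factor")
  n_sub <- nlevels(droplevels(subject))
  gm <- mean(y)
  # sums of squares for the balanced split-plot decomposition
  ss <- function(means, weights) sum(weights * (means - gm)^2)
  mean_a <- tapply(y, a, mean); n_a <- table(a)
  mean_b <- tapply(y, b, mean); n_b <- table(b)
  mean_ab <- tapply(y, list(a, b), mean)
  n_ab <- table(a, b)
  mean_s <- tapply(y, subject, mean); n_s <- table(droplevels(subject))
  ss_a <- ss(mean_a, n_a)
  ss_b <- ss(mean_b, n_b)
  ss_cells <- ss(mean_ab[!is.na(mean_ab)], n_ab[n_ab > 0])
  ss_int <- ss_cells - ss_a - ss_b
  ss_sub <- ss(mean_s, n_s)             # between-subject SS (includes A)
  ss_sub_err <- ss_sub - ss_a           # subjects within A
  ss_tot <- sum((y - gm)^2)
  ss_within_err <- ss_tot - ss_sub - ss_b - ss_int
  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_int <- df_a * df_b
  df_sub_err <- n_sub - nlevels(a)
  df_within_err <- df_sub_err * df_b
  assert_that(df_sub_err > 0, "need more subjects than between-factor levels")
  mse_sub <- ss_sub_err / df_sub_err
  mse_within <- ss_within_err / df_within_err
  tol <- 1e-10 * max(sum(y^2), 1)
  rows <- rbind(
    c(df_a, ss_a, safe_f(ss_a, df_a, mse_sub, df_sub_err, tol)),
    c(df_b, ss_b, safe_f(ss_b, df_b, mse_within, df_within_err, tol)),
    c(df_int, ss_int, safe_f(ss_int, df_int, mse_within, df_within_err, tol)))
  effects <- data.frame(term = c("A", "B", "A:B"), df = rows[, 1],
                        SS = rows[, 2], F = rows[, 3], p = rows[, 4],
                        df_error = c(df_sub_err, df_within_err, df_within_err))
  list(effects = effects, df_resid = c(df_sub_err, df_within_err),
       mse_comp = mse_within, df_comp = df_within_err)
}

# Pairwise comparisons of factor-a levels within each level of b, t tests on
# the supplied error term, Holm-Sidak adjusted across all comparisons.
pairwise_holm_sidak <- function(y, a, b, mse, df_err) {
  rows <- list()
  for (bl in levels(b)) {
    sel <- b == bl
    pairs <- utils::combn(levels(a), 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      yi <- y[sel & a == i]; yj <- y[sel & a == j]
      if (length(yi) == 0 || length(yj) == 0) next
      se <- sqrt(mse * (1 / length(yi) + 1 / length(yj)))
      t_stat <- if (se > 0) (mean(yi) - mean(yj)) / se else 0
      rows[[length(rows) + 1L]] <- data.frame(
        within = bl, level_i = i, level_j = j, t = t_stat, df = df_err,
        p_raw = 2 * pt(-abs(t_stat), df_err))
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_sidak_adjust(out$p_raw)
  out$method <- "holm_sidak"
  out
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(round(x$df, 2), collapse = ", ")
  cat(sprintf("<stat_result> %s: statistic = %.4f, df = %s, p = %.4g\n",
              x$test, x$statistic, dfs, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n"); print(x$posthoc)
  }
  invisible(x)
}
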