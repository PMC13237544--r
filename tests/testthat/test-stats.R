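test_that("identical groups give a null ANOVA and no pairwise table", {
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("control", "native", "ars"), each = 4)
  cmp <- compare_groups(v, g)
  expect_gt(cmp$anova_p, 0.99)
  expect_false(cmp$omnibus_significant)
  expect_null(cmp$pairwise)
  # all-constant groups are degenerate-flagged
  cmp2 <- compare_groups(rep(5, 12), g)
  expect_true(cmp2$degenerate)
})

test_that("a 5-SD shift is detected in essentially every simulation", {
  set.seed(21)
  hits <- mean(replicate(200, {
    v <- c(rnorm(20, 0, 1), rnorm(20, 5, 1), rnorm(20, 0, 1))
    g <- rep(c("control", "native", "ars"), each = 20)
    compare_groups(v, g)$anova_p < 0.0125
  }))
  expect_gte(hits, 0.99)
})

test_that("Tukey p-values match an independent studentized-range
           computation", {
  # fixed 3 x 5 toy table; oracle built directly from ptukey on the
  # classical q statistic with the pooled MSE
  v <- c(5.1, 4.8, 5.6, 5.0, 4.9,
         6.3, 6.8, 6.1, 6.6, 6.4,
         5.9, 5.5, 6.2, 5.7, 6.0)
  g <- rep(c("a", "b", "c"), each = 5)
  cmp <- compare_groups(v, g, threshold = 0.05)
  expect_true(cmp$omnibus_significant)
  means <- tapply(v, g, mean)
  mse <- sum((v - ave(v, g))^2) / (15 - 3)
  q_oracle <- function(i, j) {
    q <- abs(means[i] - means[j]) / sqrt(mse / 2 * (1 / 5 + 1 / 5))
    unname(ptukey(q, nmeans = 3, df = 12, lower.tail = FALSE))
  }
  pw <- cmp$pairwise
  expect_equal(pw$p[pw$contrast == "b-a"], q_oracle("b", "a"),
               tolerance = 1e-6)
  expect_equal(pw$p[pw$contrast == "c-a"], q_oracle("c", "a"),
               tolerance = 1e-6)
  expect_equal(pw$p[pw$contrast == "c-b"], q_oracle("c", "b"),
               tolerance = 1e-6)
})

test_that("the rank test matches exact enumeration oracles", {
  # identical non-constant samples: tie-corrected two-sided p of 1
  x <- c(0, 1, 2, 5, 9)
  r <- compare_abnormal_areas(x, x)
  expect_equal(r$p, 1)
  # complete separation at n = 10 vs 10: exact tail 2 / C(20, 10)
  a <- 1:10
  b <- 21:30
  r2 <- compare_abnormal_areas(a, b)
  expect_equal(r2$p, 2 / choose(20, 10), tolerance = 1e-6)
  # small-sample enumeration oracle (n = 4 vs 4, no ties)
  xx <- c(1.3, 2.1, 0.4, 3.3)
  yy <- c(2.8, 4.1, 3.9, 1.9)
  ranks <- rank(c(xx, yy))
  w_obs <- sum(ranks[1:4]) - 4 * 5 / 2
  combos <- combn(8, 4)
  wdist <- apply(combos, 2, function(id) sum(rank(c(xx, yy))[id])) - 10
  p_le <- mean(wdist <= w_obs)
  p_ge <- mean(wdist >= w_obs)
  p_exact <- min(1, 2 * min(p_le, p_ge))
  r3 <- compare_abnormal_areas(xx, yy)
  expect_equal(r3$p, p_exact, tolerance = 1e-6)
})

test_that("degenerate all-zero areas are reported as such", {
  r <- compare_abnormal_areas(rep(0, 6), rep(0, 8))
  expect_true(r$degenerate)
  expect_match(r$iqr_strings[["native"]], "0 \\(IQR: 0-0\\)")
  expect_true(is.na(r$p))
})

test_that("Pearson correlation matches the closed-form covariance
           formula", {
  x <- c(1.0, 2.0, 3.5, 4.1, 5.9, 7.2)
  y <- c(2.1, 1.8, 3.9, 4.4, 5.2, 8.0)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ct <- correlate(x, y)
  expect_equal(ct$r, r_hand, tolerance = 1e-12)
  expect_equal(correlate(x, x)$r, 1)
  # Fisher CI covers zero for independent noise about 95% of the time
  set.seed(31)
  cover <- mean(replicate(500, {
    a <- rnorm(50); b <- rnorm(50)
    ci <- correlate(a, b)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }))
  expect_gt(cover, 0.92); expect_lt(cover, 0.98)
  expect_error(correlate(c(1, 1, 1, 1), c(1, 2, 3, 4)), "variance")
})

test_that("the logistic odds ratio equals the closed-form 2x2 value", {
  # table (a, b, c, d) = (10, 10, 5, 20): OR = (10 * 20) / (10 * 5) = 4
  outcome <- c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 20))
  predictor <- c(rep(1, 20), rep(0, 25))
  fit <- logistic_univariable(outcome, predictor)
  expect_equal(fit$or, 4, tolerance = 1e-6)
  expect_false(fit$separation)
  # independence: CI covers 1 around 95% of the time
  set.seed(41)
  cover <- mean(replicate(200, {
    o <- rbinom(60, 1, 0.5)
    p <- rnorm(60)
    ci <- logistic_univariable(o, p)$ci
    ci[1] <= 1 && 1 <= ci[2]
  }))
  expect_gt(cover, 0.90)
  expect_error(logistic_univariable(rep(1, 20), rnorm(20)), "classes")
  # complete separation is flagged
  sep <- logistic_univariable(c(rep(0, 10), rep(1, 10)),
                              c(rnorm(10, -5), rnorm(10, 5)))
  expect_true(sep$separation)
  expect_true(is.na(sep$or))
})

test_that("incidence tables format counts the clinical way", {
  mk <- function(flag) data.frame(roi = "pAAo", class = "decreased",
                                  area_percent = ifelse(flag, 10, 0),
                                  any_abnormal_vertex = flag)
  s <- c(lapply(1:31, function(i) mk(TRUE)), list(mk(FALSE)))
  tab <- incidence_table(s)
  expect_equal(tab$label, "97% (31/32)")
  expect_equal(incidence_table(lapply(1:5, function(i) mk(FALSE)))$label,
               "0% (0/5)")
  expect_equal(incidence_table(lapply(1:7, function(i) mk(TRUE)))$label,
               "100% (7/7)")
})

test_that("tests are invariant to affine unit rescaling", {
  set.seed(51)
  v <- c(rnorm(10, 5), rnorm(10, 7), rnorm(10, 6))
  g <- rep(c("a", "b", "c"), each = 10)
  expect_equal(compare_groups(v, g)$anova_p,
               compare_groups(v * 3.6 + 11, g)$anova_p, tolerance = 1e-9)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(correlate(x, y)$r, correlate(x * 2 + 1, y * 0.1 - 5)$r,
               tolerance = 1e-12)
  expect_equal(compare_abnormal_areas(x, y)$p,
               compare_abnormal_areas(x * 4 + 2, y * 4 + 2)$p,
               tolerance = 1e-12)
})
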