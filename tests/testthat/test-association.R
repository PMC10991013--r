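test_that("coefficient choice follows the joint normality rule", {
  normal <- list(normal = TRUE); skewed <- list(normal = FALSE)
  expect_equal(choose_coefficient(normal, normal), "pearson")
  expect_equal(choose_coefficient(normal, skewed), "spearman")
  expect_equal(choose_coefficient(skewed, skewed), "spearman")
})

test_that("partial correlation matches the closed form and the residual oracle", {
  # equicorrelated triple r = 0.5 -> partial (0.5 - 0.25)/(1 - 0.25) = 1/3
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  L <- chol(S)
  set.seed(17)
  Z <- matrix(rnorm(3 * 40000), ncol = 3) %*% L
  pr <- partial_corr(Z[, 1], Z[, 2], Z[, 3])
  expect_lt(abs(pr$estimate - 1 / 3), 0.02)

  # exact check against an independent two-stage regression oracle
  set.seed(8)
  x <- rnorm(40); z1 <- rnorm(40); z2 <- rnorm(40)
  y <- 0.5 * x + 0.3 * z1 + rnorm(40)
  got <- partial_corr(x, y, cbind(z1, z2))
  rx <- resid(lm(x ~ z1 + z2)); ry <- resid(lm(y ~ z1 + z2))
  expect_equal(got$estimate, cor(rx, ry), tolerance = 1e-10)
  expect_equal(got$df, 40 - 2 - 2)

  # a control uncorrelated with both leaves the estimate almost unchanged
  set.seed(9)
  w <- rnorm(nrow(Z))
  pr2 <- partial_corr(Z[, 1], Z[, 2], w)
  expect_equal(pr2$estimate, cor(Z[, 1], Z[, 2]), tolerance = 0.03)
  expect_error(partial_corr(x, y, cbind(z1, z1)), "singular")
})

test_that("the battery composite standardizes, aligns and averages", {
  battery <- data.frame(t1 = c(10, 20, 30, 40), t2 = c(1, 2, 3, 4),
                        t3 = c(0, 0, 1, 1))
  comp <- average_performance_composite(battery, exclude = "t3")
  expect_equal(attr(comp, "components"), c("t1", "t2"))
  # participant at +1 SD on both components scores exactly +1
  z1 <- (battery$t1 - mean(battery$t1)) / sd(battery$t1)
  expect_equal(as.numeric(comp), z1)  # t1 and t2 are affine copies
  # sign map flips a worse-is-higher test
  comp2 <- average_performance_composite(battery, exclude = "t3",
                                         sign_map = c(t2 = -1))
  expect_equal(as.numeric(comp2), rep(0, 4))
  expect_error(average_performance_composite(battery, exclude = c("t1", "t2")),
               "fewer than two")
})

test_that("composite correlations ignore affine rescaling of components", {
  set.seed(4)
  b <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  score <- rnorm(60)
  c1 <- average_performance_composite(b, exclude = "c")
  b$a <- 100 + 7 * b$a
  c2 <- average_performance_composite(b, exclude = "c")
  expect_equal(cor(score, c1), cor(score, c2), tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment is a monotone step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  p <- c(0.001, 0.04, 0.02, 0.8)
  adj <- bh_adjust(p)
  expect_equal(order(adj), order(p))   # monotone in input ranks
  expect_true(all(adj >= p))           # never anti-conservative vs raw p
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the summary t test reproduces the pilot comparison", {
  tt <- ttest_from_summary(16.86, 3.08, 14, 16.59, 2.62, 17)
  expect_equal(tt$df, 29)
  expect_equal(rnd(tt$t), 0.26)
  # p = .795 as printed; inputs are 2-dp summaries, so allow their rounding
  expect_equal(tt$p_value, 0.795, tolerance = 0.002)

  expect_equal(ttest_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_equal(ttest_from_summary(5, 1, 10, 5, 1, 10)$p_value, 1)
  expect_warning(inf <- ttest_from_summary(5, 0, 10, 6, 0, 10), "infinite")
  expect_true(is.infinite(inf$t))

  # summary-stat t equals the raw-data pooled t
  set.seed(12)
  g1 <- rnorm(14, 17, 3); g2 <- rnorm(17, 16, 3)
  raw <- t.test(g1, g2, var.equal = TRUE)
  summ <- ttest_from_summary(mean(g1), sd(g1), 14, mean(g2), sd(g2), 17)
  expect_equal(summ$t, unname(raw$statistic), tolerance = 1e-12)
  expect_equal(summ$p_value, raw$p.value, tolerance = 1e-12)
})

test_that("Levene's check gates the pooled t test", {
  set.seed(6)
  same <- c(rnorm(50), rnorm(50))
  g <- rep(c("a", "b"), each = 50)
  lv <- levene_check(same, g)
  expect_true(lv$homogeneous)
  expect_equal(lv$df, c(1, 98))
  hetero <- c(rnorm(50, sd = 1), rnorm(50, sd = 5))
  expect_false(levene_check(hetero, g)$homogeneous)
  expect_error(levene_check(c(1, 2), c("a", "a")), "two groups")
})

test_that("the coefficient-difference Z behaves as a normal contrast", {
  expect_equal(clogg_z(0.4, 0.1, 0.4, 0.2)$z, 0)
  z <- clogg_z(0.5, 0.1, 0.2, 0.1)
  expect_equal(z$z, 0.3 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(z$z, 2.121, tolerance = 1e-3)
  # inflating either SE shrinks |Z|
  expect_lt(abs(clogg_z(0.5, 0.3, 0.2, 0.1)$z), abs(z$z))
  expect_error(clogg_z(1, 0, 1, 1), "positive")
})

test_that("the association battery adjusts within its stated family", {
  co <- simulate_cohort(default_vienna_profile(), seed = 6)
  m <- merge(co$participants[, c("participant_id", "total", "age")],
             co$covariates[, c("participant_id", "ptsot", "mmse", "gds")],
             by = "participant_id")
  res <- association_battery(m$total, m[, c("ptsot", "mmse", "gds")],
                             age = m$age)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adj_value >= res$p_value, na.rm = TRUE))
  expect_true(all(abs(res$estimate) <= 1))
  # missing covariate values shrink the pairwise n, never imputed
  expect_lt(res$n[res$variable == "gds"], nrow(m))
  # the strongly loaded test correlates positively with the total
  expect_gt(res$estimate[res$variable == "ptsot"], 0)
})
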