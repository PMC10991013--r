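test_that("forced-entry OLS matches the normal-equation oracle", {
  set.seed(15)
  n <- 120
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 + 0.8 * X$a - 0.5 * X$b + rnorm(n)
  fit <- forced_entry_ols(y, X, standardize = TRUE)
  Z <- scale(as.matrix(X))
  beta <- solve(t(cbind(1, Z)) %*% cbind(1, Z), t(cbind(1, Z)) %*% y)
  expect_equal(fit$coefficients$b, as.numeric(beta), tolerance = 1e-8)
  expect_equal(fit$coefficients$b[1], mean(y), tolerance = 1e-8)
  # CI brackets b; df consistent
  expect_true(all(fit$coefficients$ci_low <= fit$coefficients$b &
                  fit$coefficients$b <= fit$coefficients$ci_high))
  expect_equal(fit$df, c(3, n - 4))

  # exact linear outcome -> R^2 = 1 (lm warns about the perfect fit)
  y2 <- 1 + X$a + 2 * X$b
  expect_equal(suppressWarnings(forced_entry_ols(y2, X)$r_squared), 1,
               tolerance = 1e-12)

  # pure noise at larger n: R^2 near p/n, coefficients near zero
  set.seed(16)
  Xn <- as.data.frame(matrix(rnorm(500 * 5), 500, 5))
  fitn <- forced_entry_ols(rnorm(500), Xn)
  expect_lt(fitn$r_squared, 0.05)
  expect_true(all(abs(fitn$coefficients$b[-1]) < 0.2))

  expect_error(forced_entry_ols(y, data.frame(a = X$a, k = rep(1, n))),
               "constant predictor")
  expect_error(forced_entry_ols(y, data.frame(a = X$a, a2 = 2 * X$a)),
               "collinear")
})

test_that("nested model comparison matches the sums-of-squares oracle", {
  set.seed(20)
  n <- 90
  X <- data.frame(u = rnorm(n), v = rnorm(n), w = rnorm(n))
  y <- 1 + 1.0 * X$u + rnorm(n, sd = 0.5)
  full <- forced_entry_ols(y, X)
  reduced <- forced_entry_ols(y, X[c("u", "v")])
  an <- nested_anova(full, reduced)
  # from-scratch oracle
  sse_f <- sum(resid(full$fit)^2); sse_r <- sum(resid(reduced$fit)^2)
  f_oracle <- ((sse_r - sse_f) / 1) / (sse_f / (n - 4))
  expect_equal(an$f, f_oracle, tolerance = 1e-12)
  expect_equal(an$df1, 1)
  expect_equal(an$df2, n - 4)
  expect_equal(an$delta_r2, full$r_squared - reduced$r_squared)

  # identical models: no variance lost
  same <- nested_anova(full, full)
  expect_equal(same$f, 0)
  expect_equal(same$delta_r2, 0)

  # dropping a strong true predictor loses significant variance
  weak <- forced_entry_ols(y, X[c("v", "w")])
  expect_lt(nested_anova(full, weak)$p_value, 0.001)
  expect_error(nested_anova(reduced, forced_entry_ols(y, X["w"])),
               "not nested")
})

test_that("p-based reduction retains true predictors and stops correctly", {
  set.seed(30)
  n <- 200; p <- 9
  true_idx <- 1:4
  beta <- c(0.6, 0.5, 0.45, 0.4, rep(0, 5))
  exact <- 0
  for (r in 1:40) {
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(X) <- paste0("x", 1:p)
    y <- as.matrix(X) %*% beta + rnorm(n)
    red <- suppressWarnings(reduce_by_p(y, X))
    sel <- red$model$predictors
    # recall: strong true predictors are never lost
    expect_true(all(paste0("x", true_idx) %in% sel))
    # stop-rule consistency: at a natural stop all retained are significant
    if (red$stop_reason == "all predictors significant") {
      co <- red$model$coefficients
      expect_true(all(co$p_value[co$term != "(Intercept)"] < 0.05))
    }
    exact <- exact + setequal(sel, paste0("x", true_idx))
  }
  # exact support recovery: each null survives with prob ~ alpha, so the
  # expected rate is ~(1 - .05)^5 ~ 0.77; 0.65 is a conservative band
  expect_gte(exact / 40, 0.65)
})

test_that("reduction is deterministic and reverts on significant loss", {
  set.seed(31)
  X <- as.data.frame(matrix(rnorm(150 * 6), 150, 6))
  names(X) <- paste0("x", 1:6)
  y <- as.matrix(X) %*% c(1, 0.8, 0.6, 0, 0, 0) + rnorm(150)
  r1 <- reduce_by_p(y, X); r2 <- reduce_by_p(y, X)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$model$predictors, r2$model$predictors)
  expect_equal(r1$trace$rule[1], "full model")

  # a model whose every predictor matters: no reduction step happens
  set.seed(32)
  Xs <- as.data.frame(matrix(rnorm(300 * 3), 300, 3))
  names(Xs) <- c("a", "b", "c")
  ys <- as.matrix(Xs) %*% c(1, 1, 1) + rnorm(300, sd = 0.5)
  rs <- reduce_by_p(ys, Xs)
  expect_equal(nrow(rs$trace), 1)
  expect_equal(rs$stop_reason, "all predictors significant")
})

test_that("AIC backward selection prunes noise and keeps strong effects", {
  set.seed(40)
  n <- 300
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- paste0("x", 1:6)
  # single huge effect: always retained
  y1 <- 2 * X$x1 + rnorm(n, sd = 0.5)
  expect_true("x1" %in% aic_backward(y1, X)$predictors)
  # pure noise: near-empty model (each null kept with prob ~ P(chisq > 2))
  y0 <- rnorm(n)
  expect_lte(length(aic_backward(y0, X)$predictors), 2)
  # strong sparse truth: both procedures agree on the true actives
  beta <- c(0.7, 0.6, 0, 0, 0, 0)
  y2 <- as.matrix(X) %*% beta + rnorm(n)
  sel_aic <- aic_backward(y2, X)$predictors
  sel_p <- reduce_by_p(y2, X)$model$predictors
  expect_true(all(c("x1", "x2") %in% sel_aic))
  expect_true(all(c("x1", "x2") %in% sel_p))
})
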