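test_that("score frequencies count the three point classes", {
  expect_equal(item_frequencies(c(2, 2, 1)),
               c(freq0 = 0L, freq1 = 1L, freq2 = 2L))
  expect_error(item_frequencies(numeric(0)), "no scores")
  expect_error(item_frequencies(c(0, 3)), "0, 1 or 2")
})

test_that("published item summaries are recomputed exactly from frequencies", {
  t2 <- table2_fixture()
  for (i in seq_len(nrow(t2))) {
    mv <- item_mean_variance(c(t2$freq0[i], t2$freq1[i], t2$freq2[i]))
    expect_equal(mv$n, 79)
    expect_equal(rnd(mv$mean), t2$printed_mean[i],
                 info = paste("mean of", t2$item_id[i]))
    expect_equal(rnd(mv$variance), t2$printed_variance[i],
                 info = paste("variance of", t2$item_id[i]))
    # the published ratio applies report-time rounding to the mean first
    expect_equal(rnd(difficulty_ratio(rnd(mv$mean), t2$expected[i])),
                 t2$printed_ratio[i],
                 info = paste("ratio of", t2$item_id[i]))
  }
})

test_that("type-average difficulty reproduces the published gradient", {
  t2 <- table2_fixture()
  means <- vapply(seq_len(nrow(t2)), function(i)
    item_mean_variance(c(t2$freq0[i], t2$freq1[i], t2$freq2[i]))$mean,
    numeric(1))
  stats <- data.frame(item_type = t2$item_type,
                      difficulty_ratio = rnd(difficulty_ratio(rnd(means), t2$expected)))
  avg <- item_type_difficulty(stats)
  expect_equal(avg$item_type,
               c("no-turn", "single-turn", "double-turn", "full-turn"))
  expect_equal(rnd(avg$mean_difficulty_ratio), c(6.25, 6.01, 4.48, 2.38))
  # difficulty increases (ratio decreases) with turn complexity
  expect_true(all(diff(avg$mean_difficulty_ratio[2:4]) < 0))
})

test_that("difficulty ratio is scale consistent and guards its domain", {
  expect_equal(difficulty_ratio(1.2, 1.2), 1)
  expect_equal(difficulty_ratio(2 * 1.3, 2 * 0.5),
               difficulty_ratio(1.3, 0.5))
  expect_error(difficulty_ratio(1, 0), "positive")
  expect_error(item_type_difficulty(
    data.frame(item_type = "diagonal", difficulty_ratio = 1)), "unknown")
})

test_that("Wilson's e handles its canonical cases", {
  expect_equal(wilsons_e(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(wilsons_e(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  x <- c(0, 1, 1, 2, 2, 2, 0, 1); y <- c(3, 5, 4, 8, 9, 7, 4, 6)
  expect_equal(wilsons_e(x, -y), -wilsons_e(x, y))
  expect_warning(e <- wilsons_e(c(1, 1, 1), c(2, 2, 2)), "undefined")
  expect_true(is.na(e))
})

test_that("Wilson's e matches the O(n^2) pair-count oracle", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    x <- sample(0:2, n, replace = TRUE)
    y <- sample(0:8, n, replace = TRUE)
    ex <- wilsons_e_oracle(x, y)
    if (is.na(ex)) next
    expect_equal(wilsons_e(x, y), ex)
  }
  # without ties e equals Kendall's tau-a
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    x <- sample(seq_len(100), n)
    y <- sample(seq_len(100), n)
    expect_equal(wilsons_e(x, y),
                 cor(x, y, method = "kendall"))
  }
})

test_that("corrected item-total correlation uses the rest score", {
  # two identical informative items: each correlates perfectly with its rest
  set.seed(1)
  base <- sample(0:2, 60, replace = TRUE)
  e <- corrected_item_total(cbind(i1 = base, i2 = base))
  expect_equal(unname(e["i1"]), 1)
  # an item independent of the rest has e near zero at large n
  set.seed(2)
  big <- cbind(a = sample(0:2, 5000, replace = TRUE),
               b = sample(0:2, 5000, replace = TRUE),
               c = sample(0:2, 5000, replace = TRUE))
  expect_lt(abs(corrected_item_total(big)["a"]), 0.05)
  # a zero-variance item carries no discrimination: every pair is tied on
  # it, so C = D = 0 while the tied-on-x pairs keep the denominator
  # positive, giving e = 0 (matching the pair-count oracle and the
  # published convention of printing 0.00 for the no-variance item)
  zv <- cbind(k = rep(2L, 30), l = sample(0:2, 30, replace = TRUE),
              m = sample(0:2, 30, replace = TRUE))
  expect_equal(unname(corrected_item_total(zv)["k"]), 0)
  expect_equal(wilsons_e_oracle(zv[, "k"], zv[, "l"] + zv[, "m"]), 0)
})

test_that("item means are linear: their sum equals the mean total score", {
  co <- simulate_cohort(default_vienna_profile(), seed = 5)
  ia <- item_analysis(co$scores, configs = co$config$items)
  expect_equal(sum(ia$mean), mean(co$participants$total))
  # and the default bank's expectations match the published E at 2 dp
  t2 <- table2_fixture()
  expect_equal(rnd(ia$expected[match(t2$item_id, ia$item_id)]), t2$expected)
})
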