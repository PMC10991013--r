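test_that("the rubric maps each door class to its points and error type", {
  cfg <- item_config("t", "double-turn", n_doors = 10L, correct_door = 3L,
                     updating_doors = c(2L, 4L), rotation_doors = 8L)
  expect_equal(score_response(cfg, 3)[c("points", "error_type")],
               list(points = 2L, error_type = "none"))
  expect_equal(score_response(cfg, 8)[c("points", "error_type")],
               list(points = 1L, error_type = "rotation"))
  expect_equal(score_response(cfg, 4)[c("points", "error_type")],
               list(points = 1L, error_type = "updating"))
  expect_equal(score_response(cfg, 9)[c("points", "error_type")],
               list(points = 0L, error_type = "other"))
  expect_error(score_response(cfg, 11, participant_id = "p1"),
               "p1.*door 11|door 11.*p1")
  expect_error(score_response(cfg, 0), "door 0")
})

test_that("item configurations enforce the door-set invariants", {
  expect_error(item_config("x", "no-turn", 4, 5), "1\\.\\.4")
  expect_error(item_config("x", "no-turn", 4, 2, updating_doors = 2),
               "one-point set")
  expect_error(item_config("x", "no-turn", 6, 1, updating_doors = 3,
                           rotation_doors = 3), "overlap")
  # duplicates collapse, capacity 1+1+1 <= 3 holds
  expect_no_error(item_config("x", "no-turn", 3, 1, updating_doors = 2,
                              rotation_doors = c(3, 3, 3), is_main = TRUE))
})

test_that("expected score equals the enumeration mean over all doors", {
  cfg4 <- item_config("e1", "no-turn", 4, 2)
  expect_identical(expected_item_score(cfg4), 0.5)
  cfg10 <- item_config("e2", "single-turn", 10, 1, updating_doors = 5)
  expect_identical(expected_item_score(cfg10), 0.3)
  cfg19 <- item_config("e3", "no-turn", 19, 4, updating_doors = 5,
                       rotation_doors = 13)
  expect_equal(expected_item_score(cfg19), 4 / 19)

  # property: uniform enumeration over doors reproduces E for random configs,
  # and the rubric partitions the doors (every door scores exactly once)
  set.seed(42)
  for (rep in 1:25) {
    nd <- sample(4:20, 1)
    doors <- sample(nd)
    n_upd <- sample(0:2, 1); n_rot <- sample(0:2, 1)
    cfg <- item_config("r", "full-turn", nd, doors[1],
                       updating_doors = doors[1 + seq_len(n_upd)],
                       rotation_doors = doors[1 + n_upd + seq_len(n_rot)])
    pts <- vapply(seq_len(nd), function(d) score_response(cfg, d)$points,
                  integer(1))
    expect_equal(mean(pts), expected_item_score(cfg))
    expect_equal(sum(pts == 2), 1)
    expect_equal(sum(pts == 1), n_upd + n_rot)
  }
})

test_that("participant totals aggregate points and error counts", {
  bank <- default_item_bank()
  all_correct <- data.frame(
    item_id = vapply(bank, `[[`, character(1), "item_id"),
    chosen_door = vapply(bank, `[[`, integer(1), "correct_door"))
  s <- score_participant(bank, all_correct, "pmax")
  expect_equal(s$total, 24L)
  expect_equal(s$n_updating + s$n_rotation, 0L)

  # 10 correct, one rotation door, one zero-point door
  mixed <- all_correct
  mixed$chosen_door[1] <- bank[[1]]$rotation_doors[1]
  zero_door <- setdiff(seq_len(bank[[2]]$n_doors),
                       c(bank[[2]]$correct_door, bank[[2]]$updating_doors,
                         bank[[2]]$rotation_doors))[1]
  mixed$chosen_door[2] <- zero_door
  s2 <- score_participant(bank, mixed, "pmix")
  expect_equal(s2$total, 21L)
  expect_equal(s2$n_rotation, 1L)
  expect_equal(s2$n_updating, 0L)

  # all zero-point doors -> total 0
  zeros <- all_correct
  zeros$chosen_door <- vapply(bank, function(cfg)
    setdiff(seq_len(cfg$n_doors),
            c(cfg$correct_door, cfg$updating_doors, cfg$rotation_doors))[1],
    integer(1))
  expect_equal(score_participant(bank, zeros, "p0")$total, 0L)

  # order invariance
  shuf <- mixed[sample(nrow(mixed)), ]
  expect_equal(score_participant(bank, shuf, "pmix")$total, s2$total)
})

test_that("degenerate response sets are rejected or scored as missing", {
  bank <- mini_bank()
  resp <- data.frame(item_id = c("a", "a"), chosen_door = c(1, 2))
  expect_error(score_participant(bank, resp, "p1"), "duplicate")
  expect_error(score_participant(bank, data.frame(item_id = "zz", chosen_door = 1)),
               "unconfigured")
  partial <- data.frame(item_id = c("a", "b", "c"), chosen_door = c(1, 2, 5))
  expect_warning(s <- score_participant(bank, partial, "p1"),
                 "no response for item d")
  expect_equal(s$total, 6L)
  expect_equal(s$items$error_type[s$items$item_id == "d"], "other")
})

test_that("practice trials are excluded from the total", {
  bank <- c(mini_bank(),
            list(item_config("practice", "no-turn", 4, 1, is_main = FALSE)))
  resp <- data.frame(item_id = c("a", "b", "c", "d", "practice"),
                     chosen_door = c(1, 2, 5, 3, 1))
  s <- score_participant(bank, resp, "p1")
  expect_equal(s$n_items_scored, 4L)
  expect_equal(s$total, 8L)
})
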