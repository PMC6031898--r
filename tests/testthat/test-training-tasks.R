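test_that("abm correct-response rule matches the meaning-vs-ink contract", {
  s <- list(left_word_meaning = "red", left_word_ink = "green",
            right_item_text_category = "meth_word", right_item_ink = "red",
            distractor_picture_category = "meth")
  expect_equal(abm_correct_response(s), "consistent")
  # distractor and the left word's own ink are irrelevant
  s$left_word_meaning <- "blue"; s$right_item_ink <- "blue"
  expect_equal(abm_correct_response(s), "consistent")
  s$left_word_meaning <- "yellow"; s$right_item_ink <- "green"
  expect_equal(abm_correct_response(s), "inconsistent")
})

test_that("act correct-response rule follows the single/neutral border", {
  one <- list(n_pictures = 1L, picture_categories = "meth",
              border_colors = "red")
  expect_equal(act_correct_response(one), "red")
  two <- list(n_pictures = 2L, picture_categories = c("meth", "neutral"),
              border_colors = c("blue", "yellow"))
  expect_equal(act_correct_response(two), "yellow")
  one$picture_categories <- "neutral"; one$border_colors <- "green"
  expect_equal(act_correct_response(one), "green")
  bad <- list(n_pictures = 2L, picture_categories = c("meth", "meth"),
              border_colors = c("red", "blue"))
  expect_error(act_correct_response(bad), "invalid stimulus")
})

test_that("nback correct-response is a shape-and-color conjunction", {
  fig <- function(s, c) list(figure_shape = s, figure_color = c)
  h <- list(fig("circle", "red"), fig("triangle", "blue"),
            fig("circle", "red"))
  expect_equal(nback_correct_response(h, 2), "yes")
  h2 <- list(fig("circle", "red"), fig("triangle", "red"))
  expect_equal(nback_correct_response(h2, 1), "no")
  expect_true(is.na(nback_correct_response(h, 3)))  # warm-up
})

test_that("nback staircase follows the 90%-twice rule with cap and resets", {
  st <- nback_state()
  for (acc in c(0.92, 0.95)) st <- nback_update_level(st, acc)
  expect_equal(st$level, 2L)

  st <- nback_state()
  for (acc in c(0.92, 0.85, 0.95)) st <- nback_update_level(st, acc)
  expect_equal(st$level, 1L)
  expect_equal(st$success_streak, 1L)

  st <- nback_state(level = 3)
  for (acc in c(1, 1, 1, 1)) st <- nback_update_level(st, acc)
  expect_equal(st$level, 3L)  # cap

  # exact boundary counts as qualifying
  st <- nback_state()
  for (acc in c(0.90, 0.90)) st <- nback_update_level(st, acc)
  expect_equal(st$level, 2L)
})

test_that("matrix staircase trace matches a hand simulation", {
  st <- matrix_state()
  for (ok in c(TRUE, TRUE, TRUE)) st <- matrix_update_span(st, ok)
  expect_equal(st$span, 4L)

  st <- matrix_state()
  for (ok in c(FALSE, FALSE, FALSE)) st <- matrix_update_span(st, ok)
  expect_equal(st$span, 2L)

  st <- matrix_state()
  for (ok in c(TRUE, TRUE, FALSE, TRUE)) st <- matrix_update_span(st, ok)
  expect_equal(st$span, 3L)
  expect_equal(st$success_streak, 1L)
  expect_equal(st$failure_streak, 0L)

  # floor at span_min
  st <- matrix_state(span = 2)
  for (ok in rep(FALSE, 9)) st <- matrix_update_span(st, ok)
  expect_equal(st$span, 2L)
})

test_that("schedules are balanced exactly as configured", {
  sched <- generate_act_schedule(task_config("act"), seed = 1)
  expect_length(sched, 240)
  expect_equal(sum(vapply(sched, function(s) s$n_pictures, integer(1)) == 2),
               120)

  block <- generate_nback_block(task_config("nback"), level = 2, seed = 1)
  expect_equal(sum(block$is_target, na.rm = TRUE), 6)  # 0.3 * 20
  expect_equal(sum(block$is_warmup), 2)

  abm <- generate_abm_schedule(task_config("abm"), seed = 1)
  main <- abm$stimulus[abm$phase == "main"]
  cons <- vapply(main, function(s) abm_correct_response(s) == "consistent",
                 logical(1))
  expect_equal(sum(cons), 60)
  expect_true(all(vapply(main, function(s)
    s$distractor_picture_category == "meth", logical(1))))
})

test_that("correct-response rules agree with brute-force re-derivation", {
  set.seed(42)
  abm <- generate_abm_schedule(task_config("abm"))
  for (s in abm$stimulus) {
    expect_equal(abm_correct_response(s),
                 if (s$left_word_meaning == s$right_item_ink) "consistent"
                 else "inconsistent")
  }
  act <- generate_act_schedule(task_config("act"))
  for (s in act) {
    want <- s$border_colors[if (s$n_pictures == 1) 1 else
      which(s$picture_categories == "neutral")]
    expect_equal(act_correct_response(s), want)
  }
  block <- generate_nback_block(task_config("nback"), level = 3)
  stims <- block$stimulus
  for (i in seq_along(stims)) {
    tok <- nback_correct_response(stims[seq_len(i)], 3)
    if (i <= 3) expect_true(is.na(tok))
    else expect_equal(tok, if (identical(stims[[i]][1:2], stims[[i - 3]][1:2]))
      "yes" else "no")
  }
})

test_that("level and span trajectories respect staircase bounds", {
  log <- run_session(task_config("nback"), agent_params(), seed = 21)
  levels <- vapply(log$stimulus, function(s) s$level, numeric(1))
  expect_true(all(diff(levels) >= 0))       # never decreases in-session
  expect_true(all(levels %in% 1:3))

  log <- run_session(task_config("matrix"),
                     agent_params(responder = list(p_correct = 0.6)),
                     seed = 21)
  spans <- vapply(log$stimulus, function(s) s$span, numeric(1))
  expect_true(all(abs(diff(spans)) <= 1))   # at most 1 step per trial
  expect_true(all(spans >= task_config("matrix")$span_min))
})

test_that("a perfect agent reaches 3-back after exactly 4 blocks and a
           guessing agent never leaves 1-back", {
  log <- run_session(task_config("nback"), perfect_agent(), seed = 8)
  blocks <- attr(log, "blocks")
  expect_equal(blocks$level, c(1, 1, 2, 2))
  expect_equal(attr(log, "final_state")$level, 3L)

  for (seed in 1:5) {
    log <- run_session(task_config("nback"),
                       agent_params(responder = list(p_correct = 0.5)),
                       seed = seed)
    expect_equal(attr(log, "final_state")$level, 1L)
  }
})

test_that("matrix trials stay inside the grid and grow it past span 8", {
  st <- matrix_state(span = 9)
  tr <- generate_matrix_trial(st, seed = 1)
  expect_equal(tr$grid_dims, c(6, 6))
  expect_equal(nrow(tr$target_cells), 9)
  expect_false(any(duplicated(paste(tr$target_cells[, 1],
                                    tr$target_cells[, 2]))))
  expect_true(all(tr$target_cells >= 1 & tr$target_cells <= 6))

  st5 <- matrix_state(span = 4)
  tr5 <- generate_matrix_trial(st5, seed = 1)
  expect_equal(tr5$grid_dims, c(5, 5))
})
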