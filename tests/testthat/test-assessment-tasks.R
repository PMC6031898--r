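test_that("titration follows the halving schedule exactly", {
  cfg <- task_config("ddt")
  v <- ddt_titrate(function(i, A, D) "immediate", cfg, 30)
  expect_identical(v$indifference_point, 7.8125)
  expect_equal(v$trace$step, c(250, 125, 62.5, 31.25, 15.625, 7.8125))
  expect_equal(v$trace$immediate_offer[1], 500)

  v2 <- ddt_titrate(function(i, A, D) "delayed", cfg, 30)
  expect_identical(v2$indifference_point, 992.1875)
})

test_that("titration brackets any threshold agent within the resolution", {
  cfg <- task_config("ddt")
  res <- cfg$initial_immediate / 2^cfg$n_adjustments
  set.seed(1)
  for (v_true in c(3, 123.4, 400, 499, 501, 875.2, 997)) {
    got <- ddt_titrate(threshold_ddt_agent(v_true), cfg, 30)$indifference_point
    expect_lt(abs(got - v_true), res + 1e-9)
  }
})

test_that("hyperbolic k inverts the decay model and round-trips", {
  expect_identical(hyperbolic_k(1000, 1000, 30), 0)
  expect_equal(hyperbolic_k(500, 1000, 30), 1 / 30)
  expect_equal(hyperbolic_k(400, 1000, 30), 0.05)
  expect_warning(expect_true(is.na(hyperbolic_k(-5, 1000, 30))),
                 "non-positive")
  for (k in c(0.002, 0.01, 0.05, 0.25)) {
    for (D in c(2, 7, 30, 90, 180, 360)) {
      expect_equal(hyperbolic_k(1000 / (1 + k * D), 1000, D), k,
                   tolerance = 1e-12)
    }
  }
})

test_that("fit_global_k recovers noiseless k and degenerates gracefully", {
  delays <- c(2, 7, 30, 90, 180, 360)
  for (k in c(0.002, 0.01, 0.05, 0.25)) {
    pts <- data.frame(delay_days = delays,
                      indifference_point = 1000 / (1 + k * delays))
    expect_equal(fit_global_k(pts, 1000)$k, k, tolerance = 1e-6)
  }
  one <- data.frame(delay_days = 30, indifference_point = 500)
  expect_equal(fit_global_k(one, 1000)$k, 1 / 30)
  flat <- data.frame(delay_days = delays,
                     indifference_point = rep(1000, 6))
  expect_equal(fit_global_k(flat, 1000)$k, 0)
  expect_equal(fit_global_k(flat, 1000)$ln_k, -Inf)
})

test_that("fit_global_k tolerates multiplicative noise (median within 20%)", {
  delays <- c(2, 7, 30, 90, 180, 360)
  k_true <- 0.02
  err <- vapply(1:100, function(s) {
    set.seed(s)
    v <- 1000 / (1 + k_true * delays) * runif(6, 0.95, 1.05)
    abs(fit_global_k(data.frame(delay_days = delays,
                                indifference_point = v), 1000)$k - k_true)
  }, numeric(1))
  expect_lt(median(err) / k_true, 0.20)
})

test_that("canonical gambling decks net -250/+250 per 10-pick block", {
  sched <- igt_schedule(150)
  for (d in c("A", "B")) {
    deck <- sched$decks[[d]]
    nets <- tapply(deck$net, (seq_len(150) - 1) %/% 10, sum)
    expect_true(all(nets == -250))
    expect_true(all(deck$win == 100))
  }
  for (d in c("C", "D")) {
    deck <- sched$decks[[d]]
    nets <- tapply(deck$net, (seq_len(150) - 1) %/% 10, sum)
    expect_true(all(nets == 250))
    expect_true(all(deck$win == 50))
  }
})

test_that("gambling net score counts advantageous minus disadvantageous", {
  expect_equal(igt_net_score(rep(c("C", "D"), 75)), 150)
  expect_equal(igt_net_score(rep(c("A", "C"), 75)), 0)
  choices <- c(rep("A", 40), rep("B", 35), rep("C", 45), rep("D", 30))
  expect_equal(igt_net_score(choices), 0)
  # conservation: net + 2 * disadvantageous == total picks
  set.seed(3)
  for (i in 1:20) {
    ch <- sample(c("A", "B", "C", "D"), 150, replace = TRUE)
    expect_equal(igt_net_score(ch) + 2 * sum(ch %in% c("A", "B")), 150)
  }
})

test_that("balloon scores implement both numerator readings", {
  b <- data.frame(pumps = c(5, 3), exploded = c(FALSE, FALSE))
  s <- bart_score(b)
  expect_equal(s$literal, 4.0)
  expect_equal(s$adjusted, 4.0)

  b2 <- data.frame(pumps = c(10, 4, 6), exploded = c(TRUE, FALSE, FALSE))
  s2 <- bart_score(b2)
  expect_equal(s2$literal, 10.0)
  expect_equal(s2$adjusted, 5.0)
  expect_equal(s2$points, 100)

  s0 <- bart_score(data.frame(pumps = c(0, 0), exploded = c(FALSE, FALSE)))
  expect_equal(s0$literal, 0)
  expect_equal(s0$points, 0)

  all_burst <- bart_score(data.frame(pumps = 3, exploded = TRUE))
  expect_true(all_burst$undefined)
  expect_true(is.na(all_burst$literal))
})

test_that("literal >= adjusted always, equal iff nothing exploded", {
  set.seed(9)
  for (i in 1:50) {
    b <- data.frame(pumps = rpois(30, 20),
                    exploded = runif(30) < 0.4)
    if (!any(!b$exploded)) next
    s <- bart_score(b)
    expect_gte(s$literal, s$adjusted)
    if (!any(b$exploded & b$pumps > 0)) expect_equal(s$literal, s$adjusted)
    else expect_gt(s$literal, s$adjusted)
  }
})

test_that("balloon schedule is uniform on 1..max_pumps", {
  cfg <- task_config("bart")
  sched <- generate_bart_schedule(cfg, seed = 12)
  expect_length(sched, 100)
  expect_identical(sched, generate_bart_schedule(cfg, seed = 12))
  set.seed(1)
  big <- generate_bart_schedule(task_config("bart", n_balloons = 1e5))
  expect_true(all(big >= 1 & big <= 128))
  expect_lt(abs(mean(big) - 64.5) / 64.5, 0.01)
})

test_that("stroop schedule balances words, colors, and category runs", {
  sched <- generate_stroop_schedule(task_config("stroop"), seed = 7)
  expect_equal(nrow(sched), 128)
  expect_true(all(table(sched$category) == 64))
  expect_true(all(table(sched$word) == 8))
  expect_true(all(table(sched$word, sched$ink) == 2))
  runs <- rle(sched$category)
  expect_lte(max(runs$lengths), 3)
})

test_that("stroop bias is the meth-minus-neutral latency difference", {
  log <- random_stroop_log()
  lat_const <- log
  lat_const$latency_ms <- ifelse(
    vapply(lat_const$stimulus, function(s) s$category, character(1)) ==
      "meth_word", 800, 650)
  sb <- stroop_bias(lat_const)
  expect_equal(sb$bias_ms, 150)

  same <- log
  same$latency_ms <- rep(700, nrow(same))
  expect_equal(stroop_bias(same)$bias_ms, 0)
})

test_that("stroop bias centers near zero for an unbiased responder", {
  biases <- vapply(1:60, function(s) {
    log <- run_session(task_config("stroop"), agent_params(), seed = s)
    stroop_bias(log)$bias_ms
  }, numeric(1))
  # latency sd ~130 ms, 64 trials/category: |bias| < 50 ms almost surely
  expect_gt(mean(abs(biases) < 50), 0.90)
  expect_lt(abs(mean(biases)), 15)
})
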