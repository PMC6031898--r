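test_that("summary F test reproduces baseline-table statistics", {
  age <- summary_f_test(group_summary(20, 32.70, 5.27),
                        group_summary(20, 35.05, 8.02))
  expect_equal(age$F, 1.200, tolerance = 0.01)
  expect_equal(age$df, c(1L, 38L))

  onset <- summary_f_test(group_summary(20, 24.45, 6.54),
                          group_summary(20, 25.15, 8.56))
  expect_equal(round(onset$F, 3), 0.084)

  same <- summary_f_test(group_summary(10, 5, 1), group_summary(10, 5, 1))
  expect_equal(same$F, 0)

  degen_eq <- summary_f_test(group_summary(5, 2, 0), group_summary(5, 2, 0))
  expect_equal(degen_eq$F, 0)
  degen_ne <- summary_f_test(group_summary(5, 2, 0), group_summary(5, 3, 0))
  expect_true(is.infinite(degen_ne$F))
})

test_that("summary F equals squared pooled t on the raw samples", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(12, 10, 2); y <- rnorm(17, 11, 3)
    res <- summary_f_test(group_summary(length(x), mean(x), sd(x)),
                          group_summary(length(y), mean(y), sd(y)))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("chi-square is Pearson without correction", {
  tab <- rbind(c(14, 4, 1, 1), c(10, 8, 1, 1))
  res <- chi_square_test(tab)
  expect_equal(res$chisq, 2.0, tolerance = 1e-12)
  expect_equal(res$df, 3)

  flat <- rbind(c(10, 10), c(10, 10))
  expect_equal(chi_square_test(flat)$chisq, 0)

  # zero iff observed equals expected; invariant to permutation
  set.seed(15)
  tab2 <- matrix(rpois(8, 20) + 1, 2)
  r1 <- chi_square_test(tab2)
  r2 <- chi_square_test(tab2[, sample(ncol(tab2))])
  expect_equal(r1$chisq, r2$chisq)

  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("mixed ANOVA trivial cases: no change, zero noise, label swap", {
  panel <- simulate_trial(n_per_arm = 10, seed = 31)
  wide_pre <- panel[panel$time == "pre", ]
  same <- rbind(wide_pre, transform(wide_pre, time = "post"))
  res <- group_time_anova(same)
  expect_equal(res$F_time, 0)
  expect_equal(res$F_interaction, 0)

  # additive group x time effect with zero noise: infinite-F flag
  det <- expand.grid(subject = sprintf("s%02d", 1:10), time = c("pre", "post"),
                     stringsAsFactors = FALSE)
  det$group <- ifelse(as.integer(sub("s", "", det$subject)) <= 5,
                      "ccat", "control")
  det$value <- ifelse(det$group == "ccat" & det$time == "post", 1, 0)
  expect_true(is.infinite(group_time_anova(det)$F_interaction))

  swapped <- panel
  swapped$group <- ifelse(panel$group == "ccat", "control", "ccat")
  expect_equal(group_time_anova(swapped)$F_interaction,
               group_time_anova(panel)$F_interaction, tolerance = 1e-12)
})

test_that("sums of squares partition and match aov on simulated panels", {
  for (seed in 1:5) {
    panel <- simulate_trial(n_per_arm = 8, sd_subject = 1.5,
                            means = matrix(c(1, 0.2, 2, 0.1), 2), seed = seed)
    res <- group_time_anova(panel)
    ss <- res$ss
    expect_equal(sum(ss$ss[ss$term != "total"]), ss$ss[ss$term == "total"],
                 tolerance = 1e-9)

    fit <- stats::aov(value ~ group * time + Error(subject),
                      data = transform(panel, subject = factor(subject),
                                       group = factor(group),
                                       time = factor(time, c("pre", "post"))))
    s <- summary(fit)
    between <- s[["Error: subject"]][[1]]
    within <- s[["Error: Within"]][[1]]
    expect_equal(res$F_group, between["group", "F value"], tolerance = 1e-8)
    expect_equal(res$F_time, within["time", "F value"], tolerance = 1e-8)
    expect_equal(res$F_interaction, within["group:time", "F value"],
                 tolerance = 1e-8)
    expect_equal(res$p_interaction, within["group:time", "Pr(>F)"],
                 tolerance = 1e-8)
  }
})

test_that("interaction F equals the squared two-sample t on change scores", {
  for (seed in 6:10) {
    panel <- simulate_trial(n_per_arm = 12, seed = seed)
    res <- group_time_anova(panel)
    wide <- merge(panel[panel$time == "pre", c("subject", "group", "value")],
                  panel[panel$time == "post", c("subject", "value")],
                  by = "subject", suffixes = c("_pre", "_post"))
    d <- wide$value_post - wide$value_pre
    tt <- t.test(d[wide$group == "ccat"], d[wide$group == "control"],
                 var.equal = TRUE)
    expect_equal(res$F_interaction, unname(tt$statistic)^2, tolerance = 1e-8)
  }
})

test_that("interaction power matches the analytic change-score oracle", {
  delta <- 1; sd_resid <- 1; n <- 20
  # change scores have sd sqrt(2) * sd_resid; the interaction test is the
  # two-sample t on change scores, so power.t.test is an exact oracle
  analytic <- stats::power.t.test(n = n, delta = delta,
                                  sd = sqrt(2) * sd_resid)$power
  rejections <- vapply(1:400, function(s) {
    panel <- simulate_trial(n_per_arm = n,
                            means = matrix(c(0, 0, delta, 0), 2),
                            sd_subject = 1, sd_resid = sd_resid, seed = s)
    group_time_anova(panel)$p_interaction < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - analytic), 0.07)
})

test_that("subjects missing a time point are dropped and counted", {
  panel <- simulate_trial(n_per_arm = 6, seed = 44)
  panel <- panel[!(panel$subject == "ccat_01" & panel$time == "post"), ]
  res <- group_time_anova(panel)
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$n_subjects, 11L)
})

test_that("post hoc contrasts are paired and Bonferroni-doubled", {
  panel <- simulate_trial(n_per_arm = 10,
                          means = matrix(c(0, 0, 2, 0), 2), seed = 45)
  res <- group_time_anova(panel)
  ph <- res$posthoc
  expect_equal(nrow(ph), 2)
  expect_equal(ph$p_bonferroni, pmin(1, ph$p * 2))
  ccat_d <- with(merge(panel[panel$time == "pre" & panel$group == "ccat",
                             c("subject", "value")],
                       panel[panel$time == "post" & panel$group == "ccat",
                             c("subject", "value")],
                       by = "subject"), value.y - value.x)
  expect_equal(ph$mean_change[ph$group == "ccat"], mean(ccat_d))
})

test_that("simulate_trial is deterministic and honors the additive model", {
  a <- simulate_trial(n_per_arm = 20, seed = 77)
  b <- simulate_trial(n_per_arm = 20, seed = 77)
  expect_identical(a, b)
  big <- simulate_trial(n_per_arm = 4000, sd_subject = 0.5, sd_resid = 0.3,
                        means = matrix(c(1, 2, 3, 4), 2,
                                       dimnames = list(c("ccat", "control"),
                                                       c("pre", "post"))),
                        seed = 78)
  cells <- tapply(big$value, list(big$group, big$time), mean)
  expect_equal(cells["ccat", "pre"], 1, tolerance = 0.05)
  expect_equal(cells["ccat", "post"], 3, tolerance = 0.05)
  expect_equal(cells["control", "pre"], 2, tolerance = 0.05)
  expect_equal(cells["control", "post"], 4, tolerance = 0.05)
})
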