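#' Two-arm trial statistics
#'
#' Baseline tables in two-arm trials report per-group mean (SD) with an F
#' statistic, and categorical rows with a chi-square. Pre/post outcomes
#' are compared with a 2 (group, between) x 2 (time, within) mixed-model
#' ANOVA whose group-by-time interaction is the signature of a
#' differential treatment change; significant interactions are resolved by
#' Bonferroni-corrected pre/post contrasts within each group.
#'
#' @name trial-stats
NULL

#' @describeIn trial-stats Bundle a group's summary statistics.
#' @param n Group size (>= 2 for variance-based tests).
#' @param mean,sd Sample mean and standard deviation.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "ccat_group_summary")
}

#' @describeIn trial-stats One-way two-group F test computed from summary
#'   statistics alone: F = t^2 where t is the pooled-variance two-sample
#'   statistic, with df (1, n1 + n2 - 2). Degenerate inputs (both SDs
#'   zero) give F = 0 for equal means and an infinite-F flag otherwise.
#' @param g1,g2 [group_summary()] objects.
#' @return `summary_f_test()`: list with `F`, `df`, `p`.
#' @examples
#' summary_f_test(group_summary(20, 32.70, 5.27),
#'                group_summary(20, 35.05, 8.02))$F  # ~1.20
#' @export
summary_f_test <- function(g1, g2) {
  stopifnot(inherits(g1, "ccat_group_summary"),
            inherits(g2, "ccat_group_summary"))
  df2 <- g1$n + g2$n - 2L
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df2
  if (sp2 == 0) {
    f <- if (g1$mean == g2$mean) 0 else Inf
    return(list(F = f, df = c(1L, df2), p = if (is.infinite(f)) 0 else 1))
  }
  t_stat <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  f <- t_stat^2
  list(F = f, df = c(1L, df2), p = pf(f, 1, df2, lower.tail = FALSE))
}

#' @describeIn trial-stats Pearson chi-square on an r x c contingency
#'   table, without continuity correction.
#' @param counts Matrix of non-negative counts with positive marginals.
#' @return `chi_square_test()`: list with `chisq`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero marginal")
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' @describeIn trial-stats 2x2 mixed ANOVA on a long pre/post panel.
#'   `panel` needs columns `subject`, `group`, `time` ("pre"/"post") and
#'   `value`; subjects missing a time point are dropped (complete-case)
#'   with their count reported. Sums of squares partition into group,
#'   subject-within-group, time, group-by-time and residual strata; the
#'   group effect is tested against subject-within-group, time and the
#'   interaction against the residual, each with df (1, n - 2) for n
#'   complete subjects. Post hoc pre/post paired contrasts within each
#'   group are Bonferroni-corrected by the family size of 2.
#' @param panel Long-format data frame.
#' @return `group_time_anova()`: list with per-effect F/df/p, the sums of
#'   squares table, post hoc contrasts, and `n_excluded`.
#' @export
group_time_anova <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("subject", "group", "time", "value") %in% names(panel)))
  panel$time <- as.character(panel$time)
  stopifnot(all(panel$time %in% c("pre", "post")))
  grp_of <- tapply(as.character(panel$group), panel$subject,
                   function(g) unique(g))
  if (any(lengths(grp_of) > 1)) stop("subject with inconsistent group")
  counts <- table(panel$subject, panel$time)
  complete <- rownames(counts)[counts[, "pre"] == 1 & counts[, "post"] == 1]
  n_excluded <- length(unique(panel$subject)) - length(complete)
  panel <- panel[panel$subject %in% complete, , drop = FALSE]
  n <- length(complete)
  if (n < 3 || length(unique(panel$group)) != 2)
    stop("need two groups and at least 3 complete subjects")

  y <- panel$value
  m <- mean(y)
  subj_mean <- tapply(y, panel$subject, mean)
  grp_mean <- tapply(y, panel$group, mean)
  time_mean <- tapply(y, panel$time, mean)
  cell_mean <- tapply(y, list(panel$group, panel$time), mean)
  n_g <- table(vapply(grp_of[complete], identity, character(1)))

  ss_total <- sum((y - m)^2)
  ss_group <- 2 * sum(n_g * (grp_mean[names(n_g)] - m)^2)
  grp_of_subj <- vapply(grp_of[names(subj_mean)], identity, character(1))
  ss_subj <- 2 * sum((subj_mean - grp_mean[grp_of_subj])^2)
  ss_time <- n * sum((time_mean - m)^2)
  ss_inter <- 0
  for (g in rownames(cell_mean)) for (tt in colnames(cell_mean))
    ss_inter <- ss_inter + n_g[[g]] *
      (cell_mean[g, tt] - grp_mean[[g]] - time_mean[[tt]] + m)^2
  ss_resid <- ss_total - ss_group - ss_subj - ss_time - ss_inter

  df_subj <- n - 2L
  df_resid <- n - 2L
  ms <- function(ss, df) ss / df
  f_of <- function(ss, err_ss, err_df) {
    if (err_ss <= .Machine$double.eps * max(1, ss)) {
      if (ss <= .Machine$double.eps) return(list(F = 0, p = 1))
      return(list(F = Inf, p = 0))  # zero-noise panel: flagged infinite F
    }
    f <- ms(ss, 1) / ms(err_ss, err_df)
    list(F = f, p = pf(f, 1, err_df, lower.tail = FALSE))
  }
  group <- f_of(ss_group, ss_subj, df_subj)
  time <- f_of(ss_time, ss_resid, df_resid)
  inter <- f_of(ss_inter, ss_resid, df_resid)

  ss_table <- data.frame(
    term = c("group", "subject_within_group", "time", "group_time",
             "residual", "total"),
    ss = c(ss_group, ss_subj, ss_time, ss_inter, ss_resid, ss_total),
    df = c(1L, df_subj, 1L, 1L, df_resid, 2L * n - 1L)
  )

  posthoc <- do.call(rbind, lapply(sort(unique(panel$group)), function(g) {
    sub <- panel[panel$group == g, ]
    wide <- merge(sub[sub$time == "pre", c("subject", "value")],
                  sub[sub$time == "post", c("subject", "value")],
                  by = "subject", suffixes = c("_pre", "_post"))
    d <- wide$value_post - wide$value_pre
    if (sd(d) == 0) {
      t_stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- t.test(d)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(group = g, mean_change = mean(d), t = t_stat,
               df = nrow(wide) - 1L, p = p,
               p_bonferroni = min(1, p * 2), stringsAsFactors = FALSE)
  }))

  list(
    F_group = group$F, F_time = time$F, F_interaction = inter$F,
    df = c(1L, n - 2L),
    p_group = group$p, p_time = time$p, p_interaction = inter$p,
    ss = ss_table, posthoc = posthoc,
    n_subjects = n, n_excluded = n_excluded
  )
}

#' @describeIn trial-stats Simulate a two-arm pre/post outcome panel under
#'   the additive model value = mu(group, time) + subject intercept +
#'   residual, with subject intercepts N(0, sd_subject^2) and residuals
#'   N(0, sd_resid^2). The default sizes mirror a 20-per-arm trial.
#' @param n_per_arm Subjects per arm.
#' @param means 2x2 numeric matrix of cell means: rows `ccat`/`control`,
#'   columns `pre`/`post`.
#' @param sd_subject,sd_resid Between-subject and residual SDs.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param outcome Outcome name written into the panel.
#' @return `simulate_trial()`: long panel data frame.
#' @export
simulate_trial <- function(n_per_arm = 20L,
                           means = matrix(0, 2, 2,
                                          dimnames = list(c("ccat", "control"),
                                                          c("pre", "post"))),
                           sd_subject = 1, sd_resid = 1, seed = NULL,
                           outcome = "outcome") {
  stopifnot(n_per_arm >= 2, sd_resid > 0, sd_subject >= 0,
            identical(dim(means), c(2L, 2L)))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dimnames(means)))
    dimnames(means) <- list(c("ccat", "control"), c("pre", "post"))
  groups <- rownames(means)
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    intercept <- rnorm(n_per_arm, 0, sd_subject)
    do.call(rbind, lapply(c("pre", "post"), function(tt) {
      data.frame(
        subject = sprintf("%s_%02d", g, seq_len(n_per_arm)),
        group = g, time = tt, outcome = outcome,
        value = means[gi, tt] + intercept +
          rnorm(n_per_arm, 0, sd_resid),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
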