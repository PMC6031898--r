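#' Synthetic study replica
#'
#' [study_config()] validates an end-to-end configuration for a simulated
#' two-arm trial: per-arm sample size, the training session plan, per-task
#' config overrides, and agent parameter sets for each arm at each time
#' point. [run_study_replica()] then runs, for every simulated subject, a
#' pre-assessment battery, twenty training sessions (treatment arm only,
#' each of the four programs twice per session), and a post-assessment
#' battery, and emits per-subject score rows plus the group-by-time
#' analysis.
#'
#' The training "effect" is modeled purely as the configured shift in
#' agent parameters between the pre and post sets — the replica makes no
#' claim about real training efficacy, it exercises the pipeline. The
#' default shifts make the treated arm improve (lower discounting rate,
#' faster gambling-task learning, fewer risky pumps, smaller attention
#' bias) while the control arm stays at baseline, reproducing the
#' qualitative pattern a positive trial would show.
#'
#' @name study-replica
NULL

#' @describeIn study-replica Build a validated study configuration from a
#'   list or YAML file path. Recognized top-level fields: `n_per_arm`,
#'   `plan` (see [session_plan()]), `tasks` (named per-task override
#'   lists), `agents` (blocks `ccat_pre`, `ccat_post`, `control_pre`,
#'   `control_post`, each an [agent_params()] override list), and
#'   `write_training_logs`. Unknown fields are rejected.
#' @param x A named list or a YAML file path; `NULL` for all defaults.
#' @export
study_config <- function(x = NULL) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  x <- x %||% list()
  known <- c("n_per_arm", "plan", "tasks", "agents", "write_training_logs")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown study config field(s): ", paste(unknown, collapse = ", "))

  baseline <- list(ddt = list(k_true = 0.10), igt = list(alpha = 0.05),
                   bart = list(pump_threshold = 80L),
                   responder = list(category_effect_ms = 80))
  improved <- list(ddt = list(k_true = 0.03),
                   igt = list(alpha = 0.25, tau = 5),
                   bart = list(pump_threshold = 48L),
                   responder = list(category_effect_ms = 20))
  agent_defaults <- list(ccat_pre = baseline, ccat_post = improved,
                         control_pre = baseline, control_post = baseline)
  agents_in <- x$agents %||% list()
  unknown <- setdiff(names(agents_in), names(agent_defaults))
  if (length(unknown))
    stop("unknown agent block(s): ", paste(unknown, collapse = ", "))
  agents <- lapply(names(agent_defaults), function(b)
    do.call(agent_params, modifyList(agent_defaults[[b]],
                                     agents_in[[b]] %||% list())))
  names(agents) <- names(agent_defaults)

  plan_args <- x$plan %||% list()
  if (!is.null(plan_args$programs_per_session))
    plan_args$programs_per_session <- unlist(plan_args$programs_per_session)
  plan <- do.call(session_plan, plan_args)

  task_over <- x$tasks %||% list()
  unknown <- setdiff(names(task_over), CCAT_TASKS)
  if (length(unknown))
    stop("unknown task block(s): ", paste(unknown, collapse = ", "))
  tasks <- lapply(CCAT_TASKS, function(tk)
    do.call(task_config, c(list(task = tk), task_over[[tk]] %||% list())))
  names(tasks) <- CCAT_TASKS

  cfg <- list(
    n_per_arm = as.integer(x$n_per_arm %||% 20L),
    plan = plan, tasks = tasks, agents = agents,
    write_training_logs = isTRUE(x$write_training_logs %||% TRUE)
  )
  stopifnot(cfg$n_per_arm >= 1)
  class(cfg) <- "ccat_study_config"
  cfg
}

#' @describeIn study-replica Run the full replica. All output lands under
#'   `outdir`: per-session training logs (`logs/<subject>/`), a wide
#'   per-subject score table (`scores_wide.csv`), the long outcome panel
#'   (`panel.csv`), training accuracy summaries
#'   (`training_summary.csv`), and the per-outcome group-by-time ANOVA
#'   (`analysis.csv`). Existing training logs are reused instead of
#'   re-run, so an interrupted replica can be resumed; an unreadable log
#'   raises an integrity error.
#' @param cfg A [study_config()].
#' @param seed Integer master seed.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the analysis table, the outcome panel,
#'   and output paths.
#' @export
run_study_replica <- function(cfg, seed, outdir) {
  stopifnot(inherits(cfg, "ccat_study_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "logs"), showWarnings = FALSE)

  scores <- list(); training <- list()
  for (arm in c("ccat", "control")) {
    for (i in seq_len(cfg$n_per_arm)) {
      subject <- sprintf("%s_%02d", arm, i)
      pre <- score_battery(cfg$agents[[paste0(arm, "_pre")]], seed,
                           subject_id = paste0(subject, "_pre"),
                           configs = cfg$tasks)
      post <- score_battery(cfg$agents[[paste0(arm, "_post")]], seed,
                            subject_id = paste0(subject, "_post"),
                            configs = cfg$tasks)
      pre$subject <- subject; pre$group <- arm; pre$time <- "pre"
      post$subject <- subject; post$group <- arm; post$time <- "post"
      pre$subject_id <- NULL; post$subject_id <- NULL
      scores[[length(scores) + 1L]] <- pre
      scores[[length(scores) + 1L]] <- post
      if (arm == "ccat")
        training[[subject]] <-
          replica_training(cfg, seed, subject, outdir)
    }
  }
  scores <- do.call(rbind, scores)
  training <- if (length(training)) do.call(rbind, training) else NULL

  outcomes <- c("global_k", "ln_global_k", "igt_net", "bart_literal",
                "bart_adjusted", "stroop_bias_ms")
  panel <- do.call(rbind, lapply(outcomes, function(oc) {
    data.frame(subject = scores$subject, group = scores$group,
               time = scores$time, outcome = oc, value = scores[[oc]],
               stringsAsFactors = FALSE)
  }))
  analysis <- do.call(rbind, lapply(outcomes, function(oc) {
    sub <- panel[panel$outcome == oc & is.finite(panel$value), ]
    res <- group_time_anova(sub)
    data.frame(outcome = oc, F_group = res$F_group, p_group = res$p_group,
               F_time = res$F_time, p_time = res$p_time,
               F_interaction = res$F_interaction,
               p_interaction = res$p_interaction,
               n_subjects = res$n_subjects, stringsAsFactors = FALSE)
  }))

  paths <- list(scores = file.path(outdir, "scores_wide.csv"),
                panel = file.path(outdir, "panel.csv"),
                analysis = file.path(outdir, "analysis.csv"),
                training = file.path(outdir, "training_summary.csv"))
  write.csv(scores, paths$scores, row.names = FALSE)
  write.csv(panel, paths$panel, row.names = FALSE)
  write.csv(analysis, paths$analysis, row.names = FALSE)
  if (!is.null(training))
    write.csv(training, paths$training, row.names = FALSE)
  invisible(list(analysis = analysis, panel = panel, scores = scores,
                 training = training, paths = paths))
}

# Run (or resume) one subject's training sessions; one JSONL log per
# session, one summary row per program run.
replica_training <- function(cfg, seed, subject, outdir) {
  logdir <- file.path(outdir, "logs", subject)
  if (cfg$write_training_logs)
    dir.create(logdir, recursive = TRUE, showWarnings = FALSE)
  params <- cfg$agents$ccat_pre
  sched <- cfg$plan$schedule
  rows <- list()
  for (s in unique(sched$session)) {
    srows <- sched[sched$session == s, , drop = FALSE]
    path <- file.path(logdir, sprintf("session_%02d.jsonl", s))
    if (cfg$write_training_logs && file.exists(path)) {
      log <- tryCatch(read_trial_log(path), error = function(e)
        stop("corrupted training log ", path, ": ", conditionMessage(e)))
    } else {
      runs <- lapply(seq_len(nrow(srows)), function(j) {
        sid <- sprintf("%s_%s_r%d", subject, srows$session_id[j],
                       srows$repetition[j])
        run_session(cfg$tasks[[srows$program[j]]], params, seed,
                    session_id = sid)
      })
      log <- do.call(bind_trial_logs, runs)
      if (cfg$write_training_logs) write_trial_log(log, path)
    }
    for (j in seq_len(nrow(srows))) {
      sid <- sprintf("%s_%s_r%d", subject, srows$session_id[j],
                     srows$repetition[j])
      sub <- log[log$session_id == sid, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, session = s, program = srows$program[j],
        repetition = srows$repetition[j],
        accuracy = session_accuracy(sub), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
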