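#' Run one task session
#'
#' Executes a full session of any battery task against a simulated
#' respondent and returns the ordered trial log. All randomness (schedule
#' and agent behaviour) comes from one stream derived from `seed` and the
#' stream id (default `"<task>/<session_id>"`), so identical
#' (seed, config, agent) inputs reproduce the log bitwise.
#'
#' Training tasks log green-check/red-cross feedback and end after their
#' configured trial budget; timeouts are logged as incorrect with a null
#' response. Assessment tasks (delay discounting, gambling, balloon) log
#' preference trials with `scored = FALSE` — they carry no accuracy
#' notion.
#'
#' @param config A [task_config()] for any of the eight tasks.
#' @param params An [agent_params()] simulated respondent.
#' @param seed Integer master seed.
#' @param session_id Session label written into every event.
#' @param lexicon Lexicon for word-based tasks (see [read_lexicon()]).
#' @return A trial-log data frame (see [trial-log]).
#' @examples
#' log <- run_session(task_config("act"), agent_params(), seed = 1)
#' session_accuracy(log)
#' @export
run_session <- function(config, params, seed, session_id = "s01",
                        lexicon = default_lexicon()) {
  if (!inherits(config, "ccat_config"))
    stop("config must come from task_config()")
  stopifnot(inherits(params, "ccat_agent_params"))
  runner <- switch(config$task,
    abm = run_abm_session, act = run_act_session,
    nback = run_nback_session, matrix = run_matrix_session,
    ddt = run_ddt_session, igt = run_igt_session,
    bart = run_bart_session, stroop = run_stroop_session,
    stop("unknown task_id: ", config$task)
  )
  log <- with_stream_seed(seed, paste(config$task, session_id, sep = "/"),
                          runner(config, params, session_id, lexicon))
  validate_trial_log(log)
  log
}

# --- training tasks ---------------------------------------------------------

run_abm_session <- function(config, params, session_id, lexicon) {
  sched <- generate_abm_schedule(config)
  correct_tok <- vapply(sched$stimulus, abm_correct_response, character(1))
  is_meth <- vapply(sched$stimulus, function(s)
    s$distractor_picture_category == "meth" ||
      s$right_item_text_category == "meth_word", logical(1))
  draw <- responder_draw(params, nrow(sched), is_meth = is_meth)
  given <- two_afc_given(correct_tok, draw, c("consistent", "inconsistent"))
  new_trial_log("abm", session_id, sched$phase, sched$stimulus,
                correct_tok, given, draw$latency_ms)
}

run_act_session <- function(config, params, session_id, lexicon) {
  stims <- generate_act_schedule(config)
  correct_tok <- vapply(stims, act_correct_response, character(1))
  is_meth <- vapply(stims, function(s) "meth" %in% s$picture_categories,
                    logical(1))
  draw <- responder_draw(params, length(stims), is_meth = is_meth)
  given <- two_afc_given(correct_tok, draw, CCAT_COLORS)
  new_trial_log("act", session_id, "main", stims, correct_tok, given,
                draw$latency_ms)
}

# Fill the given-response column from a responder draw: correct token,
# a wrong token from the alphabet, or NA on timeout.
two_afc_given <- function(correct_tok, draw, alphabet) {
  given <- correct_tok
  flip <- !draw$correct & !draw$timeout
  given[flip] <- wrong_token(correct_tok[flip], alphabet)
  given[draw$timeout] <- NA_character_
  given
}

run_nback_session <- function(config, params, session_id, lexicon) {
  state <- nback_state(level = config$start_level,
                       block_size = config$block_size)
  logs <- vector("list", config$n_blocks)
  blocks <- data.frame(block = seq_len(config$n_blocks), level = NA_integer_,
                       accuracy = NA_real_)
  for (b in seq_len(config$n_blocks)) {
    block <- generate_nback_block(config, state$level)
    n <- nrow(block)
    correct_tok <- rep(NA_character_, n)
    correct_tok[!block$is_warmup] <-
      ifelse(block$is_target[!block$is_warmup], "yes", "no")
    draw <- responder_draw(params, n, level = state$level, is_meth = TRUE)
    given <- two_afc_given(correct_tok, draw, c("yes", "no"))
    given[block$is_warmup] <- NA_character_
    logs[[b]] <- new_trial_log("nback", session_id, "main", block$stimulus,
                               correct_tok, given, draw$latency_ms,
                               scored = !block$is_warmup)
    acc <- mean(logs[[b]]$correct[!block$is_warmup])
    blocks$level[b] <- state$level
    blocks$accuracy[b] <- acc
    state <- nback_update_level(state, acc)
  }
  out <- do.call(bind_trial_logs, logs)
  attr(out, "final_state") <- state
  attr(out, "blocks") <- blocks
  out
}

run_matrix_session <- function(config, params, session_id, lexicon) {
  state <- matrix_state(config = config)
  n <- config$n_trials
  stims <- vector("list", n)
  correct_tok <- character(n); given <- character(n)
  draw <- responder_draw(params, n)
  for (t in seq_len(n)) {
    trial <- generate_matrix_trial(state)
    stims[[t]] <- c(trial[c("grid_dims", "span", "exposure_s",
                            "response_window_s", "pattern_preview_s")],
                    list(target_cells = paste(trial$target_cells[, 1],
                                              trial$target_cells[, 2],
                                              sep = ".")))
    correct_tok[t] <- trial$correct_token
    given[t] <- if (draw$timeout[t]) NA_character_
      else if (draw$correct[t]) trial$correct_token
      else matrix_wrong_token(trial)
    state <- matrix_update_span(state, identical(given[t], correct_tok[t]))
  }
  out <- new_trial_log("matrix", session_id, "main", stims, correct_tok,
                       given, draw$latency_ms)
  attr(out, "final_state") <- state
  out
}

# A near-miss recall: one target cell replaced by an unselected cell.
matrix_wrong_token <- function(trial) {
  side <- trial$grid_dims[1]
  all_cells <- seq_len(side * side)
  tgt <- (trial$target_cells[, 1] - 1L) * side + trial$target_cells[, 2]
  swap_out <- sample(seq_along(tgt), 1)
  swap_in <- sample(setdiff(all_cells, tgt), 1)
  tgt[swap_out] <- swap_in
  cells <- cbind(row = (tgt - 1L) %/% side + 1L, col = (tgt - 1L) %% side + 1L)
  matrix_cells_token(cells)
}

# --- assessment tasks -------------------------------------------------------

run_ddt_session <- function(config, params, session_id, lexicon) {
  choice_fn <- ddt_agent(params)
  logs <- lapply(config$delays_days, function(D) {
    res <- ddt_titrate(choice_fn, config, D)
    tr <- res$trace
    n <- nrow(tr)
    stims <- lapply(seq_len(n), function(i) list(
      delay_days = D, immediate = tr$immediate_offer[i],
      delayed_amount = config$delayed_amount, step = tr$step[i],
      indifference_point = res$indifference_point
    ))
    lat <- responder_draw(params, n)$latency_ms
    new_trial_log("ddt", session_id, "main", stims,
                  rep(NA_character_, n), tr$choice, lat,
                  scored = FALSE, feedback_on = FALSE)
  })
  do.call(bind_trial_logs, logs)
}

run_igt_session <- function(config, params, session_id, lexicon) {
  sched <- igt_schedule(config$n_trials)
  run <- igt_run(sched, igt_agent(params))
  n <- nrow(run)
  stims <- lapply(seq_len(n), function(i) list(
    trial = i, win = run$win[i], loss = run$loss[i], net = run$net[i]))
  lat <- responder_draw(params, n)$latency_ms
  new_trial_log("igt", session_id, "main", stims, rep(NA_character_, n),
                run$deck, lat, scored = FALSE, feedback_on = FALSE)
}

run_bart_session <- function(config, params, session_id, lexicon) {
  sched <- generate_bart_schedule(config)
  run <- bart_run(sched, bart_agent(params))
  n <- nrow(run)
  stims <- lapply(seq_len(n), function(i) list(
    balloon = i, explosion_point = run$explosion_point[i],
    exploded = run$exploded[i],
    points_per_pump = config$points_per_pump))
  lat <- responder_draw(params, n)$latency_ms
  new_trial_log("bart", session_id, "main", stims, rep(NA_character_, n),
                as.character(run$pumps), lat, scored = FALSE,
                feedback_on = FALSE)
}

run_stroop_session <- function(config, params, session_id, lexicon) {
  sched <- generate_stroop_schedule(config, lexicon = lexicon)
  n <- nrow(sched)
  draw <- responder_draw(params, n, is_meth = sched$category == "meth_word")
  draw$timeout <- draw$timeout | draw$latency_ms > config$exposure_ms
  given <- two_afc_given(sched$ink, draw, CCAT_COLORS)
  stims <- lapply(seq_len(n), function(i) list(
    word = sched$word[i], category = sched$category[i], ink = sched$ink[i]))
  new_trial_log("stroop", session_id, "main", stims, sched$ink, given,
                draw$latency_ms, feedback_on = FALSE)
}

# --- session planning and battery scoring -----------------------------------

#' Session plan for the training protocol
#'
#' The default plan is the study protocol: 20 sessions, five per week over
#' four weeks, with each of the four training programs run twice per
#' session.
#'
#' @param n_sessions,sessions_per_week Positive integers.
#' @param programs_per_session Named integer vector: runs per program per
#'   session.
#' @return A list with the plan fields plus `schedule`, a data frame with
#'   one row per program run (session, week, program, repetition,
#'   session_id).
#' @export
session_plan <- function(n_sessions = 20L, sessions_per_week = 5L,
                         programs_per_session = c(abm = 2L, act = 2L,
                                                  nback = 2L, matrix = 2L)) {
  stopifnot(n_sessions >= 1, sessions_per_week >= 1,
            all(programs_per_session >= 0),
            all(names(programs_per_session) %in%
                  c("abm", "act", "nback", "matrix")))
  rows <- do.call(rbind, lapply(seq_len(n_sessions), function(s) {
    prog <- rep(names(programs_per_session), programs_per_session)
    reps <- unlist(lapply(programs_per_session, seq_len), use.names = FALSE)
    data.frame(session = s, week = (s - 1L) %/% sessions_per_week + 1L,
               program = prog, repetition = reps,
               session_id = sprintf("s%02d", s), stringsAsFactors = FALSE)
  }))
  list(n_sessions = as.integer(n_sessions),
       sessions_per_week = as.integer(sessions_per_week),
       programs_per_session = programs_per_session,
       schedule = rows)
}

#' Score the four-assessment battery for one respondent
#'
#' Runs delay discounting, gambling, balloon and Stroop sessions for one
#' simulated respondent and collapses them to the per-subject outcome row
#' used by the trial analyses: per-delay discount rates, the global
#' hyperbolic k (and its log), the gambling net score, both balloon
#' scores, and the Stroop bias with per-category error rates.
#'
#' @param params An [agent_params()] respondent.
#' @param seed Integer master seed.
#' @param subject_id Label for the output row.
#' @param configs Optional named list of task configs overriding the
#'   defaults for `ddt`, `igt`, `bart`, `stroop`.
#' @param keep_logs Attach the raw logs as an attribute?
#' @return One-row data frame of battery scores.
#' @export
score_battery <- function(params, seed, subject_id = "subj1",
                          configs = list(), keep_logs = FALSE) {
  cfg <- function(task) configs[[task]] %||% task_config(task)
  logs <- list(
    ddt = run_session(cfg("ddt"), params, seed, session_id = subject_id),
    igt = run_session(cfg("igt"), params, seed, session_id = subject_id),
    bart = run_session(cfg("bart"), params, seed, session_id = subject_id),
    stroop = run_session(cfg("stroop"), params, seed, session_id = subject_id)
  )
  row <- score_battery_logs(logs, cfg("ddt"))
  row <- cbind(data.frame(subject_id = subject_id, stringsAsFactors = FALSE),
               row)
  if (keep_logs) attr(row, "logs") <- logs
  row
}

# Collapse battery logs to one score row; shared by score_battery() and
# the CLI re-scoring path.
score_battery_logs <- function(logs, ddt_cfg = task_config("ddt")) {
  A <- ddt_cfg$delayed_amount
  vps <- ddt_indifference_points(logs$ddt)
  ks <- mapply(hyperbolic_k, vps$indifference_point, A, vps$delay_days)
  fit <- fit_global_k(vps, A)
  deck <- logs$igt$given_response
  balloons <- bart_log_to_balloons(logs$bart)
  bs <- bart_score(balloons)
  sb <- stroop_bias(logs$stroop)
  out <- data.frame(
    global_k = fit$k, ln_global_k = fit$ln_k,
    igt_net = igt_net_score(deck),
    bart_literal = bs$literal, bart_adjusted = bs$adjusted,
    bart_points = bs$points,
    stroop_bias_ms = sb$bias_ms,
    stroop_error_meth = sb$error_rate_meth,
    stroop_error_neutral = sb$error_rate_neutral,
    stringsAsFactors = FALSE
  )
  kcols <- as.data.frame(as.list(setNames(
    ks, paste0("k_d", vps$delay_days))))
  cbind(kcols, out)
}

#' Extract per-delay indifference points from a delay-discounting log
#'
#' @param log A DDT trial log from [run_session()].
#' @return Data frame with `delay_days` and `indifference_point`.
#' @export
ddt_indifference_points <- function(log) {
  d <- vapply(log$stimulus, function(s) s$delay_days, numeric(1))
  v <- vapply(log$stimulus, function(s) s$indifference_point, numeric(1))
  out <- unique(data.frame(delay_days = d, indifference_point = v))
  out[order(out$delay_days), , drop = FALSE]
}

#' Recover per-balloon outcomes from a balloon-task log
#'
#' @param log A BART trial log from [run_session()].
#' @return Data frame with `pumps` and `exploded`, one row per balloon.
#' @export
bart_log_to_balloons <- function(log) {
  data.frame(
    pumps = as.numeric(log$given_response),
    exploded = vapply(log$stimulus, function(s) isTRUE(s$exploded),
                      logical(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
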