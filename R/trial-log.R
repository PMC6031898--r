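#' Trial logs
#'
#' A trial log is a data frame with one row per stimulus-response event.
#' Columns: `task_id` (ABM, ACT, NBACK, MATRIX, DDT, IGT, BART, STROOP),
#' `session_id`, `trial_index` (1-based, strictly increasing within a log),
#' `phase` ("practice" or "main"), `stimulus` (list-column of task-specific
#' payloads), `correct_response`, `given_response` (`NA` on timeout),
#' `latency_ms`, `correct`, `feedback` ("green_check", "red_cross", "none")
#' and `scored` (`FALSE` for warm-up / preference trials that carry no
#' accuracy notion). Training tasks give green-check feedback on correct and
#' red-cross on incorrect responses; assessments give none.
#'
#' @name trial-log
NULL

TRIAL_LOG_SCHEMA_VERSION <- 1L

# Assemble a trial-log data frame from parallel vectors; fills feedback and
# correctness from the response columns so the log invariants hold by
# construction.
new_trial_log <- function(task_id, session_id, phase, stimulus,
                          correct_response, given_response, latency_ms,
                          scored = TRUE, feedback_on = TRUE,
                          trial_index = NULL) {
  n <- length(stimulus)
  scored <- rep_len(scored, n)
  correct <- ifelse(scored,
                    !is.na(given_response) & given_response == correct_response,
                    NA)
  feedback <- rep("none", n)
  if (feedback_on) {
    feedback[scored & correct %in% TRUE]  <- "green_check"
    feedback[scored & correct %in% FALSE] <- "red_cross"
  }
  if (is.null(trial_index)) trial_index <- seq_len(n)
  df <- data.frame(
    task_id = toupper(task_id), session_id = session_id,
    trial_index = as.integer(trial_index),
    phase = rep_len(phase, n),
    correct_response = as.character(correct_response),
    given_response = as.character(given_response),
    latency_ms = as.numeric(latency_ms),
    correct = as.logical(correct),
    feedback = feedback,
    scored = scored,
    stringsAsFactors = FALSE
  )
  df$stimulus <- stimulus
  class(df) <- c("ccat_trial_log", "data.frame")
  df
}

# Concatenate trial logs, renumbering trial_index to stay strictly increasing.
bind_trial_logs <- function(...) {
  logs <- list(...)
  logs <- logs[!vapply(logs, is.null, logical(1))]
  out <- do.call(rbind, lapply(logs, function(x) {
    class(x) <- "data.frame"
    x
  }))
  out$trial_index <- seq_len(nrow(out))
  class(out) <- c("ccat_trial_log", "data.frame")
  out
}

#' Session accuracy
#'
#' Proportion of correct responses among scored main-phase trials — the
#' number shown to a trainee at the end of a session.
#'
#' @param log A trial-log data frame.
#' @return Proportion in `[0, 1]`.
#' @export
session_accuracy <- function(log) {
  stopifnot(is.data.frame(log), nrow(log) > 0)
  main <- log[log$phase == "main" & log$scored, , drop = FALSE]
  if (nrow(main) == 0)
    stop("accuracy is undefined: no scored main-phase trials in log")
  mean(main$correct)
}

#' Validate trial-log invariants
#'
#' Checks the structural invariants of a log: strictly increasing trial
#' index, correctness consistent with the response columns, feedback
#' consistent with correctness, non-negative latencies.
#'
#' @param log A trial-log data frame.
#' @return Invisibly `TRUE`; errors with a message on violation.
#' @export
validate_trial_log <- function(log) {
  stopifnot(is.data.frame(log))
  need <- c("task_id", "session_id", "trial_index", "phase", "stimulus",
            "correct_response", "given_response", "latency_ms", "correct",
            "feedback", "scored")
  missing <- setdiff(need, names(log))
  if (length(missing)) stop("log is missing columns: ",
                            paste(missing, collapse = ", "))
  if (nrow(log) && any(diff(log$trial_index) <= 0))
    stop("trial_index must be strictly increasing")
  if (any(log$latency_ms < 0, na.rm = TRUE)) stop("negative latency_ms")
  sc <- log$scored
  expect_correct <- !is.na(log$given_response[sc]) &
    log$given_response[sc] == log$correct_response[sc]
  if (any(log$correct[sc] != expect_correct))
    stop("correct flag inconsistent with responses")
  fb <- log$feedback[sc]
  bad <- (fb == "green_check" & !log$correct[sc]) |
    (fb == "red_cross" & log$correct[sc])
  if (any(bad)) stop("feedback inconsistent with correctness")
  invisible(TRUE)
}

# --- serialization -----------------------------------------------------------

#' Read and write trial logs as JSON Lines
#'
#' One JSON object per line, schema-versioned via a `v` field. `NA`
#' responses serialize as JSON null. `read_trial_log()` restores the
#' list-column stimulus payloads.
#'
#' @param log A trial-log data frame.
#' @param path File path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns the log.
#' @export
write_trial_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    rec <- list(
      v = TRIAL_LOG_SCHEMA_VERSION,
      task_id = log$task_id[i], session_id = log$session_id[i],
      trial_index = log$trial_index[i], phase = log$phase[i],
      stimulus = log$stimulus[[i]],
      correct_response = scalar_or_null(log$correct_response[i]),
      given_response = scalar_or_null(log$given_response[i]),
      latency_ms = log$latency_ms[i],
      correct = scalar_or_null(log$correct[i]),
      feedback = log$feedback[i], scored = log$scored[i]
    )
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

scalar_or_null <- function(x) if (is.na(x)) NULL else x

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  get1 <- function(field, as) vapply(recs, function(r) {
    v <- r[[field]]
    if (is.null(v)) as(NA) else as(v)
  }, as(NA))
  df <- data.frame(
    task_id = get1("task_id", as.character),
    session_id = get1("session_id", as.character),
    trial_index = get1("trial_index", as.integer),
    phase = get1("phase", as.character),
    correct_response = get1("correct_response", as.character),
    given_response = get1("given_response", as.character),
    latency_ms = get1("latency_ms", as.numeric),
    correct = get1("correct", as.logical),
    feedback = get1("feedback", as.character),
    scored = get1("scored", as.logical),
    stringsAsFactors = FALSE
  )
  df$stimulus <- lapply(recs, `[[`, "stimulus")
  class(df) <- c("ccat_trial_log", "data.frame")
  df
}

#' Export a trial log to CSV with flattened stimulus fields
#'
#' Stimulus payload fields become `stimulus_<name>` columns; vector-valued
#' fields are collapsed with `";"`.
#'
#' @inheritParams write_trial_log
#' @export
trial_log_to_csv <- function(log, path) {
  flat <- log
  class(flat) <- "data.frame"
  stim <- flat$stimulus
  flat$stimulus <- NULL
  fields <- unique(unlist(lapply(stim, names)))
  for (f in fields) {
    flat[[paste0("stimulus_", f)]] <- vapply(stim, function(s) {
      v <- s[[f]]
      if (is.null(v)) NA_character_ else paste(v, collapse = ";")
    }, character(1))
  }
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
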