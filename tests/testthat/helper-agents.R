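# Shared fixtures: deterministic agents and small task configs.

perfect_agent <- function() agent_params(responder = list(p_correct = 1))

# DDT chooser with a fixed scripted choice sequence.
scripted_ddt_agent <- function(choices) {
  i <- 0L
  function(immediate, A, D) {
    i <<- i + 1L
    choices[[i]]
  }
}

# Threshold chooser indifferent at a known value.
threshold_ddt_agent <- function(v_true) {
  function(immediate, A, D) if (v_true >= immediate) "delayed" else "immediate"
}

small_nback_cfg <- function(...) task_config("nback", ...)

# Random trial log of constant shape for brute-force score checks.
random_stroop_log <- function(n_per_cat = 20) {
  n <- 2 * n_per_cat
  cat <- sample(rep(c("meth_word", "neutral_word"), n_per_cat))
  correct <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.9, 0.1))
  ink <- sample(c("red", "green", "yellow", "blue"), n, replace = TRUE)
  given <- ifelse(correct, ink, "purple_is_wrong")
  log <- data.frame(
    task_id = "STROOP", session_id = "t", trial_index = seq_len(n),
    phase = "main", correct_response = ink, given_response = given,
    latency_ms = runif(n, 400, 900), correct = correct, feedback = "none",
    scored = TRUE, stringsAsFactors = FALSE
  )
  log$stimulus <- lapply(seq_len(n), function(i)
    list(word = "w", category = cat[i], ink = ink[i]))
  log
}
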