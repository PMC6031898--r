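#' Drug-word Stroop task
#'
#' Eight drug-related and eight neutral words are each shown eight times,
#' color-balanced (two presentations per word in each of red, green,
#' yellow, blue), for 128 trials. The respondent names the ink color,
#' ignoring word meaning; each word stays on screen at most 3000 ms.
#' Attention bias is the mean color-naming latency on correct drug-word
#' trials minus the mean on correct neutral-word trials.
#'
#' @name stroop
NULL

#' @describeIn stroop Generate the pseudorandomized schedule: every word
#'   appears exactly `presentations_per_word` times, colors balanced
#'   within word, order shuffled under the seed and then repaired so no
#'   more than `max_category_run` consecutive trials share a word
#'   category.
#' @param cfg A `"stroop"` [task_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param lexicon Lexicon data frame (see [read_lexicon()]); needs at
#'   least `n_words_per_category` meth_word and neutral_word tokens.
#' @return `generate_stroop_schedule()`: data frame (word, category, ink).
#' @export
generate_stroop_schedule <- function(cfg, seed = NULL,
                                     lexicon = default_lexicon()) {
  stopifnot(inherits(cfg, "ccat_config"), cfg$task == "stroop")
  if (!is.null(seed)) set.seed(seed)
  nw <- cfg$n_words_per_category
  words <- c(lexicon_tokens(lexicon, "meth_word")[seq_len(nw)],
             lexicon_tokens(lexicon, "neutral_word")[seq_len(nw)])
  if (anyNA(words)) stop("lexicon too small for n_words_per_category")
  per_color <- cfg$presentations_per_word / length(CCAT_COLORS)
  sched <- expand.grid(word = words, ink = CCAT_COLORS,
                       rep = seq_len(per_color), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  sched$rep <- NULL
  sched$category <- ifelse(sched$word %in% words[seq_len(nw)],
                           "meth_word", "neutral_word")
  sched <- sched[sample.int(nrow(sched)), c("word", "category", "ink")]
  rownames(sched) <- NULL
  repair_category_runs(sched, cfg$max_category_run)
}

# Deterministic left-to-right repair: whenever a trial would extend a
# same-category run past `max_run`, swap it with the next trial of the
# other category.
repair_category_runs <- function(sched, max_run) {
  n <- nrow(sched)
  run <- 1L
  for (i in 2:n) {
    if (sched$category[i] == sched$category[i - 1]) run <- run + 1L
    else run <- 1L
    if (run > max_run) {
      j <- i
      while (j <= n && sched$category[j] == sched$category[i]) j <- j + 1L
      if (j > n) break  # tail is all one category; nothing to swap in
      sched[c(i, j), ] <- sched[c(j, i), ]
      run <- 1L
    }
  }
  rownames(sched) <- NULL
  sched
}

#' @describeIn stroop Attention-bias score from a trial log: mean latency
#'   on correct drug-word trials minus mean latency on correct
#'   neutral-word trials, plus per-category error rates. A category with
#'   no correct trials yields an undefined-bias flag.
#' @param log A trial-log data frame whose stimulus payloads carry a
#'   `category` field (`meth_word` / `neutral_word`).
#' @return `stroop_bias()`: list with `bias_ms`, per-category mean
#'   latencies and error rates, and `undefined`.
#' @export
stroop_bias <- function(log) {
  stopifnot(is.data.frame(log), nrow(log) > 0)
  cat <- vapply(log$stimulus, function(s) s$category, character(1))
  scored <- log$scored
  if (!any(scored & cat == "meth_word") || !any(scored & cat == "neutral_word"))
    stop("log must contain scored trials of both word categories")
  rate <- function(cc) mean(!log$correct[scored & cat == cc])
  mean_lat <- function(cc) {
    sel <- scored & cat == cc & log$correct
    if (!any(sel)) return(NA_real_)
    mean(log$latency_ms[sel])
  }
  m <- mean_lat("meth_word"); nl <- mean_lat("neutral_word")
  undefined <- is.na(m) || is.na(nl)
  list(bias_ms = if (undefined) NA_real_ else m - nl,
       mean_meth_ms = m, mean_neutral_ms = nl,
       error_rate_meth = rate("meth_word"),
       error_rate_neutral = rate("neutral_word"),
       undefined = undefined)
}
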