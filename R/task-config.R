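#' Task configurations
#'
#' `task_config()` builds a validated configuration for one task, starting
#' from protocol defaults and overriding named fields. Unknown fields are
#' rejected. Defaults reproduce the study protocol constants: 240 attention
#' control trials, 20 attention-bias practice trials, 150 gambling-task
#' picks, 100 balloons, a 1000-yuan delayed reward titrated from 500, and a
#' 16-word x 8-presentation Stroop list.
#'
#' Time-budgeted training tasks (the attention-bias task runs about 8
#' minutes, the N-back and matrix tasks 10) are configured by deterministic
#' trial-count surrogates (120, 80 scored, and 40 trials respectively) so
#' runs are exactly reproducible.
#'
#' @param task One of `"abm"`, `"act"`, `"nback"`, `"matrix"`, `"ddt"`,
#'   `"igt"`, `"bart"`, `"stroop"`.
#' @param ... Named overrides of the task's default fields.
#' @return A list with class `ccat_config`; `$task` names the task.
#' @examples
#' task_config("act")$n_main
#' task_config("ddt", n_adjustments = 8)
#' @export
task_config <- function(task = CCAT_TASKS, ...) {
  task <- match.arg(task)
  defaults <- ccat_task_defaults()[[task]]
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config field(s) for task '", task, "': ",
         paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, overrides)
  cfg$task <- task
  class(cfg) <- "ccat_config"
  validate_task_config(cfg)
  cfg
}

ccat_task_defaults <- function() {
  list(
    abm = list(n_practice = 20L, n_main = 120L, p_consistent = 0.5,
               meth_distractor_rate = 1.0, p_meth_word = 0.5),
    act = list(n_main = 240L, p_two_pictures = 0.5),
    nback = list(block_size = 20L, n_blocks = 4L, target_rate = 0.3,
                 start_level = 1L),
    matrix = list(n_trials = 40L, start_span = 3L, span_min = 2L,
                  streak_len = 3L, grid_base = 5L, grid_big = 6L,
                  big_grid_span = 8L, exposure_s = 3, response_window_s = 3,
                  pattern_preview_s = 1),
    ddt = list(delayed_amount = 1000, initial_immediate = 500,
               delays_days = c(2, 7, 30, 90, 180, 360), n_adjustments = 6L),
    igt = list(n_trials = 150L),
    bart = list(n_balloons = 100L, max_pumps = 128L, points_per_pump = 10),
    stroop = list(n_words_per_category = 8L, presentations_per_word = 8L,
                  exposure_ms = 3000, max_category_run = 3L)
  )
}

validate_task_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid ", cfg$task, " config: ", msg)
  switch(cfg$task,
    abm = {
      chk(cfg$n_practice >= 0 && cfg$n_main > 0, "trial counts")
      chk(cfg$p_consistent >= 0 && cfg$p_consistent <= 1, "p_consistent")
      chk(cfg$meth_distractor_rate >= 0 && cfg$meth_distractor_rate <= 1,
          "meth_distractor_rate")
    },
    act = chk(cfg$n_main > 0 && cfg$p_two_pictures >= 0 &&
                cfg$p_two_pictures <= 1, "fields"),
    nback = {
      chk(cfg$block_size > 0 && cfg$n_blocks > 0, "block layout")
      chk(cfg$target_rate > 0 && cfg$target_rate < 1, "target_rate")
      chk(cfg$start_level %in% 1:3, "start_level must be in 1..3")
      n_targets <- round(cfg$target_rate * cfg$block_size)
      chk(n_targets >= 1 && n_targets <= cfg$block_size - 1,
          "infeasible target balance for block size")
    },
    matrix = {
      chk(cfg$span_min >= 1 && cfg$start_span >= cfg$span_min, "span bounds")
      chk(cfg$grid_base^2 > cfg$big_grid_span, "grid too small for spans")
      chk(cfg$streak_len >= 1, "streak_len")
    },
    ddt = {
      chk(cfg$initial_immediate < cfg$delayed_amount,
          "initial immediate must be below the delayed amount")
      chk(all(diff(cfg$delays_days) > 0), "delays must be strictly increasing")
      chk(cfg$n_adjustments >= 1, "n_adjustments")
    },
    igt = chk(cfg$n_trials > 0, "n_trials"),
    bart = chk(cfg$n_balloons > 0 && cfg$max_pumps >= 1, "fields"),
    stroop = {
      chk(cfg$n_words_per_category > 0, "word count")
      chk(cfg$presentations_per_word %% length(CCAT_COLORS) == 0,
          "presentations_per_word must be a multiple of 4 to balance colors")
    }
  )
  invisible(cfg)
}

#' Stimulus lexicon
#'
#' Drug-related and neutral word/picture content is represented by opaque
#' category-tagged identifiers, loaded from a CSV with columns `token_id`
#' and `category` (one of meth_word, meth_picture, neutral_word,
#' neutral_picture). `default_lexicon()` returns the placeholder lexicon
#' shipped with the package.
#'
#' @param path CSV path.
#' @return A data frame with columns `token_id`, `category`.
#' @export
read_lexicon <- function(path) {
  lex <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("token_id", "category")
  if (!all(need %in% names(lex)))
    stop("lexicon must have columns token_id, category")
  allowed <- c("meth_word", "meth_picture", "neutral_word", "neutral_picture")
  bad <- setdiff(unique(lex$category), allowed)
  if (length(bad)) stop("unknown lexicon categories: ",
                        paste(bad, collapse = ", "))
  lex
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "placeholder_lexicon.csv",
                           package = "ccat", mustWork = TRUE))
}

lexicon_tokens <- function(lexicon, category) {
  tok <- lexicon$token_id[lexicon$category == category]
  if (!length(tok)) stop("lexicon has no tokens of category ", category)
  tok
}
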