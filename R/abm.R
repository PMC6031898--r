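#' Attention bias modification (ABM) task
#'
#' A word in a left box names a color (its own ink is irrelevant); an item
#' on the right — a drug-related or neutral word — is printed in some ink,
#' with a drug-related picture as distractor during real training. The
#' trainee judges whether the meaning of the left word is consistent with
#' the ink color of the right item, ignoring the distractor. Color tokens
#' are limited to red, yellow, blue and green. Practice trials (the first
#' 20 of a session) contain no drug-related content.
#'
#' @name abm
NULL

#' @describeIn abm Correct response for one stimulus: `"consistent"` iff
#'   the left word's meaning equals the right item's ink color. The left
#'   word's own ink and the distractor are ignored by the rule.
#' @param s An ABM stimulus: a list with fields `left_word_meaning`,
#'   `left_word_ink`, `right_item_text_category`, `right_item_ink`,
#'   `distractor_picture_category`.
#' @return `abm_correct_response()`: `"consistent"` or `"inconsistent"`.
#' @examples
#' s <- list(left_word_meaning = "red", left_word_ink = "green",
#'           right_item_text_category = "meth_word", right_item_ink = "red",
#'           distractor_picture_category = "meth")
#' abm_correct_response(s)  # "consistent"
#' @export
abm_correct_response <- function(s) {
  stopifnot(s$left_word_meaning %in% CCAT_COLORS,
            s$right_item_ink %in% CCAT_COLORS)
  if (identical(s$left_word_meaning, s$right_item_ink)) "consistent"
  else "inconsistent"
}

#' @describeIn abm Generate a session schedule: `n_practice` practice
#'   stimuli (neutral words, no distractor) followed by `n_main` training
#'   stimuli with an exactly balanced consistent:inconsistent mix and
#'   drug-cue distractors at `meth_distractor_rate`.
#' @param config An `"abm"` [task_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return `generate_abm_schedule()`: a data frame with columns `phase` and
#'   `stimulus` (list-column).
#' @export
generate_abm_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ccat_config"), config$task == "abm")
  if (!is.null(seed)) set.seed(seed)
  practice <- abm_stimuli(config$n_practice, practice = TRUE, config)
  main <- abm_stimuli(config$n_main, practice = FALSE, config)
  df <- data.frame(
    phase = rep(c("practice", "main"), c(config$n_practice, config$n_main)),
    stringsAsFactors = FALSE
  )
  df$stimulus <- c(practice, main)
  df
}

abm_stimuli <- function(n, practice, config) {
  if (n == 0) return(list())
  # exact balance of the consistent/inconsistent mix
  n_cons <- round(config$p_consistent * n)
  consistent <- sample(rep(c(TRUE, FALSE), c(n_cons, n - n_cons)))
  meaning <- sample(CCAT_COLORS, n, replace = TRUE)
  ink <- character(n)
  ink[consistent] <- meaning[consistent]
  ink[!consistent] <- vapply(meaning[!consistent], function(m)
    sample(setdiff(CCAT_COLORS, m), 1), character(1))
  own_ink <- sample(CCAT_COLORS, n, replace = TRUE)
  if (practice) {
    right_cat <- rep("neutral_word", n)
    distractor <- rep("none", n)
  } else {
    right_cat <- ifelse(runif(n) < config$p_meth_word,
                        "meth_word", "neutral_word")
    distractor <- ifelse(runif(n) < config$meth_distractor_rate,
                         "meth", "none")
  }
  lapply(seq_len(n), function(i) list(
    left_word_meaning = meaning[i],
    left_word_ink = own_ink[i],
    right_item_text_category = right_cat[i],
    right_item_ink = ink[i],
    distractor_picture_category = distractor[i]
  ))
}
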