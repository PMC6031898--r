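#' Adaptive N-back working-memory training
#'
#' Colored geometric figures (triangle, circle, rectangle in the four task
#' colors) appear on the right of the screen with a drug-related picture on
#' the left as distractor. The trainee answers yes/no: is the current
#' figure — shape AND color — the same as the one shown N trials earlier?
#' Training starts at 1-back and the level is upgraded after reaching 90%
#' block accuracy twice in succession, up to 3-back; the level never
#' decreases.
#'
#' @name nback
NULL

NBACK_SHAPES <- c("triangle", "circle", "rectangle")

#' @describeIn nback Construct the adaptive state. `level` is the current
#'   N (1-3), `success_streak` counts consecutive blocks at or above the
#'   90% criterion.
#' @param level Integer in 1..3.
#' @param success_streak Non-negative integer.
#' @param block_size Scored trials per block.
#' @export
nback_state <- function(level = 1L, success_streak = 0L, block_size = 20L) {
  stopifnot(level %in% 1:3, success_streak >= 0, block_size > 0)
  structure(list(level = as.integer(level),
                 success_streak = as.integer(success_streak),
                 block_size = as.integer(block_size)),
            class = "ccat_nback_state")
}

#' @describeIn nback Correct response for the last stimulus in `history`:
#'   `"yes"` iff its shape and color both match the stimulus `level`
#'   positions earlier; `NA` for warm-up trials (fewer than `level`
#'   preceding stimuli), which are logged unscored.
#' @param history List of stimuli (each with `figure_shape`,
#'   `figure_color`) up to and including the current trial.
#' @return `nback_correct_response()`: `"yes"`, `"no"`, or `NA`.
#' @export
nback_correct_response <- function(history, level) {
  i <- length(history)
  if (i - level < 1) return(NA_character_)
  cur <- history[[i]]; ref <- history[[i - level]]
  if (identical(cur$figure_shape, ref$figure_shape) &&
      identical(cur$figure_color, ref$figure_color)) "yes" else "no"
}

#' @describeIn nback Staircase update after a completed block: accuracy at
#'   or above 0.90 extends the success streak, anything lower resets it; a
#'   streak of two upgrades the level (capped at 3) and resets the streak.
#' @param state A [nback_state()].
#' @param block_accuracy Proportion correct over the block's scored trials.
#' @export
nback_update_level <- function(state, block_accuracy) {
  stopifnot(inherits(state, "ccat_nback_state"),
            block_accuracy >= 0, block_accuracy <= 1)
  if (block_accuracy >= 0.90) {
    state$success_streak <- state$success_streak + 1L
    if (state$success_streak >= 2L) {
      state$level <- min(state$level + 1L, 3L)
      state$success_streak <- 0L
    }
  } else {
    state$success_streak <- 0L
  }
  state
}

#' @describeIn nback Generate one block at a given level: `level` warm-up
#'   stimuli followed by `block_size` scored stimuli with an exact target
#'   count of `round(target_rate * block_size)`. Targets repeat the figure
#'   shown `level` trials earlier; lures differ in shape, color or both.
#'   Target figures sit on the right; the left position holds a
#'   drug-related distractor picture.
#' @param config An `"nback"` [task_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return `generate_nback_block()`: a data frame with list-column
#'   `stimulus` plus `is_warmup` and `is_target` flags.
#' @export
generate_nback_block <- function(config, level, seed = NULL) {
  stopifnot(inherits(config, "ccat_config"), config$task == "nback",
            level %in% 1:3)
  if (!is.null(seed)) set.seed(seed)
  bs <- config$block_size
  n_targets <- round(config$target_rate * bs)
  is_target <- sample(rep(c(TRUE, FALSE), c(n_targets, bs - n_targets)))
  n <- level + bs
  shape <- character(n); color <- character(n)
  for (i in seq_len(level)) {
    shape[i] <- sample(NBACK_SHAPES, 1)
    color[i] <- sample(CCAT_COLORS, 1)
  }
  figures <- as.vector(outer(NBACK_SHAPES, CCAT_COLORS, paste, sep = "|"))
  for (j in seq_len(bs)) {
    i <- level + j
    ref <- paste(shape[i - level], color[i - level], sep = "|")
    fig <- if (is_target[j]) ref else sample(setdiff(figures, ref), 1)
    parts <- strsplit(fig, "|", fixed = TRUE)[[1]]
    shape[i] <- parts[1]; color[i] <- parts[2]
  }
  df <- data.frame(
    is_warmup = c(rep(TRUE, level), rep(FALSE, bs)),
    is_target = c(rep(NA, level), is_target),
    stringsAsFactors = FALSE
  )
  df$stimulus <- lapply(seq_len(n), function(i) list(
    figure_shape = shape[i], figure_color = color[i],
    level = level, distractor_category = "meth",
    target_position = "right", distractor_position = "left"
  ))
  df
}
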