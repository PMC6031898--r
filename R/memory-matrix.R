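#' Memory matrix spatial working-memory training
#'
#' A grid of squares appears; a subset turns blue for 3 seconds, reverts,
#' and must be recalled within a 3-second response window (no response in
#' time counts as incorrect). Training starts at a span of three squares.
#' Three successes in succession raise the span by one; three failures in
#' succession lower it by one, floored at `span_min`. The grid is 5x5 and
#' grows to 6x6 once the span exceeds 8 so patterns stay sparse.
#'
#' @name memory-matrix
NULL

#' @describeIn memory-matrix Construct the adaptive state.
#' @param span Current number of target squares.
#' @param success_streak,failure_streak Consecutive-outcome counters; at
#'   most one is ever positive.
#' @param config A `"matrix"` [task_config()] supplying bounds and grid
#'   sizes.
#' @export
matrix_state <- function(span = NULL, success_streak = 0L,
                         failure_streak = 0L, config = task_config("matrix")) {
  if (is.null(span)) span <- config$start_span
  stopifnot(span >= config$span_min, success_streak >= 0, failure_streak >= 0,
            !(success_streak > 0 && failure_streak > 0))
  structure(list(span = as.integer(span),
                 success_streak = as.integer(success_streak),
                 failure_streak = as.integer(failure_streak),
                 config = config),
            class = "ccat_matrix_state")
}

#' @describeIn memory-matrix Staircase update after one scored trial. A
#'   success extends the success streak and clears the failure streak (and
#'   symmetrically for failures); a streak of `streak_len` (three)
#'   increments or decrements the span by one and resets both counters.
#'   The span never drops below `span_min`.
#' @param state A [matrix_state()].
#' @param trial_success Logical: all target cells selected, no others,
#'   within the response window.
#' @export
matrix_update_span <- function(state, trial_success) {
  stopifnot(inherits(state, "ccat_matrix_state"), is.logical(trial_success))
  k <- state$config$streak_len
  if (trial_success) {
    state$success_streak <- state$success_streak + 1L
    state$failure_streak <- 0L
    if (state$success_streak >= k) {
      state$span <- state$span + 1L
      state$success_streak <- 0L
    }
  } else {
    state$failure_streak <- state$failure_streak + 1L
    state$success_streak <- 0L
    if (state$failure_streak >= k) {
      state$span <- max(state$span - 1L, state$config$span_min)
      state$failure_streak <- 0L
    }
  }
  state
}

#' @describeIn memory-matrix Generate one trial at the state's current
#'   span: grid dimensions plus a random set of `span` distinct target
#'   cells.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return `generate_matrix_trial()`: list with `grid_dims`,
#'   `target_cells` (two-column matrix of row/col), timing fields, and the
#'   canonical response token for a fully correct recall.
#' @export
generate_matrix_trial <- function(state, seed = NULL) {
  stopifnot(inherits(state, "ccat_matrix_state"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- state$config
  side <- if (state$span > cfg$big_grid_span) cfg$grid_big else cfg$grid_base
  if (state$span > side * side)
    stop("span ", state$span, " exceeds the ", side, "x", side, " grid")
  cells <- sample.int(side * side, state$span)
  target <- cbind(row = (cells - 1L) %/% side + 1L,
                  col = (cells - 1L) %% side + 1L)
  list(grid_dims = c(side, side), span = state$span, target_cells = target,
       exposure_s = cfg$exposure_s, response_window_s = cfg$response_window_s,
       pattern_preview_s = cfg$pattern_preview_s,
       correct_token = matrix_cells_token(target))
}

# Canonical order-free token for a set of grid cells, e.g. "1.2;3.4".
matrix_cells_token <- function(cells) {
  paste(sort(paste(cells[, 1], cells[, 2], sep = ".")), collapse = ";")
}
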