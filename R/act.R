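#' Attention control training (ACT) task
#'
#' Each trial shows either one bordered picture or two (one drug-related,
#' one neutral). With one picture the trainee reports its border color;
#' with two, the drug-related picture must be ignored and the border color
#' of the neutral picture reported. A session contains 240 trials.
#'
#' @name act
NULL

#' @describeIn act Correct response: the border color of the single
#'   picture, or of the neutral picture when two are shown. Errors if a
#'   two-picture stimulus does not pair one drug-related with one neutral
#'   picture.
#' @param s An ACT stimulus: list with `n_pictures` (1 or 2),
#'   `picture_categories` and `border_colors` (parallel vectors).
#' @return `act_correct_response()`: a color token.
#' @examples
#' act_correct_response(list(n_pictures = 1, picture_categories = "meth",
#'                           border_colors = "red"))  # "red"
#' @export
act_correct_response <- function(s) {
  stopifnot(s$n_pictures %in% c(1L, 2L),
            length(s$picture_categories) == s$n_pictures,
            all(s$border_colors %in% CCAT_COLORS))
  if (s$n_pictures == 1L) return(s$border_colors[1])
  if (!setequal(s$picture_categories, c("meth", "neutral")))
    stop("invalid stimulus: two pictures must be one meth and one neutral")
  s$border_colors[s$picture_categories == "neutral"]
}

#' @describeIn act Generate the 240-trial schedule with an exact
#'   one-picture : two-picture balance at `p_two_pictures`.
#' @param config An `"act"` [task_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return `generate_act_schedule()`: list of ACT stimuli, length `n_main`.
#' @export
generate_act_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ccat_config"), config$task == "act")
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_main
  n_two <- round(config$p_two_pictures * n)
  two <- sample(rep(c(TRUE, FALSE), c(n_two, n - n_two)))
  lapply(seq_len(n), function(i) {
    if (two[i]) {
      cats <- sample(c("meth", "neutral"))
      list(n_pictures = 2L, picture_categories = cats,
           border_colors = sample(CCAT_COLORS, 2, replace = TRUE))
    } else {
      list(n_pictures = 1L,
           picture_categories = sample(c("meth", "neutral"), 1),
           border_colors = sample(CCAT_COLORS, 1))
    }
  })
}
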