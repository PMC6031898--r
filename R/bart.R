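#' Balloon Analogue Risk Task (BART)
#'
#' 100 balloons; each pump inflates the balloon and banks 10 points unless
#' the balloon bursts first. Each balloon's burst point is fixed before
#' the run, drawn uniformly from 1..`max_pumps` (128), so the hazard of a
#' further pump rises as the balloon grows. The headline score is total
#' pumps divided by the number of unexploded balloons; the variant
#' restricting the numerator to unexploded balloons (the usual adjusted
#' score) is reported alongside.
#'
#' @name bart
NULL

#' @describeIn bart Draw the pre-run explosion points.
#' @param cfg A `"bart"` [task_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return `generate_bart_schedule()`: integer vector of explosion points,
#'   length `n_balloons`.
#' @export
generate_bart_schedule <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "ccat_config"), cfg$task == "bart")
  if (!is.null(seed)) set.seed(seed)
  sample.int(cfg$max_pumps, cfg$n_balloons, replace = TRUE)
}

#' @describeIn bart Score a run from per-balloon outcomes.
#' @param balloons Data frame with columns `pumps` (pumps taken) and
#'   `exploded` (logical).
#' @param points_per_pump Points banked per successful pump (default 10).
#' @return `bart_score()`: list with `literal` (all pumps per unexploded
#'   balloon), `adjusted` (unexploded pumps per unexploded balloon),
#'   `points` (banked points), `n_unexploded`, and `undefined` (`TRUE`,
#'   with `NA` scores, when every balloon exploded).
#' @examples
#' b <- data.frame(pumps = c(10, 4, 6), exploded = c(TRUE, FALSE, FALSE))
#' bart_score(b)$literal   # 10
#' bart_score(b)$adjusted  # 5
#' @export
bart_score <- function(balloons, points_per_pump = 10) {
  stopifnot(is.data.frame(balloons),
            all(c("pumps", "exploded") %in% names(balloons)),
            all(balloons$pumps >= 0))
  ok <- !balloons$exploded
  n_ok <- sum(ok)
  points <- points_per_pump * sum(balloons$pumps[ok])
  if (n_ok == 0)
    return(list(literal = NA_real_, adjusted = NA_real_, points = points,
                n_unexploded = 0L, undefined = TRUE))
  list(literal = sum(balloons$pumps) / n_ok,
       adjusted = sum(balloons$pumps[ok]) / n_ok,
       points = points, n_unexploded = n_ok, undefined = FALSE)
}

#' @describeIn bart Play a schedule with a pump-intention function.
#' @param schedule Explosion points from [generate_bart_schedule()].
#' @param pump_fn Function `(balloon_index)` returning the intended number
#'   of pumps; the balloon bursts if its explosion point is reached first.
#' @return `bart_run()`: data frame (balloon, explosion_point, pumps,
#'   exploded).
#' @export
bart_run <- function(schedule, pump_fn) {
  n <- length(schedule)
  intent <- vapply(seq_len(n), pump_fn, numeric(1))
  stopifnot(all(intent >= 0))
  exploded <- schedule <= intent
  pumps <- ifelse(exploded, schedule, intent)
  data.frame(balloon = seq_len(n), explosion_point = schedule,
             pumps = pumps, exploded = exploded)
}
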