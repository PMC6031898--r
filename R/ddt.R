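#' Delay discounting task (DDT)
#'
#' A fixed delayed reward (1000 yuan by default) is pitted against an
#' immediate amount that starts at half the delayed reward and moves by a
#' decreasing-adjustment rule: after each choice the immediate offer drops
#' (if it was chosen) or rises (if the delayed reward was chosen) by the
#' current step, and the step halves from an initial half of the starting
#' offer. After `n_adjustments` choices the adjusted offer is recorded as
#' the indifference point V(D) for that delay. Delays default to 2 days, 1
#' week, 1 month, 3 months, 6 months and 1 year (2, 7, 30, 90, 180, 360
#' days), titrated in ascending order.
#'
#' Discounting is summarized by the hyperbolic decay model
#' V = A / (1 + k D): [hyperbolic_k()] inverts one indifference point and
#' [fit_global_k()] least-squares fits a single k across delays.
#'
#' @name ddt
NULL

#' @describeIn ddt Run the titration for one delay.
#' @param choice_fn Function `(immediate, delayed_amount, delay_days)`
#'   returning `"immediate"` or `"delayed"`.
#' @param cfg A `"ddt"` [task_config()].
#' @param delay_days The delay D in days.
#' @return `ddt_titrate()`: list with `indifference_point` and a `trace`
#'   data frame (trial, immediate offer, choice, step applied).
#' @examples
#' cfg <- task_config("ddt")
#' always_now <- function(immediate, A, D) "immediate"
#' ddt_titrate(always_now, cfg, 30)$indifference_point  # 7.8125
#' @export
ddt_titrate <- function(choice_fn, cfg, delay_days) {
  stopifnot(inherits(cfg, "ccat_config"), cfg$task == "ddt",
            is.function(choice_fn))
  A <- cfg$delayed_amount
  immediate <- cfg$initial_immediate
  step <- cfg$initial_immediate / 2  # halving doubles are exact
  n <- cfg$n_adjustments
  trace <- data.frame(trial = seq_len(n), immediate_offer = NA_real_,
                      choice = NA_character_, step = NA_real_,
                      stringsAsFactors = FALSE)
  for (t in seq_len(n)) {
    choice <- choice_fn(immediate, A, delay_days)
    if (!choice %in% c("immediate", "delayed"))
      stop("choice_fn must return 'immediate' or 'delayed'")
    trace$immediate_offer[t] <- immediate
    trace$choice[t] <- choice
    trace$step[t] <- step
    immediate <- if (choice == "immediate") immediate - step
                 else immediate + step
    step <- step / 2
  }
  list(indifference_point = immediate, trace = trace)
}

#' @describeIn ddt Per-delay discount rate: the unique k with
#'   V = A / (1 + k D), i.e. k = (A - V) / (V D). `V = A` gives exactly 0;
#'   non-positive V is flagged as `NA` with a warning rather than clamped.
#' @param V Indifference point.
#' @param A Delayed amount.
#' @param D Delay in days.
#' @return `hyperbolic_k()`: k per day.
#' @export
hyperbolic_k <- function(V, A, D) {
  stopifnot(A > 0, D > 0)
  if (is.na(V)) return(NA_real_)
  if (V <= 0) {
    warning("non-positive indifference point; k undefined")
    return(NA_real_)
  }
  if (V >= A) return(0)
  (A - V) / (V * D)
}

#' @describeIn ddt Single discount rate across delays: least-squares fit
#'   of V = A / (1 + k D) with k >= 0. One point reduces to
#'   [hyperbolic_k()]; all points at A give k = 0.
#' @param points Data frame with columns `delay_days` and
#'   `indifference_point`, or a named numeric vector (names = delays).
#' @return `fit_global_k()`: list with `k` and `ln_k` (`-Inf` when k = 0).
#' @export
fit_global_k <- function(points, A) {
  if (is.numeric(points) && !is.null(names(points)))
    points <- data.frame(delay_days = as.numeric(names(points)),
                         indifference_point = as.numeric(points))
  stopifnot(is.data.frame(points), nrow(points) >= 1,
            all(c("delay_days", "indifference_point") %in% names(points)))
  D <- points$delay_days; V <- points$indifference_point
  stopifnot(all(D > 0), all(V > 0))
  if (nrow(points) == 1) {
    k <- hyperbolic_k(V, A, D)
    return(list(k = k, ln_k = if (k > 0) log(k) else -Inf))
  }
  k_pt <- mapply(hyperbolic_k, V, A, D)
  if (all(k_pt == 0)) return(list(k = 0, ln_k = -Inf))
  upper <- max(k_pt) * 4 + 1e-3
  sse <- function(k) sum((V - A / (1 + k * D))^2)
  opt <- optimize(sse, interval = c(0, upper), tol = 1e-10)
  k <- opt$minimum
  # optimize never returns the exact boundary; snap to 0 when flat there
  if (k < 1e-9 && sse(0) <= opt$objective) k <- 0
  list(k = k, ln_k = if (k > 0) log(k) else -Inf)
}
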