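#' Simulated respondents
#'
#' Parameterized agents generate behaviour with known ground truth for
#' every task, serving as the package's fixture generator. One
#' [agent_params()] object carries four blocks:
#'
#' * `ddt`: `k_true` (per-day hyperbolic discount rate) and
#'   `choice_noise` (logistic temperature on the subjective value
#'   difference; 0 = deterministic threshold chooser, ties go to the
#'   delayed reward).
#' * `igt`: delta-rule learner with learning rate `alpha` in `[0, 1]` and
#'   softmax temperature `tau > 0` over per-deck value estimates.
#' * `bart`: fixed pump threshold `pump_threshold` — pump until the
#'   balloon bursts or the threshold is reached, then cash.
#' * `responder`: generic accuracy/latency responder for the training and
#'   Stroop tasks: correct with probability `p_correct` (a scalar or a
#'   per-level vector for the N-back), lognormal latency
#'   (`latency_meanlog`, `latency_sdlog`, floored at 150 ms) with an
#'   additive `category_effect_ms` on drug-related stimuli, and timeout
#'   probability `p_timeout`.
#'
#' @name agents
NULL

LATENCY_FLOOR_MS <- 150

#' @describeIn agents Build and validate an agent parameter set; `...`
#'   overrides individual fields inside the four blocks.
#' @param ddt,igt,bart,responder Named lists overriding block defaults.
#' @export
agent_params <- function(ddt = list(), igt = list(), bart = list(),
                         responder = list()) {
  defaults <- list(
    ddt = list(k_true = 0.05, choice_noise = 0),
    igt = list(alpha = 0.2, tau = 10),
    bart = list(pump_threshold = 64L),
    responder = list(p_correct = 0.95, latency_meanlog = 6.2,
                     latency_sdlog = 0.25, category_effect_ms = 0,
                     p_timeout = 0)
  )
  blocks <- list(ddt = ddt, igt = igt, bart = bart, responder = responder)
  out <- lapply(names(defaults), function(b) {
    unknown <- setdiff(names(blocks[[b]]), names(defaults[[b]]))
    if (length(unknown))
      stop("unknown agent field(s) in block '", b, "': ",
           paste(unknown, collapse = ", "))
    modifyList(defaults[[b]], blocks[[b]])
  })
  names(out) <- names(defaults)
  class(out) <- "ccat_agent_params"
  validate_agent_params(out)
  out
}

#' @describeIn agents Validate a parameter set (ranges and types);
#'   invisibly returns it.
#' @param params An agent parameter set.
#' @export
validate_agent_params <- function(params) {
  chk <- function(ok, msg) if (!ok) stop("invalid agent params: ", msg)
  chk(params$ddt$k_true >= 0, "k_true must be >= 0")
  chk(params$ddt$choice_noise >= 0, "choice_noise must be >= 0")
  chk(params$igt$alpha >= 0 && params$igt$alpha <= 1, "alpha in [0,1]")
  chk(params$igt$tau > 0, "tau must be > 0")
  chk(params$bart$pump_threshold >= 0, "pump_threshold must be >= 0")
  p <- params$responder$p_correct
  chk(all(p >= 0 & p <= 1), "p_correct in [0,1]")
  chk(params$responder$latency_sdlog > 0, "latency_sdlog must be > 0")
  chk(params$responder$p_timeout >= 0 && params$responder$p_timeout <= 1,
      "p_timeout in [0,1]")
  invisible(params)
}

#' @describeIn agents Load agent parameters from a YAML file whose top
#'   level holds any of the four blocks.
#' @param path YAML file path.
#' @export
read_agent_params <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("ddt", "igt", "bart", "responder"))
  if (length(unknown))
    stop("unknown agent block(s): ", paste(unknown, collapse = ", "))
  do.call(agent_params, raw)
}

#' @describeIn agents Delay-discounting chooser. Noiseless mode picks the
#'   delayed reward iff its hyperbolic subjective value A/(1 + kD) exceeds
#'   the immediate offer (ties to delayed); with `choice_noise` > 0 the
#'   choice is logistic in the value difference.
#' @return `ddt_agent()`: function `(immediate, A, D)` returning
#'   `"immediate"` or `"delayed"`.
#' @export
ddt_agent <- function(params) {
  k <- params$ddt$k_true
  noise <- params$ddt$choice_noise
  function(immediate, A, D) {
    sv <- A / (1 + k * D)
    if (noise <= 0) {
      if (sv >= immediate) "delayed" else "immediate"
    } else {
      p_delayed <- 1 / (1 + exp(-(sv - immediate) / noise))
      if (runif(1) < p_delayed) "delayed" else "immediate"
    }
  }
}

#' @describeIn agents Reinforcement-sensitive deck chooser: per-deck value
#'   estimates start at 0, the chosen deck's estimate moves toward the net
#'   payoff by `alpha`, and decks are sampled by softmax with temperature
#'   `tau`.
#' @return `igt_agent()`: list with `choose()`, `update(deck, net)` and
#'   `values()`.
#' @param init Initial per-deck value estimates (default all zero).
#' @export
igt_agent <- function(params, init = rep(0, 4)) {
  alpha <- params$igt$alpha
  tau <- params$igt$tau
  V <- setNames(rep_len(init, 4), IGT_DECKS)
  list(
    choose = function() {
      z <- (V - max(V)) / tau
      p <- exp(z) / sum(exp(z))
      sample(IGT_DECKS, 1, prob = p)
    },
    update = function(deck, net) {
      V[deck] <<- V[deck] + alpha * (net - V[deck])
    },
    values = function() V
  )
}

#' @describeIn agents Threshold pumper for the balloon task.
#' @return `bart_agent()`: function `(balloon_index)` returning the
#'   intended pump count (the fixed threshold).
#' @export
bart_agent <- function(params) {
  t_pumps <- params$bart$pump_threshold
  function(balloon_index) t_pumps
}

# Level-indexed accuracy lookup: scalar p applies to every level.
responder_p_correct <- function(params, level = 1L) {
  p <- params$responder$p_correct
  if (length(p) == 1L) return(p)
  if (level > length(p)) p[length(p)] else p[level]
}

#' @describeIn agents Vectorized accuracy/latency responder used by the
#'   training and Stroop tasks: draws `n` correct/timeout flags and
#'   latencies (lognormal, floored at 150 ms, plus `category_effect_ms`
#'   where `is_meth` is `TRUE`).
#' @param n Number of trials to draw.
#' @param level Difficulty level indexing `p_correct`.
#' @param is_meth Logical vector: does the trial carry drug-related
#'   content?
#' @return `responder_draw()`: data frame (correct, timeout, latency_ms).
#' @export
responder_draw <- function(params, n, level = 1L, is_meth = FALSE) {
  r <- params$responder
  p <- responder_p_correct(params, level)
  timeout <- runif(n) < r$p_timeout
  correct <- !timeout & runif(n) < p
  lat <- pmax(rlnorm(n, r$latency_meanlog, r$latency_sdlog),
              LATENCY_FLOOR_MS)
  lat <- lat + rep_len(is_meth, n) * r$category_effect_ms
  data.frame(correct = correct, timeout = timeout, latency_ms = lat)
}

# Pick a wrong response token given the correct one and the alphabet.
wrong_token <- function(correct, alphabet) {
  vapply(correct, function(cr) sample(setdiff(alphabet, cr), 1), character(1))
}
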