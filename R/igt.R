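#' Iowa Gambling Task (IGT)
#'
#' Four decks, 150 picks. Decks A and B pay a 100-point win on every pick
#' but carry larger scheduled penalties so each 10-pick block nets -250
#' (disadvantageous); decks C and D pay 50 per pick with smaller penalties,
#' netting +250 per block (advantageous). Deck A spreads five losses over
#' a block, deck B concentrates one large loss; C and D mirror that
#' structure at small magnitudes. The outcome is the net score
#' (advantageous minus disadvantageous picks); a positive score reflects a
#' tendency to good decisions.
#'
#' @name igt
NULL

IGT_DECKS <- c("A", "B", "C", "D")

# Within-block loss schedules (pick position -> loss) giving per-10-block
# nets of -250 (A, B) and +250 (C, D).
igt_block_losses <- function() {
  list(
    A = c("3" = 150, "5" = 300, "7" = 200, "9" = 250, "10" = 350),
    B = c("9" = 1250),
    C = c("3" = 50, "5" = 50, "7" = 50, "9" = 50, "10" = 50),
    D = c("10" = 250)
  )
}

#' @describeIn igt Build the deterministic canonical payoff schedule. Each
#'   deck holds `n_trials` cards (enough for any choice sequence); card j
#'   of a deck wins 100 (A, B) or 50 (C, D) and loses per the deck's
#'   within-block schedule at position `((j - 1) %% 10) + 1`.
#' @param n_trials Total picks the schedule must support (default 150).
#' @return `igt_schedule()`: list with `n_trials` and `decks`, a list of
#'   per-deck data frames (`win`, `loss`, `net`).
#' @export
igt_schedule <- function(n_trials = 150L) {
  stopifnot(n_trials > 0)
  wins <- c(A = 100, B = 100, C = 50, D = 50)
  losses <- igt_block_losses()
  decks <- lapply(IGT_DECKS, function(d) {
    pos <- ((seq_len(n_trials) - 1L) %% 10L) + 1L
    loss <- unname(losses[[d]][as.character(pos)])
    loss[is.na(loss)] <- 0
    data.frame(win = wins[[d]], loss = loss, net = wins[[d]] - loss)
  })
  names(decks) <- IGT_DECKS
  structure(list(n_trials = as.integer(n_trials), decks = decks),
            class = "ccat_igt_schedule")
}

#' @describeIn igt Net score of a choice sequence:
#'   (#C + #D) - (#A + #B).
#' @param choices Character vector of deck labels in `{A, B, C, D}`.
#' @return `igt_net_score()`: integer.
#' @examples
#' igt_net_score(c("C", "D", "A"))  # 1
#' @export
igt_net_score <- function(choices) {
  stopifnot(all(choices %in% IGT_DECKS))
  sum(choices %in% c("C", "D")) - sum(choices %in% c("A", "B"))
}

#' @describeIn igt Run a chooser against a schedule. `agent` is a list
#'   with `choose()` returning a deck label and `update(deck, net)` called
#'   after each payoff (see [igt_agent()]).
#' @param schedule An [igt_schedule()].
#' @param agent A stateful chooser.
#' @return `igt_run()`: data frame (trial, deck, win, loss, net).
#' @export
igt_run <- function(schedule, agent) {
  stopifnot(inherits(schedule, "ccat_igt_schedule"))
  n <- schedule$n_trials
  drawn <- setNames(rep(0L, 4), IGT_DECKS)
  deck <- character(n); win <- numeric(n); loss <- numeric(n)
  for (t in seq_len(n)) {
    d <- agent$choose()
    if (!d %in% IGT_DECKS) stop("agent chose unknown deck: ", d)
    drawn[d] <- drawn[d] + 1L
    card <- schedule$decks[[d]][drawn[d], ]
    deck[t] <- d; win[t] <- card$win; loss[t] <- card$loss
    agent$update(d, card$net)
  }
  data.frame(trial = seq_len(n), deck = deck, win = win, loss = loss,
             net = win - loss, stringsAsFactors = FALSE)
}
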