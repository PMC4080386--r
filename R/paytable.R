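#' Bet levels of the slot-machine task (EUR)
#'
#' The task offers a low bet of 20 cents and a high bet of 60 cents per trial.
#'
#' @return Named numeric vector with elements `low` and `high`.
#' @export
bet_levels <- function() c(low = 0.20, high = 0.60)

#' Default pay table
#'
#' Nine symbol combinations with payouts log-spaced from 0.05 to 20 EUR at the
#' low bet and from 0.15 to 60 EUR at the high bet (the 60-EUR jackpot),
#' rounded to cents. Combinations whose payout is below the bet at both bet
#' levels are the "fake win" outcomes: the player sees a win banner but
#' receives less than was staked.
#'
#' @return A data frame with columns `combo` (symbol-combination id),
#'   `payout_low` and `payout_high` (EUR).
#' @export
default_pay_table <- function() {
  low <- round(0.05 * (20 / 0.05)^((0:8) / 8), 2)
  high <- round(0.15 * (60 / 0.15)^((0:8) / 8), 2)
  pay_table(data.frame(combo = paste0("C", 1:9), payout_low = low,
                       payout_high = high))
}

#' Construct and validate a pay table
#'
#' @param entries Data frame with columns `combo`, `payout_low`, `payout_high`.
#' @return The validated data frame with class `"pay_table"`.
#' @export
pay_table <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("combo", "payout_low", "payout_high") %in% names(entries)))
  if (any(entries$payout_low <= 0) || any(entries$payout_high <= 0))
    stop("pay table payouts must be strictly positive")
  if (any(entries$payout_high < entries$payout_low))
    stop("high-bet payout must be >= low-bet payout for every entry")
  class(entries) <- c("pay_table", "data.frame")
  entries
}

# entries winnable as fake wins / true wins given the two bet levels
fake_entries <- function(pay, bets = bet_levels()) {
  which(pay$payout_low < bets["low"] & pay$payout_high < bets["high"])
}

true_entries <- function(pay, bets = bet_levels()) {
  which(pay$payout_low > bets["low"] & pay$payout_high > bets["high"])
}
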