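#' Specification of the pre-determined game trace
#'
#' The task is a fixed sequence of trials whose outcomes are pre-programmed:
#' every subject experiences the same wins, fake wins, near-misses and
#' double-up offers. The defaults reproduce the study conditions: 200 trials,
#' 40\% wins, half of the wins fake, half of the wins followed by a double-up
#' offer, 18\% of all trials near-misses, and a blocked streak structure with
#' stable and volatile phases. The trace is tuned so the return-to-player
#' (RTP) is at least `rtp_floor` and rounds to `rtp_target` at 5\% granularity
#' under both constant-bet policies.
#'
#' @param n_trials Number of trials.
#' @param frac_win Proportion of trials that are wins (true or fake).
#' @param frac_fake_of_wins Proportion of wins that are fake wins.
#' @param frac_du_of_wins Proportion of wins followed by a double-up offer.
#' @param frac_near_miss Proportion of all trials that are near-misses.
#' @param block_structure Data frame with columns `length` and `win_prob`
#'   defining the streak phases; lengths must sum to `n_trials`.
#' @param seed Integer seed making the trace deterministic.
#' @param rtp_target Modal return-to-player at 5\% granularity.
#' @param rtp_floor Minimum admissible return-to-player.
#' @return A list of class `"trace_spec"`.
#' @export
trace_spec <- function(n_trials = 200, frac_win = 0.40, frac_fake_of_wins = 0.50,
                       frac_du_of_wins = 0.50, frac_near_miss = 0.18,
                       block_structure = default_blocks(), seed = 1L,
                       rtp_target = 0.90, rtp_floor = 0.70) {
  spec <- list(n_trials = as.integer(n_trials), frac_win = frac_win,
               frac_fake_of_wins = frac_fake_of_wins,
               frac_du_of_wins = frac_du_of_wins,
               frac_near_miss = frac_near_miss,
               block_structure = block_structure, seed = as.integer(seed),
               rtp_target = rtp_target, rtp_floor = rtp_floor)
  class(spec) <- "trace_spec"
  validate_trace_spec(spec)
  spec
}

#' Default streak structure
#'
#' Five 40-trial blocks with win probabilities (0.40, 0.55, 0.25, 0.55, 0.25):
#' an even opening phase followed by alternating winning and losing streaks
#' (a more volatile later phase). The probabilities average to the global 40\%
#' win rate exactly.
#'
#' @return Data frame with columns `length` and `win_prob`.
#' @export
default_blocks <- function() {
  data.frame(length = rep(40L, 5), win_prob = c(0.40, 0.55, 0.25, 0.55, 0.25))
}

validate_trace_spec <- function(spec) {
  n <- spec$n_trials
  is_int <- function(x) abs(x - round(x)) < 1e-9
  counts <- c(win = spec$frac_win * n,
              fake = spec$frac_fake_of_wins * spec$frac_win * n,
              du = spec$frac_du_of_wins * spec$frac_win * n,
              near_miss = spec$frac_near_miss * n)
  if (!all(vapply(counts, is_int, logical(1))))
    stop("trace_spec infeasible: class proportions do not give integer counts")
  if (sum(spec$block_structure$length) != n)
    stop("trace_spec infeasible: block lengths do not sum to n_trials")
  if (!(spec$rtp_floor > 0 && spec$rtp_floor <= spec$rtp_target))
    stop("trace_spec infeasible: need 0 < rtp_floor <= rtp_target")
  if (spec$frac_win + spec$frac_near_miss > 1 + 1e-9)
    stop("trace_spec infeasible: win and near-miss fractions exceed 1")
  invisible(spec)
}

#' Generate the pre-determined game trace
#'
#' Places the exact number of win trials block-by-block according to the
#' streak structure (per-block win rates are held within 0.05 of the block
#' win probability), labels wins as true or fake, marks double-up offers on
#' win trials only, labels near-misses among the losses, and assigns payouts
#' from the pay table so that the return-to-player under both constant-bet
#' no-double-up policies lies in `[rtp_floor, 1]` and rounds to `rtp_target`
#' at 5\% granularity. Fake wins pay less than the bet at both bet levels;
#' true wins pay more. Fully deterministic given `spec$seed`.
#'
#' @param spec A [trace_spec()].
#' @param pay A [pay_table()]; defaults to [default_pay_table()].
#' @return Data frame of class `"game_trace"` with columns `trial`,
#'   `outcome_class`, `payout_low`, `payout_high`, `du_offered`.
#' @export
generate_trace <- function(spec = trace_spec(), pay = default_pay_table()) {
  validate_trace_spec(spec)
  n <- spec$n_trials
  n_win <- round(spec$frac_win * n)
  n_fake <- round(spec$frac_fake_of_wins * n_win)
  n_du <- round(spec$frac_du_of_wins * n_win)
  n_nm <- round(spec$frac_near_miss * n)

  with_seed(spec$seed, {
    # degenerate win-free spec: the block win probabilities are moot
    win <- if (n_win == 0) rep(FALSE, n) else
      place_wins(spec$block_structure, n_win)
    win_idx <- which(win)
    loss_idx <- which(!win)
    fake_idx <- if (n_fake > 0) sort(sample(win_idx, n_fake)) else integer(0)
    du_idx <- if (n_du > 0) sort(sample(win_idx, n_du)) else integer(0)
    nm_idx <- if (n_nm > 0) sort(sample(loss_idx, n_nm)) else integer(0)

    cls <- rep("true_loss", n)
    cls[win_idx] <- "true_win"
    cls[fake_idx] <- "fake_win"
    cls[nm_idx] <- "near_miss"

    pl <- numeric(n)
    ph <- numeric(n)
    if (n_win > 0) {
      pays <- assign_payouts(cls, pay, spec)
      pl <- pays$low
      ph <- pays$high
    }

    trace <- data.frame(trial = seq_len(n), outcome_class = cls,
                        payout_low = round(pl, 2), payout_high = round(ph, 2),
                        du_offered = as.integer(seq_len(n) %in% du_idx))
    class(trace) <- c("game_trace", "data.frame")
    trace
  })
}

# exact per-block win counts, randomly positioned inside each block
place_wins <- function(blocks, n_win) {
  counts <- round(blocks$length * blocks$win_prob)
  # reconcile rounding drift against the global target, largest blocks first
  drift <- n_win - sum(counts)
  ord <- order(blocks$length, decreasing = TRUE)
  i <- 1
  while (drift != 0) {
    j <- ord[(i - 1) %% length(ord) + 1]
    counts[j] <- counts[j] + sign(drift)
    drift <- drift - sign(drift)
    i <- i + 1
  }
  if (any(counts < 0) || any(counts > blocks$length))
    stop("trace_spec infeasible: block win counts outside block lengths")
  if (any(abs(counts / blocks$length - blocks$win_prob) > 0.05 + 1e-9))
    stop("generation error: per-block win rate deviates more than 0.05 from block win probability")
  win <- logical(0)
  for (b in seq_len(nrow(blocks))) {
    w <- rep(FALSE, blocks$length[b])
    if (counts[b] > 0) w[sample(blocks$length[b], counts[b])] <- TRUE
    win <- c(win, w)
  }
  win
}

# draw payouts, then nudge true-win payouts until both constant-bet RTPs sit
# in the admissible window around the target mode
assign_payouts <- function(cls, pay, spec) {
  bets <- bet_levels()
  fe <- fake_entries(pay, bets)
  te <- true_entries(pay, bets)
  if (length(fe) == 0 && any(cls == "fake_win"))
    stop("generation error: pay table has no entry payable below both bets (fake wins unsatisfiable)")
  if (length(te) == 0 && any(cls == "true_win"))
    stop("generation error: pay table has no entry payable above both bets (true wins unsatisfiable)")

  n <- length(cls)
  entry <- rep(NA_integer_, n)
  ifk <- which(cls == "fake_win")
  itw <- which(cls == "true_win")
  if (length(ifk)) entry[ifk] <- sample(fe, length(ifk), replace = TRUE)
  # favour small wins (weights ~ 1/payout), as on a real machine
  if (length(itw))
    entry[itw] <- sample(te, length(itw), replace = TRUE,
                         prob = 1 / pay$payout_low[te])

  # stay well inside the 5%-granularity bin of the target so the rounded
  # mode is never decided by a floating-point boundary case
  in_window <- function(rtp) {
    rtp >= spec$rtp_floor && rtp <= 1 && abs(rtp - spec$rtp_target) <= 0.02
  }
  rtps <- function(entry) {
    low <- ifelse(is.na(entry), 0, pay$payout_low[entry])
    high <- ifelse(is.na(entry), 0, pay$payout_high[entry])
    c(sum(low) / (n * bets["low"]), sum(high) / (n * bets["high"]))
  }

  ok <- FALSE
  for (attempt in 1:500) {
    r <- rtps(entry)
    if (in_window(r[1]) && in_window(r[2])) { ok <- TRUE; break }
    if (length(itw) == 0)
      stop("generation error: RTP window unsatisfiable with no true-win trials")
    if (mean(r) < spec$rtp_target) {
      # upgrade the currently smallest true-win payout one entry up
      k <- itw[which.min(pay$payout_low[entry[itw]])]
      pos <- match(entry[k], te)
      if (pos >= length(te))
        stop("generation error: RTP target unreachable below pay-table maximum")
      entry[k] <- te[pos + 1]
    } else {
      k <- itw[which.max(pay$payout_low[entry[itw]])]
      pos <- match(entry[k], te)
      if (pos <= 1)
        stop("generation error: RTP target unreachable above pay-table minimum")
      entry[k] <- te[pos - 1]
    }
  }
  if (!ok) {
    r <- rtps(entry)
    if (!(in_window(r[1]) && in_window(r[2])))
      stop("generation error: RTP window not reached within payout-assignment attempts")
  }

  list(low = ifelse(is.na(entry), 0, pay$payout_low[entry]),
       high = ifelse(is.na(entry), 0, pay$payout_high[entry]))
}

#' Return-to-player of a trace under a constant-bet policy
#'
#' Total payout divided by total amount bet over the trace, with the double-up
#' gamble ignored (it is a fair 50-50 gamble and expectation-neutral).
#'
#' @param trace A `game_trace`.
#' @param bet_policy `"constant-low"` or `"constant-high"`.
#' @return Proportion (e.g. 0.90 for a 90\% RTP).
#' @export
compute_rtp <- function(trace, bet_policy = c("constant-low", "constant-high")) {
  bet_policy <- match.arg(bet_policy)
  bets <- bet_levels()
  if (bet_policy == "constant-low")
    sum(trace$payout_low) / (nrow(trace) * bets[["low"]])
  else
    sum(trace$payout_high) / (nrow(trace) * bets[["high"]])
}

#' Write / read a game trace as CSV
#'
#' @param trace A `game_trace`.
#' @param path File path.
#' @return `read_trace` returns the `game_trace`; `write_trace` its path,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  trace <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial", "outcome_class", "payout_low", "payout_high",
                  "du_offered") %in% names(trace)))
  class(trace) <- c("game_trace", "data.frame")
  trace
}
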