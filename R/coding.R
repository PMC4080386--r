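#' Perceptual coding schemes and response sets
#'
#' Three binary perceptual codings of trial outcomes are considered:
#' * `WLN` (win/loss net): only true wins count as wins;
#' * `OL` (overlearn): true wins, fake wins and near-misses all count as wins;
#' * `WLG` (win/loss gross): true and fake wins count as wins, near-misses as
#'   losses.
#'
#' Four nested response sets aggregate the binary action channels BI (bet
#' increase), DU (double-up acceptance), CS (casino switch) and MS (machine
#' switch) by a trial-wise logical OR.
#'
#' @return Character vector of scheme ids / list of response sets.
#' @export
perceptual_schemes <- function() c("WLN", "OL", "WLG")

#' @rdname perceptual_schemes
#' @export
response_sets <- function() {
  list("BI" = "BI",
       "BI_DU" = c("BI", "DU"),
       "BI_DU_CS" = c("BI", "DU", "CS"),
       "BI_DU_CS_MS" = c("BI", "DU", "CS", "MS"))
}

#' Encode trial outcomes as a binary perceptual series
#'
#' @param trace A `game_trace`.
#' @param scheme One of `"WLN"`, `"OL"`, `"WLG"`.
#' @return List of class `"perceptual_series"` with fields `scheme` and the
#'   binary input vector `u`.
#' @export
encode_perceptual <- function(trace, scheme) {
  if (!scheme %in% perceptual_schemes())
    stop("unknown perceptual coding scheme: ", scheme)
  cls <- trace$outcome_class
  u <- switch(scheme,
              WLN = as.integer(cls == "true_win"),
              WLG = as.integer(cls %in% c("true_win", "fake_win")),
              OL = as.integer(cls %in% c("true_win", "fake_win", "near_miss")))
  structure(list(scheme = scheme, u = u), class = "perceptual_series")
}

#' Aggregate action channels into one binary response series
#'
#' The trial-wise response is the logical OR over the channels in the
#' response set.
#'
#' @param channels Data frame or matrix with binary columns `BI`, `DU`, `CS`,
#'   `MS` (one row per trial).
#' @param response_set Character vector of channel names, e.g. `c("BI","DU")`.
#' @return List of class `"response_series"` with fields `response_set` and
#'   the binary vector `y`.
#' @export
aggregate_responses <- function(channels, response_set) {
  channels <- as.data.frame(channels)
  stopifnot(all(response_set %in% names(channels)))
  sub <- as.matrix(channels[, response_set, drop = FALSE])
  if (!all(sub %in% c(0, 1))) stop("channel matrix must be binary")
  structure(list(response_set = response_set,
                 y = as.integer(rowSums(sub) > 0)),
            class = "response_series")
}

#' Enumerate the twelve perceptual/response datasets
#'
#' Cartesian product of the three perceptual codings with the four nested
#' response sets, in the stable order (WLN, OL, WLG) x ({BI}, {BI,DU},
#' {BI,DU,CS}, {BI,DU,CS,MS}).
#'
#' @param trace A `game_trace`.
#' @param cohort A `simulated_cohort` (see [generate_cohort()]), or any list
#'   with a `responses` element holding one BI/DU/CS/MS channel data frame per
#'   subject.
#' @return Named list of 12 datasets; each has `label`, `scheme`,
#'   `response_set`, `u` (binary input) and `Y` (subjects x trials binary
#'   response matrix, rownames = subject ids).
#' @export
enumerate_datasets <- function(trace, cohort) {
  out <- list()
  for (scheme in perceptual_schemes()) {
    u <- encode_perceptual(trace, scheme)$u
    for (set_name in names(response_sets())) {
      set <- response_sets()[[set_name]]
      Y <- t(vapply(cohort$responses,
                    function(ch) aggregate_responses(ch, set)$y,
                    integer(length(u))))
      rownames(Y) <- names(cohort$responses)
      label <- paste0(scheme, "__", set_name)
      out[[label]] <- list(label = label, scheme = scheme,
                           response_set = set, u = u, Y = Y)
    }
  }
  out
}
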