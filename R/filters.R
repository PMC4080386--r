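#' Parameters of the three-level binary Hierarchical Gaussian Filter
#'
#' `kappa` couples the third level (log-volatility) into the second-level
#' step-size variance `exp(kappa * mu3 + omega)` and is fixed to 1 for
#' identifiability; `omega` is the fixed (tonic) component of that step-size
#' variance on the log scale; `theta` is the variance of the third-level
#' random walk. The initial states give the prior belief before the first
#' trial: with `mu2_0 = 0` the predicted winning probability starts at 0.5.
#'
#' @param omega Real, tonic log step-size at level 2.
#' @param theta Positive real, level-3 step size.
#' @param kappa Coupling strength, fixed at 1.
#' @param mu2_0,sigma2_0,mu3_0,sigma3_0 Initial means/variances of levels 2
#'   and 3.
#' @return List of class `"hgf_params"`.
#' @export
hgf_params <- function(omega = -4, theta = 0.05, kappa = 1,
                       mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1, sigma3_0 = 1) {
  stopifnot(theta > 0, sigma2_0 > 0, sigma3_0 > 0)
  if (kappa != 1) stop("kappa is fixed to 1 for identifiability")
  structure(list(omega = omega, theta = theta, kappa = kappa,
                 mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                 mu3_0 = mu3_0, sigma3_0 = sigma3_0),
            class = "hgf_params")
}

#' Run the binary three-level HGF over an input series
#'
#' Sequential variational belief updates: at each trial the predicted winning
#' probability is `x1hat = logistic(mu2)`, the outcome prediction error
#' `delta1 = u - x1hat` is weighted by the inverse posterior precision at
#' level 2, and a volatility prediction error `delta2` updates the
#' third-level belief with a step governed by `theta`. At every level the
#' belief change is a precision-ratio-weighted prediction error.
#'
#' @param u A `perceptual_series` or binary vector.
#' @param params An [hgf_params()].
#' @return Data frame of class `"hgf_trajectory"`, one row per trial, with
#'   columns `x1hat`, `sigma1`, `mu2`, `sigma2`, `mu3`, `sigma3`, `delta1`,
#'   `delta2`, `pihat2`, `pi2`, `pihat3`, `pi3`, `psi2`, `psi3`,
#'   `sigma2_pre`, `mu3_pre` (the `_pre` columns are the states available
#'   before the trial's response). The parameters are attached as attribute
#'   `"params"`.
#' @export
hgf_filter <- function(u, params = hgf_params()) {
  u <- as_input(u)
  res <- hgf_filter_c(u, params$kappa, params$omega, params$theta,
                      params$mu2_0, params$sigma2_0, params$mu3_0,
                      params$sigma3_0)
  if (res$bad_trial > 0)
    stop(sprintf("invalid-parameter signal: non-positive precision at trial %d",
                 res$bad_trial), call. = FALSE)
  traj <- as.data.frame(res$traj)
  attr(traj, "params") <- params
  class(traj) <- c("hgf_trajectory", "data.frame")
  traj
}

#' First-level uncertainty (Bernoulli variance) of a predicted probability
#'
#' `sigma1 = x1hat * (1 - x1hat)`, the variance of a Bernoulli outcome with
#' success probability `x1hat`; it peaks at 0.25 for `x1hat = 0.5`.
#'
#' @param x1hat Predicted winning probability in (0, 1).
#' @return Numeric vector of the same length.
#' @export
first_level_uncertainty <- function(x1hat) {
  if (any(x1hat <= 0) || any(x1hat >= 1))
    stop("x1hat must lie strictly inside (0, 1)")
  x1hat * (1 - x1hat)
}

#' Rescorla-Wagner parameters and filter
#'
#' Trial-wise delta-rule tracking of the outcome probability:
#' `V(k) = V(k-1) + alpha * (u(k) - V(k-1))`.
#'
#' @param alpha Learning rate in (0, 1).
#' @param V0 Initial value estimate in (0, 1).
#' @return `rw_params` returns a parameter list; `rw_filter` a data frame of
#'   class `"rw_trajectory"` with columns `V` (posterior estimate after the
#'   trial), `pe` (prediction error) and `V_pre` (estimate available before
#'   the trial's response).
#' @export
rw_params <- function(alpha = 0.1, V0 = 0.5) {
  stopifnot(alpha > 0, alpha < 1, V0 > 0, V0 < 1)
  structure(list(alpha = alpha, V0 = V0), class = "rw_params")
}

#' @rdname rw_params
#' @param u A `perceptual_series` or binary vector.
#' @param params An [rw_params()].
#' @export
rw_filter <- function(u, params = rw_params()) {
  u <- as_input(u)
  res <- rw_filter_c(u, params$alpha, params$V0)
  traj <- as.data.frame(res$traj)
  attr(traj, "params") <- params
  class(traj) <- c("rw_trajectory", "data.frame")
  traj
}

#' Write a belief trajectory to CSV
#'
#' @param traj An `hgf_trajectory` or `rw_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  df <- cbind(trial = seq_len(nrow(traj)), as.data.frame(traj))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_input <- function(u) {
  if (inherits(u, "perceptual_series")) u <- u$u
  u <- as.integer(u)
  if (!all(u %in% c(0L, 1L))) stop("input series must be binary")
  u
}
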