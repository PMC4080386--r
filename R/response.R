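#' Core model identifiers
#'
#' The five core models: M1-M4 combine the three-level binary HGF with four
#' softmax response variants; RW is a Rescorla-Wagner learner with softmax
#' choice.
#' * M1: constant decision temperature `beta` (free parameter), argument
#'   `x1hat`;
#' * M2: `beta(k) = 1 / sigma2` (second-level uncertainty, pre-trial);
#' * M3: `beta(k) = 1 / exp(mu3)` (volatility belief, pre-trial);
#' * M4: constant `beta`, argument `4 * sigma1` (first-level uncertainty
#'   scaled so its 0.25 maximum fills the unit interval);
#' * RW: constant `beta`, argument `V` (pre-trial value estimate).
#'
#' @return Character vector of model ids.
#' @export
core_models <- function() c("M1", "M2", "M3", "M4", "RW")

model_code <- function(model) match(match.arg(model, core_models()), core_models())

#' Names of the free parameters of a core model
#'
#' M1 and M4 estimate (omega, theta, beta); M2 and M3 estimate (omega, theta)
#' with the decision temperature supplied by the filter's own uncertainty;
#' RW estimates (alpha, beta).
#'
#' @param model A core model id.
#' @return Character vector of parameter names.
#' @export
free_parameters <- function(model) {
  switch(match.arg(model, core_models()),
         M1 = c("omega", "theta", "beta"),
         M2 = c("omega", "theta"),
         M3 = c("omega", "theta"),
         M4 = c("omega", "theta", "beta"),
         RW = c("alpha", "beta"))
}

#' Specification of a belief-to-response mapping
#'
#' @param model A core model id (see [core_models()]).
#' @param beta Positive decision temperature (M1, M4, RW only).
#' @param alpha Learning rate in (0,1) (RW only).
#' @param literal Logical; if `TRUE` (default) the sigmoid is applied to the
#'   raw belief, `p = 1/(1+exp(-2*beta*x))`, so `p >= 0.5` whenever `x >= 0`.
#'   If `FALSE` the argument is centred at 0.5 first.
#' @return List of class `"response_model_spec"`.
#' @export
response_model_spec <- function(model, beta = NULL, alpha = NULL,
                                literal = TRUE) {
  model <- match.arg(model, core_models())
  if (model %in% c("M1", "M4", "RW")) {
    if (is.null(beta) || beta <= 0)
      stop(model, " requires a positive decision temperature beta")
  }
  if (model == "RW" && (is.null(alpha) || alpha <= 0 || alpha >= 1))
    stop("RW requires a learning rate alpha in (0,1)")
  structure(list(model = model, beta = beta, alpha = alpha,
                 literal = literal),
            class = "response_model_spec")
}

#' Sigmoidal belief-to-action mapping
#'
#' `1 / (1 + exp(-2 * beta * x))` in the literal form, or with the argument
#' centred at 0.5 when `literal = FALSE`. Larger `beta` makes the mapping
#' steeper (more deterministic responding); `beta = 0` gives 0.5 everywhere.
#'
#' @param x Belief in `[0, 1]` (vectorised).
#' @param beta Non-negative decision temperature (scalar or per-trial vector).
#' @param literal Use the literal (uncentred) form; default `TRUE`.
#' @return Response probabilities.
#' @export
unit_softmax <- function(x, beta, literal = TRUE) {
  arg <- if (literal) x else x - 0.5
  1 / (1 + exp(-2 * beta * arg))
}

#' Per-trial decision temperature of a core model
#'
#' @param spec A [response_model_spec()].
#' @param traj An `hgf_trajectory` (required for M2/M3) with the pre-trial
#'   state columns.
#' @param n_trials Number of trials (used for M1/M4/RW when no trajectory is
#'   given).
#' @return List of class `"beta_series"` with per-trial `beta` and the
#'   `source` of its variation.
#' @export
beta_series <- function(spec, traj = NULL, n_trials = NULL) {
  model <- spec$model
  if (model %in% c("M2", "M3") && is.null(traj))
    stop("models M2 and M3 require an HGF trajectory to derive beta")
  if (is.null(n_trials)) n_trials <- nrow(traj)
  out <- switch(model,
    M1 = list(beta = rep(spec$beta, n_trials), source = "constant"),
    M4 = list(beta = rep(spec$beta, n_trials), source = "constant"),
    RW = list(beta = rep(spec$beta, n_trials), source = "constant"),
    M2 = list(beta = 1 / traj$sigma2_pre, source = "inverse-sigma2"),
    M3 = list(beta = 1 / exp(traj$mu3_pre), source = "inverse-exp-mu3"))
  if (any(!is.finite(out$beta)) || any(out$beta <= 0))
    stop("non-positive decision temperature in beta series")
  structure(out, class = "beta_series")
}

#' Per-trial response probabilities of a core model
#'
#' The trial-k response is driven by the beliefs available before outcome k
#' is revealed: `x1hat(k)` (a function of `mu2(k-1)`), `sigma2(k-1)`,
#' `mu3(k-1)`, or `V(k-1)`.
#'
#' @param spec A [response_model_spec()].
#' @param traj An `hgf_trajectory` (M1-M4) or `rw_trajectory` (RW).
#' @return Numeric vector of `p(y = 1)` per trial.
#' @export
response_probability <- function(spec, traj) {
  model <- spec$model
  if (model == "RW") {
    if (!"V_pre" %in% names(traj))
      stop("RW response model requires an rw_trajectory")
    return(unit_softmax(traj$V_pre, spec$beta, spec$literal))
  }
  if (!"x1hat" %in% names(traj))
    stop("HGF response models require an hgf_trajectory")
  if (model == "M4") {
    arg <- 4 * first_level_uncertainty(traj$x1hat)
    return(unit_softmax(arg, spec$beta, spec$literal))
  }
  b <- beta_series(spec, traj)$beta
  unit_softmax(traj$x1hat, b, spec$literal)
}

#' Bernoulli log-likelihood of a binary response series
#'
#' Probabilities are clipped to `[1e-12, 1 - 1e-12]` so that rounding cannot
#' produce `-Inf`.
#'
#' @param p Per-trial response probabilities.
#' @param y A `response_series` or binary vector.
#' @return Scalar log-likelihood.
#' @export
response_loglik <- function(p, y) {
  if (inherits(y, "response_series")) y <- y$y
  if (length(p) != length(y)) stop("length mismatch between p and y")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log1p(-p))
}
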