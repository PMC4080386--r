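#' Parameters of a synthetic agent
#'
#' An agent is one core model plus its generative parameter values. `beta` is
#' required for M1, M4 and RW; `alpha` for RW only; `kappa` is fixed at 1.
#'
#' @param model Core model id.
#' @param omega,theta HGF parameters (M1-M4).
#' @param beta Decision temperature (M1, M4, RW).
#' @param alpha Learning rate (RW).
#' @return List of class `"agent_params"`.
#' @export
agent_params <- function(model, omega = NULL, theta = NULL, beta = NULL,
                         alpha = NULL) {
  model <- match.arg(model, core_models())
  if (model != "RW") stopifnot(!is.null(omega), !is.null(theta), theta > 0)
  if (model %in% c("M1", "M4", "RW")) stopifnot(!is.null(beta), beta > 0)
  if (model == "RW") stopifnot(!is.null(alpha), alpha > 0, alpha < 1)
  structure(list(model = model, omega = omega, theta = theta, beta = beta,
                 alpha = alpha, kappa = 1),
            class = "agent_params")
}

#' Default per-channel base-rate multipliers
#'
#' The four action channels are not equally frequent in play: bet increases
#' and double-ups follow the model probability directly, while casino and
#' machine switches are rarer. The channel probability is the model's
#' response probability times the channel multiplier.
#'
#' @return Named numeric vector over BI, DU, CS, MS.
#' @export
channel_multipliers <- function() c(BI = 1.0, DU = 1.0, CS = 0.15, MS = 0.3)

#' Simulate one agent's responses on a trace
#'
#' Runs the agent's belief filter on the coded input series and, per trial,
#' draws each of the four channels as an independent Bernoulli with
#' probability `p(k) * multiplier[channel]`, where `p(k)` comes from the
#' agent's response model. The DU channel is forced to 0 on trials without a
#' double-up offer. Fully reproducible under `seed`.
#'
#' @param trace A `game_trace`.
#' @param params An [agent_params()].
#' @param coding Perceptual coding scheme used by the agent (default WLN).
#' @param seed Integer seed.
#' @param multipliers Per-channel base-rate multipliers.
#' @param literal Use the literal softmax form (default `TRUE`).
#' @return Data frame with binary columns `BI`, `DU`, `CS`, `MS` (one row per
#'   trial).
#' @export
simulate_agent_responses <- function(trace, params, coding = "WLN", seed = 1L,
                                     multipliers = channel_multipliers(),
                                     literal = TRUE) {
  u <- encode_perceptual(trace, coding)
  p <- tryCatch(
    agent_response_probability(u, params, literal),
    error = function(e) stop("simulation error for agent: ", conditionMessage(e),
                             call. = FALSE))
  n <- nrow(trace)
  with_seed(seed, {
    ch <- vapply(names(multipliers),
                 function(nm) rbinom(n, 1L, pmin(1, p * multipliers[[nm]])),
                 integer(n))
    ch <- as.data.frame(ch)
    ch$DU[trace$du_offered == 0L] <- 0L
    ch
  })
}

agent_response_probability <- function(u, params, literal = TRUE) {
  if (params$model == "RW") {
    traj <- rw_filter(u, rw_params(alpha = params$alpha))
  } else {
    traj <- hgf_filter(u, hgf_params(omega = params$omega,
                                     theta = params$theta))
  }
  spec <- response_model_spec(params$model, beta = params$beta,
                              alpha = params$alpha, literal = literal)
  response_probability(spec, traj)
}

#' Linear trait-score model for synthetic cohorts
#'
#' The synthetic trait score (a BIS-11-like impulsivity total) is a linear
#' function of the generative parameters plus Gaussian noise:
#' `trait = intercept + b_omega * omega + b_theta * theta + N(0, sd)`. The
#' default slopes are anchored at the construct-validity regression
#' coefficients of the winning model (2.42 on omega, 243.64 on theta) and the
#' noise is sized so the population R^2 is moderate (about 0.3).
#'
#' @param intercept,b_omega,b_theta,sd Model constants.
#' @return List of class `"trait_model"`.
#' @export
trait_model <- function(intercept = 60, b_omega = 2.42, b_theta = 243.64,
                        sd = 11) {
  stopifnot(sd >= 0)
  structure(list(intercept = intercept, b_omega = b_omega,
                 b_theta = b_theta, sd = sd),
            class = "trait_model")
}

#' Default generative parameter ranges for cohort sampling
#'
#' Uniform sampling intervals in native space, centred on the across-subject
#' parameter scale reported for this task (omega around -4, theta around
#' 0.05).
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
default_param_ranges <- function() {
  list(omega = c(-6, -2), theta = c(0.01, 0.1),
       beta = c(0.5, 8), alpha = c(0.1, 0.6))
}

#' Generate a synthetic cohort of agents
#'
#' Samples each subject's generative parameters uniformly in `param_ranges`,
#' simulates the four response channels on the trace, and computes a trait
#' score from the linear `trait_model`. Optionally writes the cohort in the
#' standard CSV layout (`responses_<subject>.csv` per subject plus
#' `covariates.csv`).
#'
#' @param n_subjects Number of subjects (the study cohort size is 47).
#' @param trace A `game_trace`.
#' @param model Generating core model for all subjects (default M2, the
#'   winning model class).
#' @param param_ranges Named list of sampling ranges; see
#'   [default_param_ranges()].
#' @param trait Trait-score model; see [trait_model()].
#' @param coding Perceptual coding the agents respond under.
#' @param seed Integer seed.
#' @param multipliers Channel base-rate multipliers.
#' @param out_dir Optional directory to write the CSV layout into.
#' @return List of class `"simulated_cohort"` with `params` (per-subject
#'   generative values), `responses` (list of channel data frames),
#'   `covariates` (data frame with subject, trait_score and true parameters)
#'   and the generation settings.
#' @export
generate_cohort <- function(n_subjects = 47, trace = generate_trace(),
                            model = "M2",
                            param_ranges = default_param_ranges(),
                            trait = trait_model(), coding = "WLN", seed = 1L,
                            multipliers = channel_multipliers(),
                            out_dir = NULL) {
  model <- match.arg(model, core_models())
  ids <- sprintf("S%03d", seq_len(n_subjects))
  need <- free_parameters(model)

  draws <- with_seed(derive_seed(seed, "cohort-params"), {
    vals <- lapply(need, function(nm) {
      r <- param_ranges[[nm]]
      if (is.null(r)) stop("no sampling range given for parameter ", nm)
      runif(n_subjects, r[1], r[2])
    })
    names(vals) <- need
    as.data.frame(vals)
  })

  params <- lapply(seq_len(n_subjects), function(i) {
    agent_params(model,
                 omega = if ("omega" %in% need) draws$omega[i],
                 theta = if ("theta" %in% need) draws$theta[i],
                 beta = if ("beta" %in% need) draws$beta[i],
                 alpha = if ("alpha" %in% need) draws$alpha[i])
  })
  names(params) <- ids

  responses <- lapply(seq_len(n_subjects), function(i) {
    tryCatch(
      simulate_agent_responses(trace, params[[i]], coding = coding,
                               seed = derive_seed(seed, paste0("agent-", i)),
                               multipliers = multipliers),
      error = function(e) stop("subject ", ids[i], ": ", conditionMessage(e),
                               call. = FALSE))
  })
  names(responses) <- ids

  noise <- with_seed(derive_seed(seed, "trait-noise"),
                     rnorm(n_subjects, 0, trait$sd))
  omega_v <- if ("omega" %in% need) draws$omega else rep(0, n_subjects)
  theta_v <- if ("theta" %in% need) draws$theta else rep(0, n_subjects)
  trait_score <- trait$intercept + trait$b_omega * omega_v +
    trait$b_theta * theta_v + noise

  covariates <- data.frame(subject = ids, trait_score = trait_score,
                           true_omega = if ("omega" %in% need) draws$omega else NA,
                           true_theta = if ("theta" %in% need) draws$theta else NA,
                           true_beta = if ("beta" %in% need) draws$beta else NA,
                           core_model = model)

  cohort <- structure(list(n_subjects = n_subjects, model = model,
                           params = params, responses = responses,
                           covariates = covariates, trait_model = trait,
                           coding = coding, seed = seed),
                      class = "simulated_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write / read a cohort in the standard CSV layout
#'
#' One `responses_<subject>.csv` per subject (columns `trial`, `BI`, `DU`,
#' `CS`, `MS`) plus `covariates.csv` (columns `subject`, `trait_score`,
#' `true_omega`, `true_theta`, `true_beta`, `core_model`).
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Directory path.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a list with
#'   `responses` and `covariates`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$responses)) {
    df <- cbind(trial = seq_len(nrow(cohort$responses[[id]])),
                cohort$responses[[id]])
    write.csv(df, file.path(dir, paste0("responses_", id, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  cov <- cohort$covariates
  cov$trait_score <- round(cov$trait_score, 6)
  for (nm in c("true_omega", "true_theta", "true_beta"))
    cov[[nm]] <- round(cov[[nm]], 10)
  write.csv(cov, file.path(dir, "covariates.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cov <- read.csv(file.path(dir, "covariates.csv"), stringsAsFactors = FALSE)
  responses <- lapply(cov$subject, function(id) {
    df <- read.csv(file.path(dir, paste0("responses_", id, ".csv")))
    df[, c("BI", "DU", "CS", "MS")]
  })
  names(responses) <- cov$subject
  list(responses = responses, covariates = cov)
}
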