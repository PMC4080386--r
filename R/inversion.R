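#' Prior specification for MAP fitting
#'
#' Independent Gaussian priors in transformed space: `omega` on the identity
#' scale, `theta` and `beta` on the log scale (guaranteeing positivity), and
#' `alpha` on the logit scale (guaranteeing (0,1)). Defaults are centred on
#' the across-subject parameter scale typical for this task (omega near -4,
#' theta near 0.05) and are deliberately weak.
#'
#' @param omega,theta,beta,alpha Length-2 vectors `c(mean, sd)` on the
#'   transformed scale (`theta`/`beta`: log scale, `alpha`: logit scale).
#' @return List of class `"prior_spec"`.
#' @export
prior_spec <- function(omega = c(-4, 2), theta = c(log(0.05), 1),
                       beta = c(0, 2), alpha = c(0, 1.5)) {
  pr <- list(omega = omega, theta = theta, beta = beta, alpha = alpha)
  if (any(vapply(pr, function(x) x[2] <= 0, logical(1))))
    stop("prior sds must be positive")
  structure(pr, class = "prior_spec")
}

param_transform <- function(name) {
  switch(name, omega = "identity", theta = "log", beta = "log",
         alpha = "logit")
}

to_native <- function(par_t, names) {
  out <- numeric(length(par_t))
  for (i in seq_along(par_t)) {
    out[i] <- switch(param_transform(names[i]),
                     identity = par_t[i],
                     log = exp(par_t[i]),
                     logit = 1 / (1 + exp(-par_t[i])))
  }
  stats::setNames(out, names)
}

prior_moments <- function(priors, names) {
  m <- vapply(names, function(nm) priors[[nm]][1], numeric(1))
  s <- vapply(names, function(nm) priors[[nm]][2], numeric(1))
  list(mean = m, sd = s)
}

#' MAP objective: log joint of parameters and responses
#'
#' Response log-likelihood of the core model (filter, then response model,
#' then Bernoulli likelihood) plus the Gaussian log prior density in
#' transformed space. Returns `-Inf` where the filter signals an invalid
#' parameter set, so optimisers simply avoid the region.
#'
#' @param par_t Parameter vector in transformed space, ordered as
#'   [free_parameters()] of the model.
#' @param u Binary input series (or `perceptual_series`).
#' @param y Binary response series (or `response_series`).
#' @param model Core model id.
#' @param priors A [prior_spec()].
#' @param literal Use the literal softmax form.
#' @param include_prior Include the prior terms (set `FALSE` for the pure
#'   log-likelihood).
#' @return Scalar log joint.
#' @export
log_joint <- function(par_t, u, y, model, priors = prior_spec(),
                      literal = TRUE, include_prior = TRUE) {
  model <- match.arg(model, core_models())
  u <- as_input(u)
  if (inherits(y, "response_series")) y <- y$y
  nm <- free_parameters(model)
  stopifnot(length(par_t) == length(nm))
  pm <- prior_moments(priors, nm)
  log_joint_c(as.numeric(par_t), u, as.integer(y), model_code(model),
              pm$mean, pm$sd, 1.0, c(0, 1, 1, 1), !literal, include_prior)
}

#' Optimiser configuration for subject fits
#'
#' Deterministic multistart quasi-Newton (BFGS) maximisation: starting points
#' are drawn from the prior-quantile lattice `{0.1, 0.5, 0.9}` per dimension,
#' subsampled deterministically to `n_restarts`.
#'
#' @param n_restarts Number of restarts (default 8).
#' @param maxit Maximum BFGS iterations per restart.
#' @param reltol Relative convergence tolerance of the objective.
#' @param hessian_step Central finite-difference step for the Hessian.
#' @return List of class `"fit_control"`.
#' @export
fit_control <- function(n_restarts = 8, maxit = 500, reltol = 1e-10,
                        hessian_step = 1e-4) {
  structure(list(n_restarts = n_restarts, maxit = maxit, reltol = reltol,
                 hessian_step = hessian_step),
            class = "fit_control")
}

start_points <- function(priors, names, n_restarts) {
  qs <- lapply(names, function(nm)
    qnorm(c(0.5, 0.1, 0.9), priors[[nm]][1], priors[[nm]][2]))
  grid <- as.matrix(expand.grid(qs))
  colnames(grid) <- names
  # prior-mean start first, then an even deterministic subsample of the lattice
  ord <- c(1, setdiff(seq_len(nrow(grid)), 1))
  grid <- grid[ord, , drop = FALSE]
  keep <- unique(round(seq(1, nrow(grid), length.out = min(n_restarts, nrow(grid)))))
  grid[keep, , drop = FALSE]
}

# central finite-difference Hessian
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in (i + 1):d) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

# Laplace approximation to the log evidence at a mode
laplace_evidence <- function(lj, H) {
  d <- nrow(H)
  ch <- tryCatch(chol(-H), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  lj + d / 2 * log(2 * pi) - sum(log(diag(ch)))
}

#' Fit one subject by MAP with Laplace model evidence
#'
#' Multistart deterministic BFGS maximisation of [log_joint()] in transformed
#' space. The log model evidence is approximated by the Laplace method at the
#' posterior mode, `log p(y) ~ log_joint(MAP) + d/2 log 2*pi - 1/2 log
#' det(-H)`, with the Hessian `H` from central finite differences. If `-H` is
#' not positive definite the fit falls back to a BIC-style evidence
#' `loglik(MAP) - d/2 log n` and flags the fallback.
#'
#' @param u Binary input series.
#' @param y Binary response series.
#' @param model Core model id.
#' @param priors A [prior_spec()].
#' @param control A [fit_control()].
#' @param subject,dataset Optional labels carried into the result.
#' @param literal Use the literal softmax form.
#' @return List of class `"subject_fit"`: native-space `estimates`,
#'   transformed-space `par_t` and `hessian`, `log_joint`, `log_lik`,
#'   `log_evidence`, `laplace_fallback`, and convergence diagnostics.
#' @export
fit_subject <- function(u, y, model, priors = prior_spec(),
                        control = fit_control(), subject = NA, dataset = NA,
                        literal = TRUE) {
  model <- match.arg(model, core_models())
  u <- as_input(u)
  if (inherits(y, "response_series")) y <- y$y
  if (length(y) == 0) stop("empty dataset")
  nm <- free_parameters(model)
  pm <- prior_moments(priors, nm)
  negf <- function(p) {
    v <- log_joint_c(p, u, as.integer(y), model_code(model), pm$mean, pm$sd,
                     1.0, c(0, 1, 1, 1), !literal, TRUE)
    if (!is.finite(v)) 1e10 else -v
  }

  starts <- start_points(priors, nm, control$n_restarts)
  best <- NULL
  n_ok <- 0
  for (r in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[r, ], negf, method = "BFGS",
            control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e9) next
    n_ok <- n_ok + 1
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("fit error: all optimiser restarts failed for subject ", subject,
         ", model ", model)

  par_hat <- best$par
  lj <- -best$value
  ll <- log_joint_c(par_hat, u, as.integer(y), model_code(model), pm$mean,
                    pm$sd, 1.0, c(0, 1, 1, 1), !literal, FALSE)
  H <- fd_hessian(function(p) -negf(p), par_hat, control$hessian_step)
  le <- laplace_evidence(lj, H)
  fallback <- is.null(le)
  if (fallback) le <- ll - length(nm) / 2 * log(length(y))

  g <- numeric(length(par_hat))
  h <- control$hessian_step
  for (i in seq_along(par_hat)) {
    ei <- replace(numeric(length(par_hat)), i, h)
    g[i] <- (negf(par_hat + ei) - negf(par_hat - ei)) / (2 * h)
  }

  structure(list(subject = subject, model = model, dataset = dataset,
                 estimates = to_native(par_hat, nm), par_t = setNames(par_hat, nm),
                 hessian = H, log_joint = lj, log_lik = ll, log_evidence = le,
                 laplace_fallback = fallback, n_restarts = n_ok,
                 best_objective = best$value, grad_norm = sqrt(sum(g^2)),
                 convergence = best$convergence),
            class = "subject_fit")
}

#' Fit all subjects of one dataset under one core model
#'
#' @param dataset One element of [enumerate_datasets()] (fields `u`, `Y`,
#'   `label`).
#' @param model Core model id.
#' @param priors,control,literal Passed to [fit_subject()].
#' @return Named list of `subject_fit`s (failed subjects are dropped with a
#'   warning).
#' @export
fit_dataset <- function(dataset, model, priors = prior_spec(),
                        control = fit_control(), literal = TRUE) {
  ids <- rownames(dataset$Y)
  fits <- list()
  for (s in seq_along(ids)) {
    f <- tryCatch(
      fit_subject(dataset$u, dataset$Y[s, ], model, priors, control,
                  subject = ids[s], dataset = dataset$label,
                  literal = literal),
      error = function(e) {
        warning("subject ", ids[s], " excluded: ", conditionMessage(e))
        NULL
      })
    if (!is.null(f)) fits[[ids[s]]] <- f
  }
  fits
}

#' Evidence matrix over models for one dataset
#'
#' @param fits_by_model Named list (model id -> list of `subject_fit`s, as
#'   returned by [fit_dataset()]).
#' @return Subjects x models matrix of log evidences (only subjects fitted
#'   under every model are kept).
#' @export
evidence_matrix <- function(fits_by_model) {
  ids <- Reduce(intersect, lapply(fits_by_model, names))
  E <- vapply(fits_by_model,
              function(fits) vapply(ids, function(id) fits[[id]]$log_evidence,
                                    numeric(1)),
              numeric(length(ids)))
  E <- matrix(E, nrow = length(ids), dimnames = list(ids, names(fits_by_model)))
  E
}

#' Write fits as JSON records
#'
#' One record per (subject, model, dataset) with all fit fields.
#'
#' @param fits List of `subject_fit`s.
#' @param path Output file.
#' @export
write_fits <- function(fits, path) {
  recs <- lapply(fits, function(f) {
    list(subject = f$subject, model = f$model, dataset = f$dataset,
         estimates = as.list(f$estimates), par_t = as.list(f$par_t),
         hessian = f$hessian, log_joint = f$log_joint, log_lik = f$log_lik,
         log_evidence = f$log_evidence, laplace_fallback = f$laplace_fallback,
         n_restarts = f$n_restarts, best_objective = f$best_objective,
         grad_norm = f$grad_norm, convergence = f$convergence)
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
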