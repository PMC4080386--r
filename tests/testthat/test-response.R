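test_that("the sigmoidal belief-to-action mapping matches its closed form", {
  expect_equal(unit_softmax(0, 5), 0.5)
  expect_equal(unit_softmax(0.5, 1), 1 / (1 + exp(-1)))
  expect_equal(unit_softmax(0.5, 1), 0.7311, tolerance = 1e-4)
  # monotone in the belief at fixed temperature
  x <- seq(0, 1, by = 0.1)
  expect_true(all(diff(unit_softmax(x, 2)) > 0))
  # centred variant has its midpoint at 0.5
  expect_equal(unit_softmax(0.5, 3, literal = FALSE), 0.5)
  # literal form cannot go below 0.5 for non-negative beliefs
  expect_true(all(unit_softmax(x, 2) >= 0.5))
})

test_that("decision-temperature series follow the model definitions", {
  traj <- mock_hgf_traj(x1hat = c(0.4, 0.6), sigma2_pre = c(2, 0.5),
                        mu3_pre = c(0, 1))
  expect_equal(beta_series(response_model_spec("M2"), traj)$beta, c(0.5, 2))
  expect_equal(beta_series(response_model_spec("M3"), traj)$beta,
               c(1, exp(-1)))
  m1 <- beta_series(response_model_spec("M1", beta = 3), n_trials = 5)
  expect_equal(m1$beta, rep(3, 5))
  expect_equal(m1$source, "constant")
  expect_error(beta_series(response_model_spec("M2")), "trajectory")
})

test_that("response probabilities use pre-trial beliefs per model", {
  traj <- mock_hgf_traj(x1hat = c(0.3, 0.7), sigma2_pre = c(1, 2),
                        mu3_pre = c(0, 0.5))
  expect_equal(response_probability(response_model_spec("M1", beta = 2), traj),
               unit_softmax(c(0.3, 0.7), 2))
  expect_equal(response_probability(response_model_spec("M2"), traj),
               unit_softmax(c(0.3, 0.7), 1 / c(1, 2)))
  expect_equal(response_probability(response_model_spec("M3"), traj),
               unit_softmax(c(0.3, 0.7), exp(-c(0, 0.5))))
  # M4: argument is 4*sigma1, maximal (=1) at x1hat = 0.5, symmetric
  t_sym <- mock_hgf_traj(x1hat = c(0.1, 0.5, 0.9))
  p4 <- response_probability(response_model_spec("M4", beta = 1.5), t_sym)
  expect_equal(p4[1], p4[3])
  expect_equal(max(p4), p4[2])
  expect_equal(p4[2], unit_softmax(1, 1.5))
  # RW uses the pre-trial value estimate
  rw <- rw_filter(c(1L, 1L, 0L), rw_params(alpha = 0.2, V0 = 0.5))
  prw <- response_probability(response_model_spec("RW", beta = 2, alpha = 0.2),
                              rw)
  expect_equal(prw, unit_softmax(rw$V_pre, 2))
  expect_equal(rw$V_pre[1], 0.5)
})

test_that("a step-function temperature saturates the response", {
  traj <- mock_hgf_traj(x1hat = rep(0.9, 10))
  p <- response_probability(response_model_spec("M1", beta = 1e4), traj)
  expect_true(all(p > 1 - 1e-6))
})

test_that("larger second-level uncertainty pulls responses to the midpoint", {
  traj <- mock_hgf_traj(x1hat = rep(0.6, 2), sigma2_pre = c(0.5, 5))
  p <- response_probability(response_model_spec("M2"), traj)
  expect_lt(abs(p[2] - 0.5), abs(p[1] - 0.5))
})

test_that("free-parameter counts match the model-space contract", {
  expect_equal(free_parameters("M1"), c("omega", "theta", "beta"))
  expect_equal(free_parameters("M2"), c("omega", "theta"))
  expect_equal(free_parameters("M3"), c("omega", "theta"))
  expect_equal(free_parameters("M4"), c("omega", "theta", "beta"))
  expect_equal(free_parameters("RW"), c("alpha", "beta"))
})

test_that("the Bernoulli response log-likelihood matches hand arithmetic", {
  expect_equal(response_loglik(rep(0.5, 7), rep(1L, 7)), 7 * log(0.5))
  expect_equal(response_loglik(c(0.8, 0.3), c(1L, 0L)), log(0.8) + log(0.7))
  expect_equal(response_loglik(c(0.8, 0.3), c(1L, 0L)), -0.5798,
               tolerance = 1e-4)
  expect_equal(response_loglik(1 - 1e-15, 1L), 0, tolerance = 1e-10)
  expect_error(response_loglik(c(0.5, 0.5), 1L), "length mismatch")
})

test_that("the compiled MAP objective equals the R-composed pipeline", {
  tr <- default_trace()
  u <- encode_perceptual(tr, "WLN")
  y <- withr::with_seed(8, rbinom(200, 1, 0.6))
  priors <- prior_spec()
  cases <- list(M1 = c(-4, log(0.05), log(2)),
                M2 = c(-3.5, log(0.08)),
                M3 = c(-4.5, log(0.03)),
                M4 = c(-4, log(0.05), log(1)),
                RW = c(0.2, log(1.5)))
  for (model in names(cases)) {
    par_t <- cases[[model]]
    nm <- free_parameters(model)
    native <- setNames(par_t, nm)
    native[nm %in% c("theta", "beta")] <- exp(native[nm %in% c("theta", "beta")])
    if ("alpha" %in% nm) native["alpha"] <- plogis(par_t[match("alpha", nm)])
    traj <- if (model == "RW") {
      rw_filter(u, rw_params(alpha = native[["alpha"]]))
    } else {
      hgf_filter(u, hgf_params(omega = native[["omega"]],
                               theta = native[["theta"]]))
    }
    spec <- response_model_spec(model,
                                beta = if ("beta" %in% nm) native[["beta"]],
                                alpha = if ("alpha" %in% nm) native[["alpha"]])
    ll_r <- response_loglik(response_probability(spec, traj), y)
    lp <- sum(vapply(seq_along(nm), function(j)
      dnorm(par_t[j], priors[[nm[j]]][1], priors[[nm[j]]][2], log = TRUE),
      numeric(1)))
    expect_equal(log_joint(par_t, u, y, model, priors), ll_r + lp,
                 tolerance = 1e-10, info = model)
    expect_equal(log_joint(par_t, u, y, model, priors, include_prior = FALSE),
                 ll_r, tolerance = 1e-10, info = model)
  }
})
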