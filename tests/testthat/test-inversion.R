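test_that("the MAP objective matches a hand-built two-trial oracle", {
  u <- c(1L, 0L)
  y <- c(1L, 0L)
  priors <- prior_spec()
  par_t <- c(-4, log(0.05), log(2))       # omega, log theta, log beta for M1
  # hand-computed pieces: filter from an unbiased start predicts x1hat(1)=0.5;
  # second prediction from the updated mu2
  traj <- hgf_filter(u, hgf_params(omega = -4, theta = 0.05))
  p <- 1 / (1 + exp(-2 * 2 * traj$x1hat))
  ll_hand <- log(p[1]) + log(1 - p[2])
  lp_hand <- dnorm(-4, -4, 2, log = TRUE) +
    dnorm(log(0.05), log(0.05), 1, log = TRUE) +
    dnorm(log(2), 0, 2, log = TRUE)
  expect_equal(log_joint(par_t, u, y, "M1", priors), ll_hand + lp_hand,
               tolerance = 1e-12)
})

test_that("invalid parameter regions map to a -Inf log joint", {
  case <- invalid_hgf_case()
  y <- rep(0L, length(case$u))
  lj <- log_joint(c(0, log(2)), case$u, y, "M2")
  expect_identical(lj, -Inf)
})

test_that("a near-zero-sd prior pins its parameter at the prior mean", {
  tr <- default_trace()
  u <- encode_perceptual(tr, "WLN")
  y <- withr::with_seed(5, rbinom(200, 1, 0.7))
  priors <- prior_spec(beta = c(log(3), 1e-4))
  f <- fit_subject(u, y, "M1", priors, fit_control(n_restarts = 2,
                                                   maxit = 200))
  expect_equal(unname(f$estimates["beta"]), 3, tolerance = 1e-2)
})

test_that("refitting with identical configuration reproduces the result", {
  tr <- default_trace()
  u <- encode_perceptual(tr, "WLN")
  ap <- agent_params("M2", omega = -3.5, theta = 0.06)
  y <- simulate_agent_responses(tr, ap, seed = 14)$BI
  f1 <- fit_subject(u, y, "M2")
  f2 <- fit_subject(u, y, "M2")
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$log_evidence, f2$log_evidence)
})

test_that("the MAP dominates the generating parameters in log joint", {
  tr <- default_trace()
  u <- encode_perceptual(tr, "WLN")
  for (s in 1:3) {
    om <- c(-5, -4, -3)[s]
    th <- c(0.03, 0.05, 0.08)[s]
    ap <- agent_params("M2", omega = om, theta = th)
    y <- simulate_agent_responses(tr, ap, seed = 100 + s)$BI
    f <- fit_subject(u, y, "M2")
    lj_true <- log_joint(c(om, log(th)), u, y, "M2")
    expect_gte(f$log_joint, lj_true - 1e-8)
  }
})

test_that("the Laplace evidence is exact for a Gaussian log joint", {
  # unnormalised Gaussian: log f(x) = -0.5 * sum((x-m)^2 / s^2);
  # its integral is prod(s) * (2*pi)^(d/2)
  m <- c(1, -2)
  s <- c(0.5, 3)
  f <- function(x) -0.5 * sum((x - m)^2 / s^2)
  H <- slotbelief:::fd_hessian(f, m, h = 1e-4)
  le <- slotbelief:::laplace_evidence(f(m), H)
  expect_equal(le, sum(log(s)) + length(m) / 2 * log(2 * pi),
               tolerance = 1e-7)
})

test_that("omega is recovered within tolerance across seeded replicates", {
  tr <- default_trace()
  u <- encode_perceptual(tr, "WLN")
  hits <- 0
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    ap <- agent_params("M1", omega = -4, theta = 0.05, beta = 5)
    y <- simulate_agent_responses(tr, ap, seed = 1000 + s)$BI
    f <- fit_subject(u, y, "M1", control = fast_control())
    if (abs(f$estimates[["omega"]] - (-4)) <= 1.5) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_rep)
})

test_that("the evidence penalises the extra parameter of a nested rival", {
  tr <- default_trace()
  u <- encode_perceptual(tr, "WLN")
  gaps <- vapply(1:10, function(s) {
    ap <- agent_params("M2", omega = -4, theta = 0.05)
    y <- simulate_agent_responses(tr, ap, seed = 2000 + s)$BI
    f2 <- fit_subject(u, y, "M2", control = fast_control())
    f1 <- fit_subject(u, y, "M1", control = fast_control())
    f1$log_evidence - f2$log_evidence
  }, numeric(1))
  expect_lte(median(gaps), 3)
})

test_that("dataset fits produce a finite evidence matrix", {
  tr <- default_trace()
  co <- generate_cohort(4, tr, seed = 6)
  ds <- enumerate_datasets(tr, co)[["WLN__BI"]]
  fits <- lapply(setNames(c("M2", "RW"), c("M2", "RW")),
                 function(m) fit_dataset(ds, m, control = fast_control()))
  E <- evidence_matrix(fits)
  expect_equal(dim(E), c(4, 2))
  expect_true(all(is.finite(E)))
  path <- withr::local_tempfile(fileext = ".json")
  write_fits(fits[["M2"]], path)
  rec <- jsonlite::read_json(path)
  expect_length(rec, 4)
  expect_equal(rec[[1]]$model, "M2")
  expect_equal(rec[[1]]$dataset, "WLN__BI")
})
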