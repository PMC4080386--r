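# shared fixtures, built once per test run

default_trace <- local({
  tr <- NULL
  function() {
    if (is.null(tr)) tr <<- generate_trace()
    tr
  }
})

# a small, cheap optimiser configuration for cohort-scale studies
fast_control <- function() fit_control(n_restarts = 3, maxit = 200)

# hand-built HGF-trajectory-like frame for response-model unit tests
mock_hgf_traj <- function(x1hat, sigma2_pre = rep(1, length(x1hat)),
                          mu3_pre = rep(0, length(x1hat))) {
  data.frame(x1hat = x1hat, sigma1 = x1hat * (1 - x1hat),
             sigma2_pre = sigma2_pre, mu3_pre = mu3_pre)
}

# parameter set known to drive the level-3 precision non-positive at trial 61
invalid_hgf_case <- function() {
  list(u = c(rep(0L, 60), 1L, rep(0L, 139)),
       params = hgf_params(omega = 0, theta = 2))
}
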