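#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet-multinomial scheme over which model generated each
#' subject's data: iterate assignment weights
#' `u_nk ~ exp(E_nk + digamma(alpha_k) - digamma(sum(alpha)))` (normalised per
#' subject) and Dirichlet counts `alpha_k = alpha0 + sum_n u_nk` until the
#' largest change in `alpha` falls below `tol`. The posterior expected model
#' probability is `r_k = alpha_k / sum(alpha)`; exceedance probabilities (the
#' posterior probability that model k is the most frequent) are estimated by
#' seeded Monte-Carlo Dirichlet sampling.
#'
#' @param E Subjects x models matrix of log evidences (finite).
#' @param alpha0 Dirichlet prior count per model (default 1, uniform).
#' @param tol Convergence tolerance on `max |delta alpha|`.
#' @param max_iter Maximum iterations; non-convergence returns the last
#'   iterate with a warning and `converged = FALSE`.
#' @param n_exceed Number of Dirichlet draws for the exceedance estimate.
#' @param seed Seed for the exceedance sampling.
#' @return List of class `"bms_result"`: `alpha`, `r` (posterior expected
#'   model probabilities), `exceedance`, `winner`, `iterations`, `converged`.
#' @export
rfx_bms <- function(E, alpha0 = 1, tol = 1e-6, max_iter = 500,
                    n_exceed = 1e5, seed = 1L) {
  E <- as.matrix(E)
  if (!all(is.finite(E))) stop("evidence matrix must be finite")
  if (nrow(E) < 2 || ncol(E) < 2)
    stop("need at least 2 subjects and 2 models")
  K <- ncol(E)
  alpha <- rep(alpha0, K)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    lw <- sweep(E, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged) warning("rfx_bms did not converge in ", max_iter, " iterations")

  r <- alpha / sum(alpha)
  xp <- with_seed(seed, {
    draws <- matrix(rgamma(n_exceed * K, shape = rep(alpha, each = n_exceed)),
                    ncol = K)
    tabulate(max.col(draws), nbins = K) / n_exceed
  })
  names(r) <- names(xp) <- colnames(E)
  structure(list(alpha = setNames(alpha, colnames(E)), r = r,
                 exceedance = xp,
                 winner = colnames(E)[which.max(r)],
                 iterations = it, converged = converged),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects BMS over", length(x$r), "models\n")
  cat("  posterior model probabilities r_k:\n")
  print(round(x$r, 4))
  cat("  exceedance probabilities:\n")
  print(round(x$exceedance, 4))
  cat("  winner:", x$winner, "(", x$iterations, "iterations )\n")
  invisible(x)
}
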